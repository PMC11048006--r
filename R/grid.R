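# The experiment grid: one stratified 67/33 split per cohort, reused for
# every region and classifier of that cohort; the leakage-safe chain
# (z-score, correlation filter, importance selection, SMOTE) refitted per
# region on the training rows only.

#' Stratified train/test split
#'
#' @param labels binary labels.
#' @param fraction training fraction (default 0.67).
#' @param seed integer seed.
#' @return Integer vector of training row indices (test = the rest).
#' @export
stratified_split <- function(labels, fraction = 0.67, seed = 42L) {
  labels <- as.integer(labels)
  with_seed(seed, {
    idx <- unlist(lapply(unique(labels), function(k) {
      rows <- which(labels == k)
      sample(rows, max(1L, round(fraction * length(rows))))
    }))
    sort(idx)
  })
}

# Fit the preprocessing chain on training rows and transform both
# partitions. Returns the balanced training matrix, transformed test
# matrix and the fitted reports (for leakage auditing).
fit_prep_chain <- function(train_x, train_y, test_x, threshold_r = 0.8,
                           k_selected = 30L, seed = 42L,
                           smote_k = 5L) {
  scaler <- zscore_fit(train_x)
  ztr <- zscore_apply(scaler, train_x)
  zte <- zscore_apply(scaler, test_x)
  corr <- correlation_filter(ztr, threshold_r)
  ztr <- ztr[, corr$kept, drop = FALSE]
  zte <- zte[, corr$kept, drop = FALSE]
  k_eff <- min(k_selected, ncol(ztr))
  sel <- importance_select(ztr, train_y, k = k_eff, seed = seed)
  ztr <- ztr[, sel$kept, drop = FALSE]
  zte <- zte[, sel$kept, drop = FALSE]
  bal <- smote(ztr, train_y, k_neighbours = smote_k, seed = seed)
  list(train_x = bal$x, train_y = bal$y, test_x = zte,
       scaler = scaler, corr = corr, sel = sel)
}

feature_columns <- function(df) {
  setdiff(names(df), c("subject_id", "grade_label", "region"))
}

# One cell: train every spec on the balanced training data, score the test
# partition, return a metrics row per spec.
run_cell_models <- function(prep, test_y, specs) {
  out <- list()
  for (nm in names(specs)) {
    model <- train_model(specs[[nm]], prep$train_x, prep$train_y)
    pr <- predict(model, prep$test_x)
    cm <- confusion(test_y, pr$label)
    mr <- diagnostic_metrics(cm, scores = pr$score, y_true = test_y)
    out[[nm]] <- data.frame(model = nm, ACC = mr$ACC, SEN = mr$SEN,
                            SPE = mr$SPE, AUC = mr$AUC, MCC = mr$MCC,
                            F1 = mr$F1, McN_p = mr$McN_p,
                            chi2_p = as.numeric(mr$chi2_p),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the classifier x region x cohort experiment grid
#'
#' For each cohort, draws a single stratified split (reused across all
#' regions and classifiers of that cohort), refits the leakage-safe
#' preprocessing chain per region on the training rows, trains every
#' classifier and evaluates on the held-out rows. With 3 cohorts, 7
#' regions and 11 classifiers this yields the full 231-cell grid.
#'
#' @param cohort_tables named list of cohorts; each cohort is a named list
#'   of per-region feature tables (from [extract_feature_table()]) sharing
#'   the subject index.
#' @param specs classifier specifications, see [default_model_specs()].
#' @param split_fraction training fraction (default 0.67).
#' @param seed seed for splitting, selection and SMOTE.
#' @param threshold_r,k_selected,smote_k preprocessing parameters.
#' @return An `experiment_grid`: data frame of per-cell metrics with the
#'   split row-index hash per cohort in `attr(, "splits")`.
#' @export
run_grid <- function(cohort_tables, specs = default_model_specs(),
                     split_fraction = 0.67, seed = 42L, threshold_r = 0.8,
                     k_selected = 30L, smote_k = 5L) {
  rows <- list()
  splits <- list()
  for (cn in names(cohort_tables)) {
    tables <- cohort_tables[[cn]]
    ids <- tables[[1]]$subject_id
    y <- as.integer(tables[[1]]$grade_label)
    for (tb in tables) {
      if (!identical(tb$subject_id, ids) ||
          !identical(as.integer(tb$grade_label), y))
        stop_subgrade(sprintf(
          "region tables of cohort %s do not share the subject index", cn),
          "subgrade_alignment_error")
    }
    tr <- stratified_split(y, split_fraction, seed)
    te <- setdiff(seq_along(y), tr)
    splits[[cn]] <- list(train = ids[tr], test = ids[te],
                         hash = hash_object(list(ids[tr], ids[te])))
    for (rn in names(tables)) {
      df <- tables[[rn]]
      fx <- as.matrix(df[, feature_columns(df), drop = FALSE])
      prep <- fit_prep_chain(fx[tr, , drop = FALSE], y[tr],
                             fx[te, , drop = FALSE], threshold_r,
                             k_selected, seed, smote_k)
      cellm <- run_cell_models(prep, y[te], specs)
      cellm <- cbind(data.frame(cohort = cn, region = rn,
                                stringsAsFactors = FALSE), cellm)
      rows[[paste(cn, rn)]] <- cellm
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  structure(grid, splits = splits, class = c("experiment_grid",
                                             class(grid)))
}

#' External validation: train on one cohort, test on another
#'
#' The scaler, correlation filter, importance selection, SMOTE balancing
#' and the model fits use the training cohort only; the test cohort is
#' transformed with frozen parameters and scored.
#'
#' @param train_tables,test_tables named per-region feature tables with
#'   identical feature names.
#' @param specs classifier specifications.
#' @param seed,threshold_r,k_selected,smote_k as in [run_grid()].
#' @return Data frame of per-region, per-model metrics.
#' @export
external_validate <- function(train_tables, test_tables,
                              specs = default_model_specs(), seed = 42L,
                              threshold_r = 0.8, k_selected = 30L,
                              smote_k = 5L) {
  rows <- list()
  for (rn in names(train_tables)) {
    tr_df <- train_tables[[rn]]
    te_df <- test_tables[[rn]]
    if (is.null(te_df))
      stop_subgrade(paste("test cohort lacks region", rn),
                    "subgrade_alignment_error")
    fc <- feature_columns(tr_df)
    if (!identical(sort(fc), sort(feature_columns(te_df))))
      stop_subgrade("feature names differ between cohorts",
                    "subgrade_schema_error")
    prep <- fit_prep_chain(as.matrix(tr_df[, fc, drop = FALSE]),
                           as.integer(tr_df$grade_label),
                           as.matrix(te_df[, fc, drop = FALSE]),
                           threshold_r, k_selected, seed, smote_k)
    cellm <- run_cell_models(prep, as.integer(te_df$grade_label), specs)
    rows[[rn]] <- cbind(data.frame(region = rn, stringsAsFactors = FALSE),
                        cellm)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Region-average AUC of an experiment grid
#'
#' Mean test AUC over all classifiers, per cohort and region.
#'
#' @param grid an [run_grid()] result (or compatible data frame).
#' @return Data frame cohort/region/AUC, sorted by AUC within cohort.
#' @export
region_average_auc <- function(grid) {
  ag <- aggregate(AUC ~ cohort + region, data = as.data.frame(grid), FUN = mean)
  ag[order(ag$cohort, -ag$AUC), ]
}

#' Classifier-average AUC (core/periphery averaging)
#'
#' Per classifier and cohort: the mean AUC over the core regions and the
#' mean over the periphery regions are averaged, `(core + periphery) / 2`,
#' the summary used to rank classifiers across sub-regions.
#'
#' @param grid an [run_grid()] result.
#' @return Data frame cohort/model/core_avg/periphery_avg/AUC.
#' @export
classifier_average_auc <- function(grid) {
  df <- as.data.frame(grid)
  df$kind <- ifelse(grepl("^core", df$region), "core",
                    ifelse(grepl("^periphery", df$region), "periphery",
                           "full"))
  sub <- df[df$kind != "full", ]
  ag <- aggregate(AUC ~ cohort + model + kind, data = sub, FUN = mean)
  wide <- merge(ag[ag$kind == "core", c("cohort", "model", "AUC")],
                ag[ag$kind == "periphery", c("cohort", "model", "AUC")],
                by = c("cohort", "model"), suffixes = c("_core", "_periphery"))
  wide$AUC <- (wide$AUC_core + wide$AUC_periphery) / 2
  names(wide)[names(wide) == "AUC_core"] <- "core_avg"
  names(wide)[names(wide) == "AUC_periphery"] <- "periphery_avg"
  wide[order(wide$cohort, -wide$AUC), ]
}
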