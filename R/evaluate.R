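#' Confusion matrix with high grade as the positive class
#'
#' @param y_true,y_pred equal-length binary vectors (1 = high grade).
#' @return A `confusion_matrix` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop_subgrade("need equal-length non-empty label vectors",
                  "subgrade_value_error")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L)))
    stop_subgrade("labels must be binary 0/1", "subgrade_label_error")
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_matrix")
}

#' Build a confusion matrix from counts
#' @param TP,FP,TN,FN non-negative counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  if (any(c(TP, FP, TN, FN) < 0) || TP + FP + TN + FN == 0)
    stop_subgrade("counts must be non-negative with positive total",
                  "subgrade_value_error")
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion> TP %d FP %d TN %d FN %d\n", x$TP, x$FP, x$TN,
              x$FN))
  invisible(x)
}

# Rank-based ROC area (equals the trapezoidal area under the empirical ROC
# with tie handling).
auc_scores <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Accuracy, sensitivity, specificity and AUC as percentages with 95%
#' Wald half-widths (`1.96 sqrt(p(1-p)/m)`, `m` = all samples for ACC,
#' positives for SEN, negatives for SPE); Matthews correlation coefficient
#' and F1 unitless; McNemar and chi-squared p-values. AUC is the
#' trapezoidal ROC area when continuous `scores` (with `y_true`) are
#' given, and the balanced accuracy `(SEN + SPE) / 2` for a label-only
#' predictor. MCC is 0 (flagged) when any marginal factor vanishes.
#'
#' @param cm a [confusion()] / [confusion_counts()] result.
#' @param scores optional continuous scores for the positive class.
#' @param y_true labels matching `scores` (required with `scores`).
#' @return A `metrics_report` list; percentages on the 0-100 scale.
#' @export
diagnostic_metrics <- function(cm, scores = NULL, y_true = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$TP + cm$FP + cm$TN + cm$FN
  npos <- cm$TP + cm$FN
  nneg <- cm$TN + cm$FP
  acc <- (cm$TP + cm$TN) / n
  sen <- if (npos > 0) cm$TP / npos else NA_real_
  spe <- if (nneg > 0) cm$TN / nneg else NA_real_
  if (!is.null(scores)) {
    if (is.null(y_true))
      stop_subgrade("y_true is required with scores", "subgrade_value_error")
    auc <- auc_scores(y_true, scores)
  } else {
    auc <- mean(c(sen, spe))
  }
  fac <- c(cm$TP + cm$FP, npos, nneg, cm$TN + cm$FN)
  mcc_flag <- any(fac == 0)
  mcc <- if (mcc_flag) 0 else
    (cm$TP * cm$TN - cm$FP * cm$FN) / sqrt(prod(fac))
  f1 <- if (2 * cm$TP + cm$FP + cm$FN > 0)
    2 * cm$TP / (2 * cm$TP + cm$FP + cm$FN) else 0
  wald <- function(p, m) if (!is.na(p) && m > 0)
    100 * 1.96 * sqrt(p * (1 - p) / m) else NA_real_
  structure(list(
    ACC = 100 * acc, ACC_ci = wald(acc, n),
    SEN = 100 * sen, SEN_ci = wald(sen, npos),
    SPE = 100 * spe, SPE_ci = wald(spe, nneg),
    AUC = 100 * auc,
    MCC = mcc, MCC_zero_flag = mcc_flag,
    F1 = f1,
    McN_p = mcnemar_p(cm),
    chi2_p = chi2_randomness_p(cm),
    n = n), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "ACC %.2f+-%.2f  SEN %.2f+-%.2f  SPE %.2f+-%.2f  AUC %.1f\n",
    x$ACC, x$ACC_ci, x$SEN, x$SEN_ci, x$SPE, x$SPE_ci, x$AUC))
  cat(sprintf("MCC %.2f  F1 %.2f  McN %.2f  chi2 %.2f  (n = %d)\n",
              x$MCC, x$F1, x$McN_p, x$chi2_p, x$n))
  invisible(x)
}

#' McNemar test on discordant errors
#'
#' Tests whether false negatives and false positives are balanced:
#' `chi2 = (FN - FP)^2 / (FN + FP)` on 1 df, without continuity
#' correction. Returns p = 1 when there are no discordant errors.
#'
#' @param cm a confusion matrix.
#' @return p-value in `[0, 1]`.
#' @export
mcnemar_p <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  disc <- cm$FN + cm$FP
  if (disc == 0) return(1)
  stat <- (cm$FN - cm$FP)^2 / disc
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Chi-squared test that predictions differ from randomness
#'
#' Two constructions are provided: `independence` (default) tests the 2x2
#' association between prediction and truth; `goodness_of_fit_uniform`
#' tests the predicted-label counts against a 50/50 split. Both use 1 df
#' without continuity correction; a small-sample warning attribute is
#' attached when any expected cell is below 1.
#'
#' @param cm a confusion matrix.
#' @param mode `"independence"` or `"goodness_of_fit_uniform"`.
#' @return p-value (attribute `small_sample` when expected counts < 1).
#' @export
chi2_randomness_p <- function(cm,
                              mode = c("independence",
                                       "goodness_of_fit_uniform")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  mode <- match.arg(mode)
  n <- cm$TP + cm$FP + cm$TN + cm$FN
  if (mode == "independence") {
    obs <- c(cm$TP, cm$FN, cm$FP, cm$TN)
    rows <- c(cm$TP + cm$FN, cm$FP + cm$TN) # truth margins
    cols <- c(cm$TP + cm$FP, cm$FN + cm$TN) # prediction margins
    expd <- c(rows[1] * cols[1], rows[1] * cols[2], rows[2] * cols[1],
              rows[2] * cols[2]) / n
    if (any(expd == 0)) return(structure(1, small_sample = TRUE))
    stat <- sum((obs - expd)^2 / expd)
  } else {
    pred1 <- cm$TP + cm$FP
    stat <- (pred1 - n / 2)^2 / (n / 2) + ((n - pred1) - n / 2)^2 / (n / 2)
    expd <- c(n / 2, n / 2)
  }
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (any(expd < 1)) attr(p, "small_sample") <- TRUE
  p
}

#' Compare biopsy grading with machine-learning prediction
#'
#' Scores the biopsy arm and the ML arm against nephrectomy histopathology
#' (the reference standard) on the same subjects. An indeterminate biopsy
#' is mapped to the opposite of the nephrectomy grade before scoring (so
#' it always counts as an error), the conservative convention for
#' non-contributory biopsies.
#'
#' @param records data frame with columns `subject_id`, `biopsy_grade`
#'   (`"low"`, `"high"` or `"indeterminate"`) and `nephrectomy_grade`
#'   (`"low"`/`"high"`, no missing values).
#' @param ml_predictions named vector (by subject id) or vector of 0/1 ML
#'   labels; optional named `ml_scores` for a score-based AUC.
#' @param ml_scores optional continuous ML scores.
#' @return List with `biopsy` and `ml` [diagnostic_metrics()] reports and
#'   the mapped biopsy labels.
#' @export
biopsy_compare <- function(records, ml_predictions, ml_scores = NULL) {
  need <- c("subject_id", "biopsy_grade", "nephrectomy_grade")
  if (!all(need %in% names(records)))
    stop_subgrade("records need subject_id, biopsy_grade, nephrectomy_grade",
                  "subgrade_schema_error")
  if (any(is.na(records$nephrectomy_grade)) ||
      !all(records$nephrectomy_grade %in% c("low", "high")))
    stop_subgrade("nephrectomy grade must be low/high for every record",
                  "subgrade_reference_error")
  truth <- as.integer(records$nephrectomy_grade == "high")
  bg <- records$biopsy_grade
  if (!all(bg %in% c("low", "high", "indeterminate")))
    stop_subgrade("biopsy_grade must be low/high/indeterminate",
                  "subgrade_value_error")
  biopsy <- ifelse(bg == "indeterminate", 1L - truth,
                   as.integer(bg == "high"))
  ml <- ml_predictions
  if (!is.null(names(ml))) ml <- ml[records$subject_id]
  ml <- as.integer(ml)
  if (length(ml) != nrow(records) || any(is.na(ml)))
    stop_subgrade("ml_predictions must cover every subject",
                  "subgrade_alignment_error")
  if (!is.null(ml_scores) && !is.null(names(ml_scores)))
    ml_scores <- ml_scores[records$subject_id]
  list(biopsy = diagnostic_metrics(confusion(truth, biopsy)),
       ml = diagnostic_metrics(confusion(truth, ml), scores = ml_scores,
                               y_true = if (is.null(ml_scores)) NULL else truth),
       biopsy_labels = biopsy, truth = truth)
}

#' Clinical covariate statistics by grade
#'
#' Student's t-test (equal variances) for continuous covariates against
#' the binary grade, a chi-squared association test for sex, and the
#' point-biserial correlation (Pearson correlation with the binary grade)
#' for each continuous covariate, with significance at p < 0.05.
#'
#' @param cohort_table data frame with `grade_label`, `age_years`, `sex`,
#'   `tumour_size_cm`, `tumour_volume_cm3` (a `cohort` object is accepted).
#' @return Data frame with variable, test, statistic, p-value, point-
#'   biserial r and significance.
#' @export
clinical_stats <- function(cohort_table) {
  df <- if (inherits(cohort_table, "cohort")) cohort_table$subjects else
    cohort_table
  g <- as.integer(df$grade_label)
  if (length(unique(g)) < 2L)
    stop_subgrade("cohort has a single grade class", "subgrade_test_error")
  rows <- list()
  for (v in c("age_years", "tumour_size_cm", "tumour_volume_cm3")) {
    tt <- t.test(df[[v]][g == 1], df[[v]][g == 0], var.equal = TRUE)
    rpb <- cor(df[[v]], g)
    rows[[v]] <- data.frame(variable = v, test = "t", statistic = unname(tt$statistic),
                            p_value = tt$p.value, rpb = rpb,
                            significant = tt$p.value < 0.05,
                            stringsAsFactors = FALSE)
  }
  tab <- table(df$sex, g)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  rows$sex <- data.frame(variable = "sex", test = "chi2",
                         statistic = unname(ct$statistic),
                         p_value = ct$p.value, rpb = NA_real_,
                         significant = ct$p.value < 0.05,
                         stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
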