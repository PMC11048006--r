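# Leakage-safe preprocessing chain: z-scoring, correlation filtering,
# gradient-boosting importance selection and SMOTE balancing. Every fit
# operation accepts the training partition only; test data are transformed
# with frozen training parameters.

#' Fit z-score scaling parameters on the training partition
#'
#' Records the per-feature training mean and standard deviation
#' (population, n-denominator convention by default). Constant features
#' (sd 0) are recorded and flagged; [zscore_apply()] maps them to 0.
#'
#' @param train_table numeric data frame or matrix of training features.
#' @param sample_sd use the sample (n-1) convention instead of the
#'   population convention.
#' @return A `scaler_params` list with `mu`, `sigma` and `constant` flags.
#' @export
zscore_fit <- function(train_table, sample_sd = FALSE) {
  x <- as.matrix(train_table)
  if (nrow(x) < 1L)
    stop_subgrade("empty training table", "subgrade_empty_error")
  mu <- colMeans(x)
  sigma <- apply(x, 2, function(v) {
    s2 <- mean((v - mean(v))^2)
    if (sample_sd) s2 <- s2 * length(v) / max(1, length(v) - 1)
    sqrt(s2)
  })
  structure(list(mu = mu, sigma = sigma, constant = sigma == 0,
                 sample_sd = sample_sd),
            class = "scaler_params")
}

#' Apply fitted z-score parameters to a table
#'
#' @param params a [zscore_fit()] result.
#' @param table data with the same feature columns.
#' @return Matrix of standardised values; constant training features map
#'   to 0 (a `constant_features` attribute lists them).
#' @export
zscore_apply <- function(params, table) {
  x <- as.matrix(table)
  if (!identical(colnames(x), names(params$mu)))
    x <- x[, names(params$mu), drop = FALSE]
  z <- sweep(x, 2, params$mu)
  sig <- ifelse(params$constant, 1, params$sigma)
  z <- sweep(z, 2, sig, `/`)
  z[, params$constant] <- 0
  attr(z, "constant_features") <- names(params$mu)[params$constant]
  z
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_subgrade("need two equal-length vectors of length >= 3",
                  "subgrade_value_error")
  if (sd(x) == 0 || sd(y) == 0)
    stop_subgrade("correlation undefined for constant input",
                  "subgrade_value_error")
  cor(x, y)
}

#' Redundancy filter: drop one of every feature pair with |r| > threshold
#'
#' Greedy scan over features in canonical (column) order on the training
#' data only: when a pair exceeds the threshold the later-ordered feature
#' is dropped, so the surviving set has all pairwise |r| <= threshold and
#' the result is deterministic. Constant features are kept (their
#' correlation is undefined and they carry no redundancy).
#'
#' @param train_table numeric training feature table (>= 2 columns).
#' @param threshold_r absolute-correlation threshold (default 0.8).
#' @return A `selection_report` with `kept`, `dropped_by_correlation`
#'   (feature, partner, r) and `threshold_r`.
#' @export
correlation_filter <- function(train_table, threshold_r = 0.8) {
  x <- as.matrix(train_table)
  if (ncol(x) < 2L)
    stop_subgrade("need at least 2 features", "subgrade_value_error")
  nm <- colnames(x)
  sds <- apply(x, 2, sd)
  cm <- suppressWarnings(cor(x))
  cm[!is.finite(cm)] <- 0 # constant features correlate with nothing
  dropped <- logical(ncol(x))
  rec <- list()
  for (i in seq_len(ncol(x) - 1L)) {
    if (dropped[i]) next
    for (j in seq((i + 1L), ncol(x))) {
      if (dropped[j]) next
      if (abs(cm[i, j]) > threshold_r) {
        dropped[j] <- TRUE
        rec[[length(rec) + 1L]] <- data.frame(
          feature = nm[j], partner = nm[i], r = cm[i, j],
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(kept = nm[!dropped],
                 dropped_by_correlation =
                   if (length(rec)) do.call(rbind, rec)
                   else data.frame(feature = character(0),
                                   partner = character(0), r = numeric(0)),
                 threshold_r = threshold_r),
            class = "selection_report")
}

#' Importance-based feature selection with gradient-boosted trees
#'
#' Fits an XGBoost classifier on the (already correlation-filtered)
#' training data and keeps the `k` features with the highest gain
#' importance. Features the booster never uses rank after used ones, in
#' canonical column order; deterministic under `seed` (single thread).
#'
#' @param train_x numeric training feature matrix/data frame.
#' @param train_y binary labels (1 = high grade).
#' @param k number of features to keep; clamped (with a warning) to the
#'   number available.
#' @param seed integer RNG seed.
#' @param nrounds boosting rounds for the ranking model.
#' @return A `selection_report` with `kept` (ordered by importance) and
#'   `importance` (data frame feature/gain).
#' @export
importance_select <- function(train_x, train_y, k = 30L, seed = 42L,
                              nrounds = 50L) {
  x <- as.matrix(train_x)
  y <- as.numeric(train_y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop_subgrade("labels must be binary 0/1 with both classes present",
                  "subgrade_label_error")
  if (k < 1L)
    stop_subgrade("k must be >= 1", "subgrade_value_error")
  if (k > ncol(x)) {
    warning(sprintf("k = %d exceeds %d available features; clamped", k,
                    ncol(x)))
    k <- ncol(x)
  }
  booster <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                  nthread = 1L, seed = as.integer(seed)),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
    nrounds = nrounds, verbose = 0))
  imp <- xgboost::xgb.importance(model = booster)
  gain <- setNames(rep(0, ncol(x)), colnames(x))
  if (!is.null(imp) && nrow(imp) > 0)
    gain[imp$Feature] <- imp$Gain
  ord <- order(-gain, seq_along(gain)) # ties: canonical column order
  kept <- colnames(x)[ord[seq_len(k)]]
  structure(list(kept = kept,
                 importance = data.frame(feature = colnames(x)[ord],
                                         gain = gain[ord],
                                         stringsAsFactors = FALSE),
                 k_selected = k),
            class = "selection_report")
}

#' SMOTE: synthetic minority oversampling
#'
#' Oversamples the minority class to the majority count. Each synthetic
#' point is `x_i + lambda * (x_nn - x_i)` with `x_nn` one of the `k`
#' Euclidean nearest minority neighbours of a minority point `x_i` and
#' `lambda ~ Uniform(0, 1)`, so synthetic points lie on segments between
#' same-class originals. Originals are preserved; deterministic under
#' `seed`. Apply to the training partition only.
#'
#' @param train_x numeric training feature matrix.
#' @param train_y binary labels (1 = high grade).
#' @param k_neighbours neighbours considered per minority point (clamped,
#'   with a warning, to minority size minus 1).
#' @param seed integer RNG seed.
#' @return List `x` (matrix), `y` (labels) with equal class counts and a
#'   `synthetic` logical marker per row.
#' @export
smote <- function(train_x, train_y, k_neighbours = 5L, seed = 42L) {
  x <- as.matrix(train_x)
  y <- as.integer(train_y)
  if (!all(y %in% c(0L, 1L)))
    stop_subgrade("labels must be binary 0/1", "subgrade_label_error")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == n0)
    return(list(x = x, y = y, synthetic = rep(FALSE, length(y))))
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  mi <- which(y == minority)
  if (length(mi) < 2L)
    stop_subgrade("minority class needs at least 2 samples",
                  "subgrade_balance_error")
  if (k_neighbours > length(mi) - 1L) {
    warning(sprintf("k_neighbours clamped to %d", length(mi) - 1L))
    k_neighbours <- length(mi) - 1L
  }
  xm <- x[mi, , drop = FALSE]
  dmat <- as.matrix(dist(xm))
  diag(dmat) <- Inf
  ord <- apply(dmat, 1, function(r) order(r)[seq_len(k_neighbours)])
  nn <- if (k_neighbours == 1L) matrix(ord, ncol = 1L) else t(ord)
  syn <- with_seed(seed, {
    base <- rep_len(seq_along(mi), need) # cycle through minority points
    pick <- nn[cbind(base, sample.int(k_neighbours, need, replace = TRUE))]
    lam <- runif(need)
    xm[base, , drop = FALSE] +
      lam * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  })
  list(x = rbind(x, syn),
       y = c(y, rep(minority, need)),
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, need)))
}
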