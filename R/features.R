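#' Fixed-bin-width intensity discretisation
#'
#' Maps masked intensities to integer grey levels
#' `floor((x - min_mask) / bin_width) + 1` with the minimum taken over the
#' masked voxels only (min-anchored binning, so shifting all intensities by
#' a constant never changes the levels). Voxels outside the mask get level
#' 0. A constant region yields a single level (`Ng = 1`), which is valid.
#'
#' @param image an [image_volume()].
#' @param mask a [voxel_mask()] on the same grid, non-empty.
#' @param bin_width positive bin width in intensity units (default 20 HU).
#' @return A `discretized_volume`: integer array of levels with attributes
#'   `Ng`, `bin_width` and `min_intensity`.
#' @export
discretize <- function(image, mask, bin_width = 20) {
  check_aligned(image, mask)
  if (bin_width <= 0)
    stop_subgrade("bin_width must be > 0", "subgrade_value_error")
  m <- as.logical(mask)
  if (!any(m))
    stop_subgrade("mask is empty", "subgrade_empty_error")
  lev <- array(0L, dim(image))
  x <- as.numeric(image)[m]
  lo <- min(x)
  lev[m] <- as.integer(floor((x - lo) / bin_width)) + 1L
  structure(lev, Ng = max(lev), bin_width = bin_width, min_intensity = lo,
            spacing = spacing(image), class = "discretized_volume")
}

disc_levels <- function(disc) {
  l <- as.integer(disc)
  dim(l) <- dim(disc)
  l
}

# Histogram probabilities over levels 1..Ng within the mask.
disc_prob <- function(disc) {
  l <- as.integer(disc)
  l <- l[l > 0L]
  tabulate(l, attr(disc, "Ng")) / length(l)
}

#' First-order intensity statistics (19 features)
#'
#' Energy, total energy, entropy, minimum, 10th/90th percentiles, maximum,
#' mean, median, interquartile range, range, mean absolute deviation, robust
#' MAD (over the 10-90 percentile band), root mean squared, standard
#' deviation, skewness, kurtosis (non-excess), variance and uniformity.
#' Entropy and uniformity use the discretised histogram; moments use the
#' population (n-denominator) convention. Degenerate (constant) regions
#' return the defined limits: variance 0, skewness and kurtosis 0,
#' entropy 0, uniformity 1.
#'
#' @inheritParams discretize
#' @param disc optional [discretize()] result (recomputed if missing).
#' @return Named numeric vector of 19 features.
#' @export
first_order_features <- function(image, mask, disc = NULL) {
  check_aligned(image, mask)
  m <- as.logical(mask)
  x <- as.numeric(image)[m]
  if (length(x) < 2L)
    stop_subgrade("need at least 2 masked voxels", "subgrade_empty_error")
  if (is.null(disc)) disc <- discretize(image, mask)
  p <- disc_prob(disc)
  p <- p[p > 0]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  band <- x[x >= q[1] & x <= q[4]]
  voxvol <- prod(spacing(image))
  c(Energy = sum(x^2),
    TotalEnergy = voxvol * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = mu,
    Median = median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(band)) mean(abs(band - mean(band))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    StandardDeviation = sqrt(m2),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}
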