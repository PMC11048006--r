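# Texture-matrix feature classes. All matrices are built by compiled
# counters over the 13 unique distance-1 directions (GLCM/GLRLM, feature
# values averaged over directions), 26-connectivity (GLSZM zones, GLDM
# dependence, NGTDM neighbourhoods). Degenerate cases take their defined
# limits (e.g. GLCM correlation is 1 when a marginal variance vanishes) so
# every feature is finite on any non-empty region.

check_disc <- function(disc) {
  if (!inherits(disc, "discretized_volume"))
    stop_subgrade("expected a discretized_volume (see discretize())",
                  "subgrade_value_error")
  if (attr(disc, "Ng") < 1L || !any(disc > 0L))
    stop_subgrade("discretised region is empty", "subgrade_empty_error")
  invisible(TRUE)
}

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Grey-level co-occurrence matrix features (24 features)
#'
#' Co-occurrences are counted for the 13 unique 3D unit offsets at
#' Chebyshev distance 1, symmetrised and normalised per offset; each
#' feature is computed per offset and averaged over the 13 offsets.
#'
#' @param disc a [discretize()] result.
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(disc) {
  check_disc(disc)
  ng <- attr(disc, "Ng")
  counts <- .glcm_counts(disc_levels(disc), dim(disc), ng)
  acc <- NULL
  used <- 0L
  for (d in 1:13) {
    tab <- matrix(counts[, , d], ng, ng)
    tot <- sum(tab)
    if (tot == 0) next # no valid pairs along this offset
    f <- glcm_features_one(tab / tot, ng)
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1L
  }
  if (used == 0L) # single isolated voxel: all offsets empty
    return(glcm_features_one(matrix(1, 1, 1), 1))
  acc / used
}

glcm_features_one <- function(p, ng) {
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal / cross-diagonal marginals
  k_sum <- 2:(2 * ng)
  pxy_sum <- vapply(k_sum, function(k) sum(p[i + j == k]), numeric(1))
  k_diff <- 0:(ng - 1)
  pxy_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  autoc <- sum(i * j * p)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sigx > 0 && sigy > 0)
    (autoc - mux * muy) / (sigx * sigy) else 1
  da <- sum(k_diff * pxy_diff)
  hx <- -sum(xlog2(px))
  hy <- -sum(xlog2(py))
  hxy <- -sum(xlog2(p))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * ifelse(pxpy > 0, log2(pxpy), 0))
  hxy2 <- -sum(xlog2(pxpy))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  # MCC: second-largest eigenvalue of Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
  mcc <- 1
  nz <- which(px > 0)
  if (length(nz) > 1) {
    psub <- p[nz, nz, drop = FALSE]
    pxs <- px[nz]
    pys <- py[nz]
    q <- matrix(0, length(nz), length(nz))
    for (a in seq_along(nz))
      for (b in seq_along(nz))
        q[a, b] <- sum(psub[a, ] * psub[b, ] / (pxs[a] * pys))
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, ev[2]))
  }
  c(Autocorrelation = autoc,
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = contrast,
    Correlation = correlation,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(xlog2(pxy_diff)),
    DifferenceVariance = sum((k_diff - da)^2 * pxy_diff),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p[i != j] / (i[i != j] - j[i != j])^2),
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * pxy_sum),
    SumEntropy = -sum(xlog2(pxy_sum)),
    SumSquares = sum((i - mux)^2 * p),
    MCC = mcc)
}

#' Grey-level run-length matrix features (16 features)
#'
#' Runs are maximal same-level straight segments along each of the 13
#' unique 3D directions; features are computed per direction and averaged.
#'
#' @param disc a [discretize()] result.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(disc) {
  check_disc(disc)
  ng <- attr(disc, "Ng")
  counts <- .glrlm_counts(disc_levels(disc), dim(disc), ng)
  np <- sum(disc > 0L)
  acc <- NULL
  for (d in 1:13) {
    tab <- matrix(counts[, , d], ng)
    f <- glrlm_features_one(tab, ng, np)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / 13
}

glrlm_features_one <- function(tab, ng, np) {
  nr <- sum(tab)
  lmax <- ncol(tab)
  iv <- seq_len(ng)
  jv <- seq_len(lmax)
  ri <- rowSums(tab)
  rj <- colSums(tab)
  p <- tab / nr
  mu_i <- sum(iv * rowSums(p))
  mu_j <- sum(jv * colSums(p))
  c(ShortRunEmphasis = sum(rj / jv^2) / nr,
    LongRunEmphasis = sum(rj * jv^2) / nr,
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    RunLengthNonUniformity = sum(rj^2) / nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(outer((iv - mu_i)^2, rep(1, lmax)) * p),
    RunVariance = sum(outer(rep(1, ng), (jv - mu_j)^2) * p),
    RunEntropy = -sum(xlog2(p)),
    LowGrayLevelRunEmphasis = sum(ri / iv^2) / nr,
    HighGrayLevelRunEmphasis = sum(ri * iv^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(outer(1 / iv^2, 1 / jv^2) * tab) / nr,
    ShortRunHighGrayLevelEmphasis = sum(outer(iv^2, 1 / jv^2) * tab) / nr,
    LongRunLowGrayLevelEmphasis = sum(outer(1 / iv^2, jv^2) * tab) / nr,
    LongRunHighGrayLevelEmphasis = sum(outer(iv^2, jv^2) * tab) / nr)
}

#' Grey-level size-zone matrix features (16 features)
#'
#' Zones are 26-connected components of equal grey level; the size-zone
#' matrix counts zones by (level, size). Single matrix (no directionality).
#'
#' @param disc a [discretize()] result.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(disc) {
  check_disc(disc)
  ng <- attr(disc, "Ng")
  zones <- .glszm_zones(disc_levels(disc), dim(disc))
  np <- sum(disc > 0L)
  nz <- nrow(zones)
  iv <- zones[, 1]
  sv <- zones[, 2]
  p <- rep(1 / nz, nz)
  mu_i <- sum(iv * p)
  mu_s <- sum(sv * p)
  # grey-level and size marginal sums of counts
  gl_counts <- tapply(rep(1, nz), factor(iv, levels = seq_len(ng)), sum,
                      default = 0)
  sz_counts <- table(sv)
  pz <- as.numeric(table(paste(iv, sv))) / nz
  c(SmallAreaEmphasis = mean(1 / sv^2),
    LargeAreaEmphasis = mean(sv^2),
    GrayLevelNonUniformity = sum(gl_counts^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gl_counts^2) / nz^2,
    SizeZoneNonUniformity = sum(as.numeric(sz_counts)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(as.numeric(sz_counts)^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum((iv - mu_i)^2 * p),
    ZoneVariance = sum((sv - mu_s)^2 * p),
    ZoneEntropy = -sum(xlog2(pz)),
    LowGrayLevelZoneEmphasis = mean(1 / iv^2),
    HighGrayLevelZoneEmphasis = mean(iv^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (iv^2 * sv^2)),
    SmallAreaHighGrayLevelEmphasis = mean(iv^2 / sv^2),
    LargeAreaLowGrayLevelEmphasis = mean(sv^2 / iv^2),
    LargeAreaHighGrayLevelEmphasis = mean(iv^2 * sv^2))
}

#' Grey-level dependence matrix features (14 features)
#'
#' For each in-region voxel, the dependence size is one plus the number of
#' 26-neighbours (distance 1) whose level differs by at most
#' `alpha` (default 0). The matrix counts voxels by (level, dependence).
#'
#' @param disc a [discretize()] result.
#' @param alpha dependence tolerance on the level difference.
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(disc, alpha = 0L) {
  check_disc(disc)
  ng <- attr(disc, "Ng")
  tab <- .gldm_counts(disc_levels(disc), dim(disc), ng, as.integer(alpha))
  nz <- sum(tab)
  iv <- seq_len(ng)
  jv <- seq_len(ncol(tab)) # dependence size = dependent neighbours + 1
  p <- tab / nz
  ri <- rowSums(tab)
  rj <- colSums(tab)
  mu_i <- sum(iv * rowSums(p))
  mu_j <- sum(jv * colSums(p))
  c(SmallDependenceEmphasis = sum(rj / jv^2) / nz,
    LargeDependenceEmphasis = sum(rj * jv^2) / nz,
    GrayLevelNonUniformity = sum(ri^2) / nz,
    DependenceNonUniformity = sum(rj^2) / nz,
    DependenceNonUniformityNormalized = sum(rj^2) / nz^2,
    GrayLevelVariance = sum(outer((iv - mu_i)^2, rep(1, length(jv))) * p),
    DependenceVariance = sum(outer(rep(1, ng), (jv - mu_j)^2) * p),
    DependenceEntropy = -sum(xlog2(p)),
    LowGrayLevelEmphasis = sum(ri / iv^2) / nz,
    HighGrayLevelEmphasis = sum(ri * iv^2) / nz,
    SmallDependenceLowGrayLevelEmphasis =
      sum(outer(1 / iv^2, 1 / jv^2) * tab) / nz,
    SmallDependenceHighGrayLevelEmphasis =
      sum(outer(iv^2, 1 / jv^2) * tab) / nz,
    LargeDependenceLowGrayLevelEmphasis =
      sum(outer(1 / iv^2, jv^2) * tab) / nz,
    LargeDependenceHighGrayLevelEmphasis =
      sum(outer(iv^2, jv^2) * tab) / nz)
}

#' Neighbouring grey-tone difference matrix features (5 features)
#'
#' Coarseness, contrast, busyness, complexity and strength from the
#' distance-1 (26-neighbour) grey-tone difference statistics. Degenerate
#' denominators take the defined limits (coarseness is capped at 1e6 as in
#' standard extractors; contrast is 0 for a single grey level).
#'
#' @param disc a [discretize()] result.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(disc) {
  check_disc(disc)
  ng <- attr(disc, "Ng")
  st <- .ngtdm_stats(disc_levels(disc), dim(disc), ng)
  ni <- st[, 1]
  si <- st[, 2]
  nv <- sum(ni)
  if (nv == 0) # isolated voxels only: no neighbourhoods
    return(c(Coarseness = 1e6, Contrast = 0, Busyness = 0, Complexity = 0,
             Strength = 0))
  pi_ <- ni / nv
  iv <- seq_len(ng)
  ngp <- sum(pi_ > 0)
  val <- which(pi_ > 0)
  coars_den <- sum(pi_ * si)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contrast <- 0
  busy_den <- 0
  complexity <- 0
  strength_num <- 0
  if (ngp > 1) {
    for (a in val)
      for (b in val) {
        contrast <- contrast + pi_[a] * pi_[b] * (a - b)^2
        busy_den <- busy_den + abs(a * pi_[a] - b * pi_[b])
        complexity <- complexity +
          abs(a - b) * (pi_[a] * si[a] + pi_[b] * si[b]) / (pi_[a] + pi_[b])
        strength_num <- strength_num + (pi_[a] + pi_[b]) * (a - b)^2
      }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(si) / nv
  }
  c(Coarseness = min(coarseness, 1e6),
    Contrast = contrast,
    Busyness = if (busy_den > 0) coars_den / busy_den else 0,
    Complexity = complexity / nv,
    Strength = if (sum(si) > 0) strength_num / sum(si) else 0)
}
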