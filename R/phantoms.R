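#' Configuration for one synthetic CT tumour phantom
#'
#' Describes an ellipsoidal tumour embedded in a uniform background
#' (default -50 HU): the binary mask is the discretised ellipsoid, and the
#' intensity field is a Gaussian random field with separate first-order and
#' correlation structure for the inner core (the deepest `core_fraction` of
#' the tumour volume) and the outer shell, plus independent acquisition
#' noise. Every output is a pure function of the configuration (which
#' includes the seed).
#'
#' @param tumour_axes_mm ellipsoid semi-axes (mm), length 3.
#' @param spacing_mm voxel spacing (mm), length 3.
#' @param grid_shape voxels per axis; `NULL` fits the ellipsoid plus a
#'   5-voxel pad.
#' @param class_label 0 (low grade) or 1 (high grade); carried as metadata.
#' @param core_texture numeric `(mean HU, sd HU, correlation length mm)` of
#'   the core field.
#' @param periphery_texture same triple for the outer shell.
#' @param noise_sd additive white acquisition-noise sd (HU).
#' @param core_fraction volume fraction given the core texture (default
#'   0.5: the inner half of the tumour volume).
#' @param background_hu intensity outside the tumour.
#' @param seed integer RNG seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(tumour_axes_mm, spacing_mm = c(1, 1, 1),
                           grid_shape = NULL, class_label = 0L,
                           core_texture = c(40, 15, 3),
                           periphery_texture = c(25, 15, 3),
                           noise_sd = 10, core_fraction = 0.5,
                           background_hu = -50, seed = 42L) {
  spacing_mm <- check_spacing(spacing_mm)
  tumour_axes_mm <- as.numeric(tumour_axes_mm)
  if (length(tumour_axes_mm) != 3L || any(tumour_axes_mm <= 0))
    stop_subgrade("tumour_axes_mm must be 3 positive semi-axes",
                  "subgrade_value_error")
  if (any(tumour_axes_mm <= 2 * max(spacing_mm)))
    stop_subgrade("semi-axes must exceed twice the largest voxel spacing",
                  "subgrade_value_error")
  check_texture <- function(tx, what) {
    if (length(tx) != 3L || tx[2] < 0 || tx[3] < 0)
      stop_subgrade(paste(what, "must be (mean, sd >= 0, corr length >= 0)"),
                    "subgrade_value_error")
    as.numeric(tx)
  }
  core_texture <- check_texture(core_texture, "core_texture")
  periphery_texture <- check_texture(periphery_texture, "periphery_texture")
  if (noise_sd < 0)
    stop_subgrade("noise_sd must be >= 0", "subgrade_value_error")
  if (core_fraction <= 0 || core_fraction >= 1)
    stop_subgrade("core_fraction must be in (0, 1)", "subgrade_value_error")
  pad <- 5L
  need <- as.integer(2 * ceiling(tumour_axes_mm / spacing_mm) + 2L * pad + 1L)
  if (is.null(grid_shape)) grid_shape <- need
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < need))
    stop_subgrade(sprintf(
      "grid_shape must be at least %s to hold the ellipsoid plus a %d-voxel pad",
      paste(need, collapse = "x"), pad), "subgrade_size_error")
  structure(list(tumour_axes_mm = tumour_axes_mm, spacing_mm = spacing_mm,
                 grid_shape = grid_shape, class_label = as.integer(class_label),
                 core_texture = core_texture,
                 periphery_texture = periphery_texture, noise_sd = noise_sd,
                 core_fraction = core_fraction, background_hu = background_hu,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

gaussian_kernel_1d <- function(sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array, sigma given in voxels per axis.
gauss_smooth3d <- function(arr, sigma_vox, mode = 0L) {
  d <- dim(arr)
  out <- as.numeric(arr)
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[ax])
    if (length(k) > 1L) out <- .conv3d_axis(out, d, k, ax - 1L, mode)
  }
  dim(out) <- d
  out
}

# Standardised Gaussian random field: smoothed white noise rescaled to unit
# sd over the grid (zero if the smoothed field is constant).
random_field <- function(grid_shape, sigma_vox) {
  w <- array(rnorm(prod(grid_shape)), grid_shape)
  f <- gauss_smooth3d(w, sigma_vox)
  s <- sd(f)
  if (s < .Machine$double.eps) return(array(0, grid_shape))
  (f - mean(f)) / s
}

#' Generate a synthetic CT phantom
#'
#' Realises a [phantom_config()]: the mask is the discretised ellipsoid
#' centred in the grid, and the image carries the core texture triple on the
#' deepest `core_fraction` of the tumour volume, the periphery triple on the
#' remaining shell, and white Gaussian acquisition noise everywhere.
#' Identical configurations (including seed) give bit-identical output; the
#' mask never depends on the seed.
#'
#' @param config a [phantom_config()].
#' @return List with `image` ([image_volume()]) and `mask` ([voxel_mask()]).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape
  sp <- config$spacing_mm
  centre <- (gs + 1) / 2 * sp
  ax <- seq_len(gs[1]) * sp[1]
  ay <- seq_len(gs[2]) * sp[2]
  az <- seq_len(gs[3]) * sp[3]
  u2 <- ((ax - centre[1]) / config$tumour_axes_mm[1])^2
  v2 <- ((ay - centre[2]) / config$tumour_axes_mm[2])^2
  w2 <- ((az - centre[3]) / config$tumour_axes_mm[3])^2
  ell <- outer(outer(u2, v2, `+`), w2, `+`) <= 1
  if (!any(ell))
    stop_subgrade("discretised ellipsoid is empty", "subgrade_size_error")
  border <- c(ell[1, , ], ell[gs[1], , ], ell[, 1, ], ell[, gs[2], ],
              ell[, , 1], ell[, , gs[3]])
  if (any(border))
    stop_subgrade("ellipsoid touches the grid border; enlarge grid_shape",
                  "subgrade_size_error")
  mask <- voxel_mask(ell, sp)
  core <- extract_core(mask, config$core_fraction)
  img <- with_seed(config$seed, {
    out <- array(config$background_hu, gs)
    ct <- config$core_texture
    pt <- config$periphery_texture
    fc <- ct[1] + ct[2] * random_field(gs, ct[3] / sp)
    fp <- pt[1] + pt[2] * random_field(gs, pt[3] / sp)
    shell <- as.logical(mask) & !as.logical(core)
    out[shell] <- fp[shell]
    out[as.logical(core)] <- fc[as.logical(core)]
    if (config$noise_sd > 0)
      out <- out + array(rnorm(prod(gs), sd = config$noise_sd), gs)
    out
  })
  list(image = image_volume(img, sp), mask = mask)
}

#' Per-class clinical covariate parameters
#'
#' Mean and standard deviation of age (years) and maximum tumour diameter
#' (cm) per grade class, with the male fraction per class, for the two
#' study populations this package emulates: a ~187-patient institutional
#' cohort and a ~204-patient public kidney-tumour cohort.
#'
#' @param cohort `"cohort1"` or `"cohort2"`.
#' @return A list of per-class parameters used by [generate_cohort()].
#' @export
default_clinical_params <- function(cohort = c("cohort1", "cohort2")) {
  cohort <- match.arg(cohort)
  if (cohort == "cohort1")
    list(age_mean = c(low = 59.05, high = 64), age_sd = c(low = 12.28, high = 9.40),
         size_mean = c(low = 4.32, high = 6.03), size_sd = c(low = 2.02, high = 3.23),
         male_frac = c(low = 49 / 80, high = 74 / 107),
         volume_sdlog = 0.45)
  else
    list(age_mean = c(low = 57.17, high = 63.68), age_sd = c(low = 12.67, high = 11.14),
         size_mean = c(low = 3.89, high = 6.81), size_sd = c(low = 2.16, high = 3.55),
         male_frac = c(low = 77 / 127, high = 57 / 77),
         volume_sdlog = 0.45)
}

#' Default phantom texture parameters per grade class
#'
#' The class signal lives in the tumour core only: low- and high-grade
#' cores differ in mean attenuation (45 vs 59 HU) and texture amplitude
#' (sd 16 vs 22 HU), while the peripheral shell shares one texture across
#' classes. Between-subject variability is asymmetric by design: core
#' means jitter little (sd 2 HU), so core separability is limited by
#' texture-sampling noise and grows with sub-region volume, whereas
#' peripheral means vary widely between subjects (sd 10 HU, emulating
#' class-independent differences in vascularity and necrosis), which
#' dilutes whole-tumour separability. Geometry is drawn independently of
#' class, so by construction every discriminative voxel sits in the inner
#' half of the tumour volume.
#'
#' @return A list of generator parameters used by [generate_cohort()].
#' @export
default_phantom_params <- function() {
  list(core_texture = list(low = c(45, 16, 3), high = c(63, 16, 3)),
       periphery_texture = c(54, 18, 3),
       core_jitter_sd = 2,       # between-subject jitter on core means (HU)
       periphery_jitter_sd = 15, # between-subject jitter on shell means (HU)
       periphery_sd_jitter = 4,  # between-subject jitter on shell sd (HU)
       noise_sd = 12,
       radius_range_mm = c(7, 11),
       anisotropy_range = c(0.85, 1.15),
       spacing_mm = c(1, 1, 1),
       core_fraction = 0.5)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
  }
  pmin(pmax(out, lower), upper)
}

#' Generate a synthetic study cohort
#'
#' Draws grade labels Bernoulli(`prevalence_high`), clinical covariates from
#' per-class truncated normals (age in [18, 100] years, size > 0.5 cm), a
#' tumour volume coupled to size through an ellipsoid relation with
#' lognormal scatter, and one [phantom_config()] per subject whose core
#' texture carries the class signal. Deterministic under `seed`.
#'
#' @param n number of subjects (>= 4).
#' @param prevalence_high probability of the high-grade class, in (0, 1).
#' @param clinical_params per-class covariate parameters, see
#'   [default_clinical_params()].
#' @param phantom_params generator texture/geometry parameters, see
#'   [default_phantom_params()].
#' @param seed integer RNG seed.
#' @param id_prefix prefix for subject identifiers.
#' @details At least 3 subjects per class are guaranteed: if the Bernoulli
#'   draw leaves a class short, the needed labels are flipped at random
#'   (negligible at study sizes, but it keeps tiny smoke-test cohorts
#'   usable by the split/SMOTE chain).
#' @return A `cohort` list: `subjects` (data frame with subject_id,
#'   grade_label, age_years, sex, tumour_size_cm, tumour_volume_cm3) and
#'   `configs` (named list of [phantom_config()] per subject).
#' @export
generate_cohort <- function(n, prevalence_high,
                            clinical_params = default_clinical_params("cohort1"),
                            phantom_params = default_phantom_params(),
                            seed = 42L, id_prefix = "S") {
  if (n < 4L)
    stop_subgrade("need at least 4 subjects", "subgrade_value_error")
  if (prevalence_high <= 0 || prevalence_high >= 1)
    stop_subgrade("prevalence_high must be in (0, 1)", "subgrade_value_error")
  cp <- clinical_params
  pp <- phantom_params
  if (any(c(cp$age_sd, cp$size_sd) < 0))
    stop_subgrade("clinical sds must be >= 0", "subgrade_parameter_error")
  with_seed(seed, {
    label <- rbinom(n, 1L, prevalence_high)
    # guarantee a workable cohort: at least 3 subjects per class (the
    # Bernoulli draw is left untouched otherwise; at study sizes the
    # adjustment has vanishing probability)
    min_per_class <- if (n >= 6L) 3L else 2L
    for (k in c(0L, 1L)) {
      short <- min_per_class - sum(label == k)
      if (short > 0L) {
        flip <- sample(which(label != k), short)
        label[flip] <- k
      }
    }
    cls <- ifelse(label == 1L, "high", "low")
    age <- numeric(n)
    size <- numeric(n)
    sex <- character(n)
    for (k in c("low", "high")) {
      i <- which(cls == k)
      if (!length(i)) next
      age[i] <- rnorm_trunc(length(i), cp$age_mean[k], cp$age_sd[k], 18, 100)
      size[i] <- rnorm_trunc(length(i), cp$size_mean[k], cp$size_sd[k], 0.5, Inf)
      sex[i] <- ifelse(runif(length(i)) < cp$male_frac[k], "male", "female")
    }
    volume <- pi / 6 * size^3 * exp(rnorm(n, 0, cp$volume_sdlog))
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    r0 <- runif(n, pp$radius_range_mm[1], pp$radius_range_mm[2])
    aniso <- matrix(runif(3 * n, pp$anisotropy_range[1],
                          pp$anisotropy_range[2]), ncol = 3)
    core_jit <- rnorm(n, 0, pp$core_jitter_sd)
    peri_jit <- rnorm(n, 0, pp$periphery_jitter_sd)
    peri_sd_jit <- rnorm(n, 0, pp$periphery_sd_jitter %||% 0)
    ids <- sprintf("%s%03d", id_prefix, seq_len(n))
    configs <- vector("list", n)
    for (i in seq_len(n)) {
      ct <- pp$core_texture[[cls[i]]]
      ct[1] <- ct[1] + core_jit[i]
      pt <- pp$periphery_texture
      pt[1] <- pt[1] + peri_jit[i]
      pt[2] <- max(1, pt[2] + peri_sd_jit[i])
      configs[[i]] <- phantom_config(
        tumour_axes_mm = r0[i] * aniso[i, ],
        spacing_mm = pp$spacing_mm,
        class_label = label[i],
        core_texture = ct, periphery_texture = pt,
        noise_sd = pp$noise_sd, core_fraction = pp$core_fraction,
        seed = sub_seeds[i])
    }
    names(configs) <- ids
    subjects <- data.frame(subject_id = ids, grade_label = label,
                           age_years = age, sex = sex,
                           tumour_size_cm = size, tumour_volume_cm3 = volume,
                           stringsAsFactors = FALSE)
    structure(list(subjects = subjects, configs = configs, seed = seed),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d high-grade), seed %d\n",
              nrow(x$subjects), sum(x$subjects$grade_label), x$seed))
  invisible(x)
}

#' Write a cohort table as CSV
#' @param cohort a `cohort` or its `subjects` data frame.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(cohort, path) {
  df <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#' @param path CSV path.
#' @return The subjects data frame.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "grade_label", "age_years", "sex",
            "tumour_size_cm", "tumour_volume_cm3")
  if (!all(need %in% names(df)))
    stop_subgrade("cohort table is missing required columns",
                  "subgrade_schema_error")
  df
}
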