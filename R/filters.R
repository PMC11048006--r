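# Intensity and spatial filter images. Each filter maps the original image
# to a derived image on the same grid; the texture battery is then
# recomputed on the derived image with the original mask. Intensity filters
# (square, square-root, logarithm, exponential) follow the standard
# radiomics conventions with rescaling so the output range stays comparable
# to the input; gradient is the central-difference gradient magnitude
# honouring spacing; LoG is the Laplacian of a Gaussian-smoothed image at a
# sigma given in mm; wavelet is a single-level stationary (undecimated)
# separable coiflet-1 decomposition into 8 sub-bands.

# coiflet-1 decomposition filters
COIF1_LO <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
              0.852572020212255, 0.337897662457809, -0.072732619512854)
COIF1_HI <- rev(COIF1_LO) * c(1, -1, 1, -1, 1, -1)

filter_square <- function(x) {
  mx <- max(abs(x))
  if (mx == 0) return(x)
  x^2 / mx
}

filter_squareroot <- function(x) {
  mx <- max(abs(x))
  if (mx == 0) return(x)
  sign(x) * sqrt(abs(x) * mx)
}

filter_logarithm <- function(x) {
  mx <- max(abs(x))
  if (mx == 0) return(x)
  y <- sign(x) * log1p(abs(x))
  my <- max(abs(y))
  if (my == 0) return(y)
  y * (mx / my)
}

filter_exponential <- function(x) {
  mx <- max(abs(x))
  if (mx == 0) return(exp(x))
  exp(log(mx) / mx * x)
}

filter_gradient <- function(x, sp) {
  d <- dim(x)
  g2 <- array(0, d)
  for (ax in 1:3) {
    k <- c(-1, 0, 1) / (2 * sp[ax])
    g <- .conv3d_axis(as.numeric(x), d, rev(k), ax - 1L, 0L)
    g2 <- g2 + array(g^2, d)
  }
  sqrt(g2)
}

filter_log_sigma <- function(x, sp, sigma_mm) {
  d <- dim(x)
  sm <- gauss_smooth3d(array(as.numeric(x), d), sigma_mm / sp)
  lap <- array(0, d)
  for (ax in 1:3) {
    k <- c(1, -2, 1) / sp[ax]^2
    lap <- lap + array(.conv3d_axis(as.numeric(sm), d, k, ax - 1L, 0L), d)
  }
  lap
}

wavelet_subbands <- function(x, lo = COIF1_LO, hi = COIF1_HI) {
  d <- dim(x)
  bands <- list(L = lo, H = hi)
  out <- list()
  for (bz in c("L", "H"))
    for (by in c("L", "H"))
      for (bx in c("L", "H")) {
        y <- .conv3d_axis(as.numeric(x), d, bands[[bx]], 0L, 1L)
        y <- .conv3d_axis(y, d, bands[[by]], 1L, 1L)
        y <- .conv3d_axis(y, d, bands[[bz]], 2L, 1L)
        out[[paste0(bx, by, bz)]] <- array(y, d)
      }
  out
}

#' Derived filter images for the radiomics battery
#'
#' @param image an [image_volume()].
#' @param mask the paired [voxel_mask()]; returned untouched with each
#'   filter image.
#' @param filters character vector drawn from `"gradient"`,
#'   `"exponential"`, `"logarithm"`, `"squareroot"`, `"square"`, `"log"`
#'   (Laplacian of Gaussian, expanded to `log_sigma_<s>` for each sigma) and
#'   `"wavelet"` (expanded to the 8 sub-bands `wavelet_LLL` ...
#'   `wavelet_HHH`). Explicit `log_sigma_<s>` and `wavelet_<band>` names are
#'   also accepted.
#' @param log_sigmas LoG sigmas in mm (default 1, 2, 3).
#' @return Named list of [image_volume()] objects, one per expanded filter.
#' @export
filter_images <- function(image, mask, filters, log_sigmas = c(1, 2, 3)) {
  check_aligned(image, mask)
  sp <- spacing(image)
  x <- unclass_keep_dim(image)
  out <- list()
  wav <- NULL
  for (f in filters) {
    if (f == "square") out[[f]] <- filter_square(x)
    else if (f == "squareroot") out[[f]] <- filter_squareroot(x)
    else if (f == "logarithm") out[[f]] <- filter_logarithm(x)
    else if (f == "exponential") out[[f]] <- filter_exponential(x)
    else if (f == "gradient") out[[f]] <- filter_gradient(x, sp)
    else if (f == "log") {
      for (s in log_sigmas)
        out[[sprintf("log_sigma_%g", s)]] <- filter_log_sigma(x, sp, s)
    } else if (grepl("^log_sigma_", f)) {
      s <- as.numeric(sub("^log_sigma_", "", f))
      if (!is.finite(s) || s <= 0)
        stop_subgrade(paste("bad LoG sigma in filter name:", f),
                      "subgrade_config_error")
      out[[f]] <- filter_log_sigma(x, sp, s)
    } else if (f == "wavelet") {
      if (is.null(wav)) wav <- wavelet_subbands(x)
      for (b in names(wav)) out[[paste0("wavelet_", b)]] <- wav[[b]]
    } else if (grepl("^wavelet_[LH]{3}$", f)) {
      if (is.null(wav)) wav <- wavelet_subbands(x)
      out[[f]] <- wav[[sub("^wavelet_", "", f)]]
    } else {
      stop_subgrade(paste("unknown filter:", f), "subgrade_config_error")
    }
  }
  lapply(out, image_volume, spacing_mm = sp)
}
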