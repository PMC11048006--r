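# Working sub-volume: the mask bounding box plus a fixed pad (default 5
# voxels), so filters and texture counters never scan empty space far from
# the region. Feature values are unaffected: all computations are
# mask-restricted and the pad keeps spatial filters supported.
crop_to_mask <- function(image, mask, pad = 5L) {
  d <- dim(mask)
  idx <- which(as.logical(mask))
  co <- arrayInd(idx, d)
  lo <- pmax(apply(co, 2, min) - pad, 1L)
  hi <- pmin(apply(co, 2, max) + pad, d)
  if (all(lo == 1L) && all(hi == d)) return(list(image = image, mask = mask))
  ig <- unclass_keep_dim(image)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                drop = FALSE]
  mg <- array(as.logical(mask), d)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                   drop = FALSE]
  list(image = image_volume(ig, spacing(image)),
       mask = voxel_mask(mg, spacing(mask)))
}

texture_classes <- function(image, mask, bin_width) {
  disc <- discretize(image, mask, bin_width)
  c(prefix_names("firstorder", first_order_features(image, mask, disc)),
    prefix_names("glcm", glcm_features(disc)),
    prefix_names("glrlm", glrlm_features(disc)),
    prefix_names("glszm", glszm_features(disc)),
    prefix_names("gldm", gldm_features(disc)),
    prefix_names("ngtdm", ngtdm_features(disc)))
}

prefix_names <- function(cls, x) {
  names(x) <- paste0(cls, "_", names(x))
  x
}

#' Extract the full radiomics feature vector of one region
#'
#' Computes the original battery — 19 first-order, 24 GLCM, 16 GLRLM, 16
#' GLSZM, 14 GLDM and 5 NGTDM intensity/texture features plus 16 3D shape
#' features (110 features) — and, for every enabled filter image, the 94
#' intensity/texture features recomputed on the filtered intensities (shape
#' is computed once, on the mask only). Names follow
#' `<filter>_<class>_<feature>` with `original` for the unfiltered image,
#' in a fixed canonical order, and all values are finite for any region
#' passing the minimum-ROI check.
#'
#' @param image an [image_volume()].
#' @param mask the region [voxel_mask()]; bounding box at least 2 voxels
#'   on every axis.
#' @param filters filter names passed to [filter_images()]; empty for the
#'   original-only battery.
#' @param bin_width discretisation bin width (intensity units).
#' @param log_sigmas LoG sigmas in mm.
#' @return Named numeric vector (110 + 94 per expanded filter).
#' @export
extract_all <- function(image, mask, filters = character(0), bin_width = 20,
                        log_sigmas = c(1, 2, 3)) {
  check_aligned(image, mask)
  if (!roi_ok(mask))
    stop_subgrade("region below minimum ROI dimension of 2 voxels per axis",
                  "subgrade_roi_error")
  cr <- crop_to_mask(image, mask, pad = 5L)
  image <- cr$image
  mask <- cr$mask
  out <- c(prefix_names("original", texture_classes(image, mask, bin_width)),
           prefix_names("original_shape", shape_features(mask)))
  if (length(filters)) {
    fimgs <- filter_images(image, mask, filters, log_sigmas)
    for (fn in names(fimgs))
      out <- c(out, prefix_names(fn, texture_classes(fimgs[[fn]], mask,
                                                     bin_width)))
  }
  if (any(!is.finite(out))) { # defensive: defined limits should prevent this
    bad <- names(out)[!is.finite(out)]
    stop_subgrade(paste("non-finite features:", paste(bad, collapse = ", ")),
                  "subgrade_value_error")
  }
  out
}

#' Per-region feature tables for a set of subjects
#'
#' Runs [build_subregion_set()] and [extract_all()] for every subject and
#' assembles one feature table per analysis region (rows = subjects,
#' columns = features), each carrying `subject_id` and `grade_label`.
#'
#' @param volumes named list (by subject id) of lists with elements `image`
#'   and `mask`, e.g. from [generate_phantom()].
#' @param labels named integer vector of grade labels (1 = high).
#' @param fractions core/periphery volume fractions.
#' @param filters,bin_width,log_sigmas passed to [extract_all()].
#' @return Named list of data frames, one per region (`full`, `core25`,
#'   ..., `periphery75`).
#' @export
extract_feature_table <- function(volumes, labels,
                                  fractions = c(0.25, 0.5, 0.75),
                                  filters = character(0), bin_width = 20,
                                  log_sigmas = c(1, 2, 3)) {
  ids <- names(volumes)
  if (is.null(ids) || !all(ids %in% names(labels)))
    stop_subgrade("volumes and labels must share subject ids",
                  "subgrade_alignment_error")
  rows <- list()
  for (id in ids) {
    set <- build_subregion_set(volumes[[id]]$mask, fractions)
    for (rn in names(subregion_masks(set))) {
      fv <- extract_all(volumes[[id]]$image, subregion_masks(set)[[rn]],
                        filters, bin_width, log_sigmas)
      rows[[rn]][[id]] <- fv
    }
  }
  lapply(rows, function(rr) {
    mat <- do.call(rbind, rr)
    df <- data.frame(subject_id = names(rr),
                     grade_label = as.integer(labels[names(rr)]),
                     mat, check.names = FALSE, stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  })
}
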