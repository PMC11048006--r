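#' Depth map: distance from each tumour voxel to the tumour boundary
#'
#' For every foreground voxel, the Euclidean distance (mm, honouring
#' anisotropic spacing) to the centre of the nearest background voxel;
#' background voxels map to 0. Computed with a separable lower-envelope
#' distance transform, exact for arbitrary anisotropic spacing.
#'
#' @param mask a [voxel_mask()], non-empty.
#' @return A 3D numeric array of distances (mm) with the mask's spacing.
#' @export
boundary_distance <- function(mask) {
  if (sum(mask) == 0L)
    stop_subgrade("mask is empty", "subgrade_empty_error")
  sq <- .edt3d_sq(as.logical(mask), dim(mask), spacing(mask))
  d <- sqrt(sq)
  dim(d) <- dim(mask)
  attr(d, "spacing") <- spacing(mask)
  d
}

# Foreground voxels ordered deepest-first; ties broken lexicographically in
# (z, y, x) so the cut is deterministic across platforms.
depth_order <- function(mask, dmap) {
  idx <- which(as.logical(mask))
  co <- arrayInd(idx, dim(mask))
  idx[order(-dmap[idx], co[, 3], co[, 2], co[, 1])]
}

#' Extract the volume-fraction core of a tumour mask
#'
#' The core at fraction `p` is the `round(p * |mask|)` foreground voxels
#' lying deepest below the tumour surface (largest [boundary_distance()]),
#' i.e. `p` of the tumour volume taken from the centre outwards. Fraction
#' 1 returns the mask unchanged.
#'
#' @param mask a [voxel_mask()], non-empty.
#' @param fraction volume fraction in (0, 1].
#' @return A [voxel_mask()] with the selected voxels.
#' @export
extract_core <- function(mask, fraction) {
  n <- sum(mask)
  if (n == 0L)
    stop_subgrade("mask is empty", "subgrade_empty_error")
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 ||
      fraction > 1)
    stop_subgrade("fraction must be a single number in (0, 1]",
                  "subgrade_value_error")
  if (fraction == 1) return(mask)
  target <- round(fraction * n)
  if (target < 1)
    stop_subgrade(sprintf("core fraction %.3g of %d voxels is empty",
                          fraction, n), "subgrade_degenerate_error")
  ord <- depth_order(mask, boundary_distance(mask))
  out <- array(FALSE, dim(mask))
  out[ord[seq_len(target)]] <- TRUE
  voxel_mask(out, spacing(mask))
}

#' Extract the hollow-rim periphery of a tumour mask
#'
#' The periphery at fraction `p` is the outer rim holding `p` of the tumour
#' volume, obtained by subtracting the `1 - p` core from the full mask, so
#' `periphery(p)` and `core(1 - p)` partition the mask exactly.
#'
#' @inheritParams extract_core
#' @param fraction volume fraction in (0, 1).
#' @return A [voxel_mask()].
#' @export
extract_periphery <- function(mask, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 ||
      fraction >= 1)
    stop_subgrade("periphery fraction must be in (0, 1)",
                  "subgrade_value_error")
  core <- extract_core(mask, 1 - fraction)
  out <- as.logical(mask) & !as.logical(core)
  dim(out) <- dim(mask)
  if (!any(out))
    stop_subgrade("periphery is empty", "subgrade_degenerate_error")
  voxel_mask(out, spacing(mask))
}

# Number of bounding-box axes with foreground extent >= 2; a usable 3D ROI
# needs extent >= 2 on every axis.
roi_extents <- function(mask) {
  idx <- which(as.logical(mask))
  if (length(idx) == 0L) return(c(0L, 0L, 0L))
  co <- arrayInd(idx, dim(mask))
  apply(co, 2, function(v) max(v) - min(v) + 1L)
}

roi_ok <- function(mask) all(roi_extents(mask) >= 2L)

#' Build the seven analysis sub-regions of a tumour mask
#'
#' Decomposes the volume of interest into the full mask, cores at 25/50/75%
#' of the tumour volume, and the complementary hollow-rim peripheries at
#' 25/50/75%. Regions whose bounding box is thinner than 2 voxels on any
#' axis are flagged (not dropped), as are masks with more than one
#' 26-connected component (where the deepest-voxel core may sit in the
#' largest component only).
#'
#' @param mask a [voxel_mask()] with foreground extent of at least 2 voxels
#'   on every axis.
#' @param fractions volume fractions for the cores/peripheries.
#' @return A `subregion_set`: list with elements `full`, `cores` (named
#'   list), `peripheries` (named list), `counts` (voxel counts per region)
#'   and `flags` (character vector of degeneracy warnings).
#' @export
build_subregion_set <- function(mask, fractions = c(0.25, 0.5, 0.75)) {
  if (!roi_ok(mask))
    stop_subgrade("mask foreground must span at least 2 voxels per axis",
                  "subgrade_roi_error")
  n <- sum(mask)
  dmap <- boundary_distance(mask)
  ord <- depth_order(mask, dmap)
  flags <- character(0)
  nz <- .glszm_zones(array(as.integer(mask), dim(mask)), dim(mask))
  if (nrow(nz) > 1L)
    flags <- c(flags, sprintf("mask has %d connected components", nrow(nz)))
  cores <- list()
  peripheries <- list()
  for (f in fractions) {
    key <- sprintf("%d", round(100 * f))
    target <- max(0L, round(f * n))
    if (target < 1L) {
      flags <- c(flags, sprintf("core%s degenerate: no voxels", key))
      next
    }
    cg <- array(FALSE, dim(mask))
    cg[ord[seq_len(target)]] <- TRUE
    core <- voxel_mask(cg, spacing(mask))
    if (!roi_ok(core))
      flags <- c(flags, sprintf("core%s below minimum ROI dimension", key))
    cores[[key]] <- core
  }
  for (f in fractions) {
    key <- sprintf("%d", round(100 * f))
    ckey <- sprintf("%d", round(100 * (1 - f)))
    if (is.null(cores[[ckey]])) {
      flags <- c(flags, sprintf("periphery%s degenerate: complement core missing", key))
      next
    }
    pg <- as.logical(mask) & !as.logical(cores[[ckey]])
    dim(pg) <- dim(mask)
    if (!any(pg)) {
      flags <- c(flags, sprintf("periphery%s degenerate: empty", key))
      next
    }
    per <- voxel_mask(pg, spacing(mask))
    if (!roi_ok(per))
      flags <- c(flags, sprintf("periphery%s below minimum ROI dimension", key))
    peripheries[[key]] <- per
  }
  regions <- c(list(full = mask),
               setNames(cores, paste0("core", names(cores))),
               setNames(peripheries, paste0("periphery", names(peripheries))))
  structure(list(full = mask, cores = cores, peripheries = peripheries,
                 counts = vapply(regions, sum, integer(1)),
                 flags = flags),
            class = "subregion_set")
}

#' @export
print.subregion_set <- function(x, ...) {
  cat("<subregion_set>\n")
  print(x$counts)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Flatten a subregion set to a named list of masks
#' @param set a `subregion_set` from [build_subregion_set()].
#' @return Named list of [voxel_mask()] objects (`full`, `core25`, ...).
#' @export
subregion_masks <- function(set) {
  c(list(full = set$full),
    setNames(set$cores, paste0("core", names(set$cores))),
    setNames(set$peripheries, paste0("periphery", names(set$peripheries))))
}
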