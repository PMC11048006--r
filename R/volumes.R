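#' Create a 3D scalar image volume
#'
#' A thin container pairing a 3D numeric array of intensities (Hounsfield
#' units for CT) with its anisotropic voxel spacing in millimetres.
#'
#' @param grid 3D numeric array of voxel intensities.
#' @param spacing_mm numeric length-3, voxel edge lengths per axis (mm).
#' @return An `image_volume` object (the array with a `spacing` attribute).
#' @export
image_volume <- function(grid, spacing_mm = c(1, 1, 1)) {
  grid <- check_grid3d(grid, "image grid")
  storage.mode(grid) <- "double"
  if (any(!is.finite(grid)))
    stop_subgrade("image grid contains non-finite values", "subgrade_value_error")
  structure(grid, spacing = check_spacing(spacing_mm),
            class = c("image_volume", class(grid)))
}

#' Create a 3D binary voxel mask
#'
#' The volume of interest: a 3D logical array on the same grid as its image,
#' with anisotropic voxel spacing.
#'
#' @param grid 3D logical (or coercible) array; `TRUE` marks foreground.
#' @param spacing_mm numeric length-3 voxel edge lengths (mm).
#' @return A `voxel_mask` object.
#' @export
voxel_mask <- function(grid, spacing_mm = c(1, 1, 1)) {
  grid <- check_grid3d(grid, "mask grid")
  if (!is.logical(grid)) {
    g <- grid != 0
    dim(g) <- dim(grid)
    grid <- g
  }
  structure(grid, spacing = check_spacing(spacing_mm),
            class = c("voxel_mask", "logical"))
}

check_grid3d <- function(grid, what) {
  if (is.null(dim(grid)) || length(dim(grid)) != 3L)
    stop_subgrade(paste(what, "must be a 3D array"), "subgrade_shape_error")
  grid
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_subgrade("spacing must be 3 positive numbers", "subgrade_value_error")
  spacing
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s, spacing %s mm, %d foreground voxels\n",
              paste(dim(x), collapse = "x"),
              paste(signif(spacing(x), 4), collapse = "x"), sum(x)))
  invisible(x)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, spacing %s mm, range [%.5g, %.5g]\n",
              paste(dim(x), collapse = "x"),
              paste(signif(spacing(x), 4), collapse = "x"),
              min(x), max(x)))
  invisible(x)
}

#' Voxel spacing of a volume or mask
#' @param x an `image_volume`, `voxel_mask` or distance map.
#' @return Numeric length-3 spacing in mm.
#' @export
spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) c(1, 1, 1) else s
}

check_aligned <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    stop_subgrade("image and mask shapes differ", "subgrade_alignment_error")
  if (!isTRUE(all.equal(spacing(image), spacing(mask), tolerance = 1e-8)))
    stop_subgrade("image and mask spacing differ", "subgrade_alignment_error")
  invisible(TRUE)
}

#' Write an image/mask pair as NIfTI files
#'
#' Writes `<prefix>_image.nii.gz` and `<prefix>_mask.nii.gz` with the voxel
#' spacing stored in the NIfTI header, so that [read_volume()] round-trips
#' data, spacing and affine.
#'
#' @param image an [image_volume()].
#' @param mask a [voxel_mask()] on the same grid.
#' @param prefix output path prefix (directories must exist).
#' @return Invisibly, the two file paths.
#' @export
write_volume <- function(image, mask, prefix) {
  check_aligned(image, mask)
  sp <- spacing(image)
  paths <- paste0(prefix, c("_image.nii.gz", "_mask.nii.gz"))
  img <- RNifti::asNifti(unclass_keep_dim(image))
  msk <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- sp
  RNifti::pixdim(msk) <- sp
  RNifti::writeNifti(img, paths[1])
  RNifti::writeNifti(msk, paths[2])
  invisible(paths)
}

unclass_keep_dim <- function(x) {
  d <- dim(x)
  y <- as.numeric(x)
  dim(y) <- d
  y
}

#' Read an image/mask pair written by [write_volume()]
#'
#' @param prefix path prefix used at write time.
#' @return A list with elements `image` ([image_volume()]) and `mask`
#'   ([voxel_mask()]).
#' @export
read_volume <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, "_image.nii.gz"))
  msk <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  sp_i <- RNifti::pixdim(img)[1:3]
  sp_m <- RNifti::pixdim(msk)[1:3]
  if (!identical(dim(img), dim(msk)) ||
      !isTRUE(all.equal(sp_i, sp_m, tolerance = 1e-6)))
    stop_subgrade("image and mask files are not aligned",
                  "subgrade_alignment_error")
  list(image = image_volume(array(as.numeric(img), dim = dim(img)), sp_i),
       mask = voxel_mask(array(as.integer(msk) != 0, dim = dim(msk)), sp_m))
}

#' Dice similarity coefficient of two masks
#'
#' `2|A  B| / (|A| + |B|)`; the overlap measure used for inter-reader
#' agreement between segmentations. Two empty masks have Dice 1 by
#' convention.
#'
#' @param a,b `voxel_mask` objects on identical grids.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_subgrade("masks have different shapes", "subgrade_alignment_error")
  if (!isTRUE(all.equal(spacing(a), spacing(b), tolerance = 1e-8)))
    stop_subgrade("masks have different spacing", "subgrade_alignment_error")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}
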