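#' 3D scalar volume with voxel geometry
#'
#' Lightweight container used throughout the package for acquired MRI
#' channels, derived channels, and intermediate images. The voxel-to-world
#' affine follows the NIfTI convention (column 4 = world origin); analyses
#' in this package operate on the voxel grid and use `spacing_mm` for all
#' physical measurements.
#'
#' @param data numeric 3D array.
#' @param spacing_mm numeric length-3, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world matrix; default diag(spacing) centred
#'   at the origin.
#' @return object of class `vol3d`.
#' @export
vol3d <- function(data, spacing_mm = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(!is.finite(data)))
    stop("volume contains non-finite values")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive values")
  if (is.null(affine)) {
    affine <- diag(c(spacing_mm, 1))
    affine[1:3, 4] <- -spacing_mm * (dim(data) - 1) / 2
  }
  structure(list(data = data, spacing_mm = spacing_mm, affine = affine),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels, spacing %s mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary lesion mask (VOI)
#'
#' A volume of interest traced on T2-weighted images, stored on a voxel
#' grid together with the space it lives in (`native` scanner space or
#' `atlas` standard space).
#'
#' @param data 3D array coercible to 0/1.
#' @param space `"native"` or `"atlas"`.
#' @inheritParams vol3d
#' @return object of class `voi_mask` (also a `vol3d`).
#' @export
voi_mask <- function(data, space = c("native", "atlas"),
                     spacing_mm = c(1, 1, 1), affine = NULL) {
  space <- match.arg(space)
  data <- array(as.integer(data != 0), dim = dim(data))
  v <- vol3d(data, spacing_mm, affine)
  v$space <- space
  class(v) <- c("voi_mask", "vol3d")
  v
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s voxels, %d in mask, space=%s\n",
              paste(dim(x$data), collapse = "x"), sum(x$data), x$space))
  invisible(x)
}

same_grid <- function(a, b) identical(dim(a$data), dim(b$data))

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("grid mismatch between volumes")
  invisible(TRUE)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over RNifti keeping the `vol3d` geometry attributes.
#'
#' @param x a `vol3d` or `voi_mask`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` a `vol3d`.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data, reference = NULL)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vol3d(array(as.numeric(img), dim = dim(img)),
        spacing_mm = RNifti::pixdim(img)[1:3])
}
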