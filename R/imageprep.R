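#' Normalize a channel to 256 gray levels
#'
#' Intensity normalization applied to every acquired channel before
#' feature extraction, so that images from different scanners share a
#' common 0..255 gray-level scale. Two modes are used:
#'
#' * `clip999` (T1, FLAIR, gadolinium T1): voxels above the 99.9th
#'   percentile — mostly high-signal noise — are capped at that
#'   percentile, and the retained range is mapped linearly onto 0..255.
#' * `t2_fullrange` (T2): the full data range is mapped onto 0..255.
#'
#' The gray-level map is `floor(255 * (x - min) / (max - min))` with the
#' maximum mapped to 255; a constant volume maps to all zeros. The map is
#' monotone non-decreasing and invariant to positive affine rescaling of
#' the input.
#'
#' @param vol a `vol3d` with arbitrary intensity units.
#' @param mode `"clip999"` or `"t2_fullrange"`.
#' @return a `vol3d` whose data are integers in 0..255, with attribute
#'   `provenance` recording the mode.
#' @export
normalize_channel <- function(vol, mode = c("clip999", "t2_fullrange")) {
  mode <- match.arg(mode)
  x <- vol$data
  if (length(x) == 0) stop("empty volume")
  if (any(!is.finite(x))) stop("non-finite intensities")
  if (mode == "clip999") {
    cap <- stats::quantile(x, 0.999, names = FALSE)
    x <- pmin(x, cap)
  }
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    y <- floor(255 * (x - lo) / (hi - lo))
    y[y > 255] <- 255  # guard against floating-point spill at the max
  } else {
    y <- x * 0
  }
  out <- vol3d(array(as.integer(y), dim = dim(vol$data)),
               spacing_mm = vol$spacing_mm, affine = vol$affine)
  out$provenance <- mode
  out
}

# separable 3x3x3 convolution, replicate (nearest-edge) padding, so a
# locally constant image has zero derivative response at the boundary too
conv3_sep <- function(x, kx, ky, kz) {
  d <- dim(x)
  out <- array(0, d)
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    w <- kx[ox + 2] * ky[oy + 2] * kz[oz + 2]
    if (w == 0) next
    ix <- pmin(pmax(seq_len(d[1]) + ox, 1L), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + oy, 1L), d[2])
    iz <- pmin(pmax(seq_len(d[3]) + oz, 1L), d[3])
    out <- out + w * x[ix, iy, iz]
  }
  out
}

#' T2 edge channel via a 3D Prewitt filter
#'
#' Derived channel emphasizing lesion borders: each axis response is the
#' separable Prewitt kernel (derivative `(-1, 0, 1)` along the axis,
#' uniform `(1, 1, 1)` smoothing along the other two), the edge magnitude
#' is the Euclidean norm of the three responses, and the result is mapped
#' back onto 0..255 with the full-range gray-level rule. The image is
#' replicate-padded at the grid boundary, so constant regions respond
#' zero everywhere, including at the edge of the volume.
#'
#' @param t2 normalized T2 channel (`vol3d`, 0..255).
#' @return a `vol3d` of integers in 0..255.
#' @export
prewitt_edge <- function(t2) {
  d <- dim(t2$data)
  if (any(d < 3)) stop("kernel larger than volume")
  x <- t2$data
  deriv <- c(-1, 0, 1); smooth <- c(1, 1, 1)
  gx <- conv3_sep(x, deriv, smooth, smooth)
  gy <- conv3_sep(x, smooth, deriv, smooth)
  gz <- conv3_sep(x, smooth, smooth, deriv)
  mag <- sqrt(gx^2 + gy^2 + gz^2)
  normalize_channel(vol3d(mag, t2$spacing_mm, t2$affine), "t2_fullrange")
}

#' Gadolinium contrast-enhancement z-score channel
#'
#' Voxel-wise contrast enhancement computed from the co-registered
#' non-contrast and gadolinium-enhanced T1 channels: the difference
#' `d = gd - t1` is standardized against its distribution over a
#' reference mask of normal-appearing brain (brain minus lesion), giving
#' `z = (d - mean_ref) / sd_ref`. The reference SD is the population SD.
#' If the reference difference is constant (SD 0) the z-map is defined as
#' identically zero.
#'
#' @param t1,gd normalized T1 and gadolinium-enhanced T1 (`vol3d`, same grid).
#' @param reference_mask `voi_mask` of normal-appearing brain.
#' @return a `vol3d` of z values with attribute `reference_stats`
#'   (`mean`, `sd` of the reference differences).
#' @export
gd_zscore <- function(t1, gd, reference_mask) {
  stopifnot_same_grid(t1, gd)
  stopifnot_same_grid(t1, reference_mask)
  ref <- reference_mask$data > 0
  if (!any(ref)) stop("empty reference mask")
  d <- gd$data - t1$data
  dr <- d[ref]
  m <- mean(dr)
  s <- sqrt(mean((dr - m)^2))
  if (s > 0) {
    z <- (d - m) / s
  } else {
    z <- d * 0
  }
  out <- vol3d(z, t1$spacing_mm, t1$affine)
  out$reference_stats <- c(mean = m, sd = s)
  out
}
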