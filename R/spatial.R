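#' Affine transform parameters to a 4x4 matrix
#'
#' Builds the voxel-to-voxel map used for registration and resampling.
#' Parameters are applied about the fixed-grid center: rotations (deg,
#' about x, y, z), then anisotropic scales, then shears, then
#' translation (voxels). The returned matrix maps homogeneous fixed
#' voxel coordinates to moving voxel coordinates (the backward/sampling
#' map).
#'
#' @param params numeric vector `c(tx, ty, tz, rx, ry, rz[, sx, sy, sz[,
#'   hxy, hxz, hyz]])`; length 6, 9 or 12.
#' @param center_fixed,center_moving grid centers (voxel coords).
#' @return 4x4 matrix.
#' @export
affine_from_params <- function(params, center_fixed, center_moving = center_fixed) {
  stopifnot(length(params) %in% c(6L, 9L, 12L))
  t <- params[1:3]; r <- params[4:6] * pi / 180
  s <- if (length(params) >= 9) params[7:9] else c(1, 1, 1)
  h <- if (length(params) == 12) params[10:12] else c(0, 0, 0)
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  Sh <- rbind(c(1, h[1], h[2]), c(0, 1, h[3]), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% diag(s) %*% Sh
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- center_moving + t - A %*% center_fixed
  M
}

# trilinear sampling of a 3D array at fractional voxel coords (Nx3);
# returns NA outside the grid
sample_trilinear <- function(x, co) {
  d <- dim(x)
  ok <- co[, 1] >= 1 & co[, 1] <= d[1] & co[, 2] >= 1 & co[, 2] <= d[2] &
    co[, 3] >= 1 & co[, 3] <= d[3]
  # clamp the base node so coordinates exactly on the last grid plane
  # interpolate with fraction 1 instead of falling out of bounds
  i0 <- pmin(floor(co), rep(d - 1L, each = nrow(co)))
  f <- co - i0
  out <- rep(NA_real_, nrow(co))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; f <- f[ok, , drop = FALSE]
  g <- function(dx, dy, dz)
    x[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  w <- function(dx, dy, dz)
    (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
    (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
    (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    acc <- acc + w(dx, dy, dz) * g(dx, dy, dz)
  out[ok] <- acc
  out
}

grid_coords <- function(d) {
  cbind(as.vector(slice.index(array(0L, d), 1)),
        as.vector(slice.index(array(0L, d), 2)),
        as.vector(slice.index(array(0L, d), 3)))
}

# negative mutual information of fixed vs transformed moving (32-bin
# joint histogram over in-bounds voxels)
neg_mi <- function(params, fixed, moving, coords, fixed_bin, mov_rng,
                   n_bins = 32L) {
  d_f <- dim(fixed)
  M <- affine_from_params(params, (dim(fixed) + 1) / 2, (dim(moving) + 1) / 2)
  co <- coords %*% t(M[1:3, 1:3])
  co <- sweep(co, 2, M[1:3, 4], `+`)
  mv <- sample_trilinear(moving, co)
  ok <- !is.na(mv)
  if (sum(ok) < 100) return(0)  # negligible overlap
  mb <- pmin(n_bins, pmax(1L, 1L + floor((mv[ok] - mov_rng[1]) /
                                           diff(mov_rng) * n_bins)))
  joint <- matrix(tabulate(fixed_bin[ok] + n_bins * (mb - 1L),
                           nbins = n_bins^2), n_bins)
  pj <- joint / sum(joint)
  pf <- rowSums(pj); pm <- colSums(pj)
  nz <- which(pj > 0, arr.ind = TRUE)
  v <- pj[nz]
  -sum(v * log(v / (pf[nz[, 1]] * pm[nz[, 2]])))
}

downsample2 <- function(x) {
  d <- dim(x)
  dd <- floor(d / 2)
  x <- x[seq_len(2 * dd[1]), seq_len(2 * dd[2]), seq_len(2 * dd[3])]
  (x[seq(1, 2 * dd[1], 2), , ] + x[seq(2, 2 * dd[1], 2), , ]) |>
    (\(a) (a[, seq(1, 2 * dd[2], 2), ] + a[, seq(2, 2 * dd[2], 2), ]))() |>
    (\(a) (a[, , seq(1, 2 * dd[3], 2)] + a[, , seq(2, 2 * dd[3], 2)]) / 8)()
}

#' Mutual-information affine registration
#'
#' Registers `moving` to `fixed` by maximizing the mutual information of
#' their joint 32-bin intensity histogram over an affine transform with
#' 6, 9 or 12 degrees of freedom, using a multi-resolution coarse-to-fine
#' pyramid and derivative-free (Nelder-Mead) local optimization at each
#' level. Optional seeded jitter restarts guard against local optima;
#' the run is deterministic given `seed`.
#'
#' This is a self-contained registration with the same contract as the
#' standard template-registration step of the analysis (12-DOF MI
#' affine); it is validated on synthetic phantoms, not against any
#' external tool.
#'
#' @param moving,fixed `vol3d` volumes (nonconstant).
#' @param dof 6 (rigid), 9 (+scale) or 12 (+shear).
#' @param n_restarts extra jittered starts at the coarsest level.
#' @param seed RNG seed for the jitter.
#' @return `affine_transform`: list with `matrix` (4x4 fixed-to-moving
#'   voxel sampling map), `params`, `dof`, and `cost` (maximized MI).
#' @export
register_affine_mi <- function(moving, fixed, dof = 12L, n_restarts = 2L,
                               seed = 1L) {
  if (!dof %in% c(6L, 9L, 12L)) stop("dof must be 6, 9 or 12")
  if (min(moving$data) == max(moving$data) ||
      min(fixed$data) == max(fixed$data))
    stop("degenerate image: constant intensity, MI undefined")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  # pyramid: coarsest first; translations live in the level's voxel units
  pyr <- list(list(f = fixed$data, m = moving$data))
  while (all(dim(pyr[[1]]$f) >= 24)) {
    pyr <- c(list(list(f = downsample2(pyr[[1]]$f),
                       m = downsample2(pyr[[1]]$m))), pyr)
    if (length(pyr) >= 3) break
  }

  p0_full <- c(rep(0, 3), rep(0, 3), rep(1, 3), rep(0, 3))
  take <- seq_len(dof)
  par <- p0_full[take]
  n_bins <- 32L
  for (li in seq_along(pyr)) {
    f <- pyr[[li]]$f; m <- pyr[[li]]$m
    coords <- grid_coords(dim(f))
    frng <- range(f); mrng <- range(m)
    fb <- pmin(n_bins, pmax(1L, 1L + floor((as.vector(f) - frng[1]) /
                                             diff(frng) * n_bins)))
    obj <- function(p) neg_mi(p, f, m, coords, fb, mrng, n_bins)
    scale_up <- 2^(length(pyr) - li)
    par[1:3] <- par[1:3] * ifelse(li == 1, 1 / scale_up, 2)
    parscale <- c(rep(1, 3), rep(2, 3), rep(0.05, 3), rep(0.05, 3))[take]
    starts <- list(par)
    if (li == 1 && n_restarts > 0) {
      for (r in seq_len(n_restarts)) {
        jit <- par
        jit[1:3] <- jit[1:3] + stats::rnorm(3, 0, 2)
        jit[4:6] <- jit[4:6] + stats::rnorm(3, 0, 6)
        starts[[r + 1L]] <- jit
      }
    }
    best <- NULL
    for (st in starts) {
      fit <- stats::optim(st, obj, method = "Nelder-Mead",
                          control = list(parscale = parscale,
                                         maxit = 500, reltol = 1e-9))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    # successive simplex restarts at shrinking scale refine past the
    # collapsed-simplex plateau of Nelder-Mead
    for (shrink in c(4, 16)) {
      fit <- stats::optim(best$par, obj, method = "Nelder-Mead",
                          control = list(parscale = parscale / shrink,
                                         maxit = 400, reltol = 1e-10))
      if (fit$value < best$value) best <- fit
    }
    par <- best$par
  }
  M <- affine_from_params(par, (dim(fixed$data) + 1) / 2,
                          (dim(moving$data) + 1) / 2)
  if (abs(det(M)) < 1e-8) stop("non-invertible transform")
  structure(list(matrix = M, params = par, dof = dof, cost = -best$value),
            class = "affine_transform")
}

#' Resample a volume or mask through an affine transform
#'
#' Pulls `vol` onto `target_grid` through the fixed-to-moving sampling
#' map of `transform`: trilinear interpolation for intensity volumes,
#' nearest neighbor for masks (binarity preserved). Out-of-field voxels
#' become 0.
#'
#' @param vol `vol3d` or `voi_mask`.
#' @param transform `affine_transform` (or plain 4x4 matrix).
#' @param target_grid integer length-3 output grid.
#' @param spacing_mm spacing of the target grid (defaults to `vol`'s).
#' @return resampled `vol3d` / `voi_mask` (masks marked `space = "atlas"`).
#' @export
resample_to_atlas <- function(vol, transform, target_grid = dim(vol$data),
                              spacing_mm = vol$spacing_mm) {
  M <- if (inherits(transform, "affine_transform")) transform$matrix else transform
  if (abs(det(M)) < 1e-12) stop("non-invertible transform")
  is_mask <- inherits(vol, "voi_mask")
  co <- grid_coords(target_grid) %*% t(M[1:3, 1:3])
  co <- sweep(co, 2, M[1:3, 4], `+`)
  if (is_mask) {
    co <- round(co)
    d <- dim(vol$data)
    ok <- co[, 1] >= 1 & co[, 1] <= d[1] & co[, 2] >= 1 & co[, 2] <= d[2] &
      co[, 3] >= 1 & co[, 3] <= d[3]
    out <- numeric(nrow(co))
    out[ok] <- vol$data[co[ok, , drop = FALSE]]
    voi_mask(array(out, target_grid), space = "atlas", spacing_mm = spacing_mm)
  } else {
    out <- sample_trilinear(vol$data, co)
    out[is.na(out)] <- 0
    vol3d(array(out, target_grid), spacing_mm = spacing_mm)
  }
}

#' Mirror a mask about the mid-sagittal plane
#'
#' Left-right flip in atlas voxel space (reversal of the x axis), used to
#' pool lesions across hemispheres when laterality is ignored.
#'
#' @param mask `voi_mask` in atlas space.
#' @return flipped `voi_mask`.
#' @export
flip_lr <- function(mask) {
  if (!inherits(mask, "voi_mask")) stop("need a voi_mask")
  if (!identical(mask$space, "atlas")) stop("mask must be in atlas space")
  d <- dim(mask$data)
  voi_mask(mask$data[d[1]:1, , , drop = FALSE], space = "atlas",
           spacing_mm = mask$spacing_mm, affine = mask$affine)
}

#' Smooth synthetic head phantom
#'
#' Deterministic structured test image for registration: a large
#' ellipsoidal "head" with a smooth internal intensity gradient, an
#' off-center "ventricle" dip and two bright blobs, so the joint
#' histogram carries enough information to drive MI.
#'
#' @param n grid size per axis.
#' @param transform optional `affine_transform` or 4x4 matrix; the
#'   analytic phantom is evaluated at the transformed voxel coordinates,
#'   giving an exactly-warped copy free of interpolation error (the
#'   ground-truth construction for registration tests).
#' @return `vol3d` with unit spacing.
#' @export
head_phantom <- function(n = 32L, transform = NULL) {
  d <- rep(as.integer(n), 3)
  co <- grid_coords(d)
  if (!is.null(transform)) {
    M <- if (inherits(transform, "affine_transform")) transform$matrix else transform
    co <- sweep(co %*% t(M[1:3, 1:3]), 2, M[1:3, 4], `+`)
  }
  cx <- (d + 1) / 2
  u <- sweep(co, 2, cx) / (n / 2)
  r2 <- rowSums(sweep(u, 2, c(1, 0.85, 0.95), `/`)^2)
  head <- pmax(0, 1 - r2)
  blob <- function(c0, s) exp(-rowSums(sweep(u, 2, c0)^2) / (2 * s^2))
  img <- (100 * head * (1 + 0.4 * u[, 2] + 0.25 * u[, 1] - 0.2 * u[, 3]) -
            60 * blob(c(0, 0.1, 0), 0.22) +
            80 * blob(c(0.35, -0.2, 0.2), 0.13) +
            70 * blob(c(-0.3, 0.25, -0.15), 0.16) -
            50 * blob(c(0.2, 0.4, -0.3), 0.12) +
            65 * blob(c(-0.25, -0.35, 0.3), 0.11) +
            55 * blob(c(0.1, -0.1, -0.4), 0.14) -
            45 * blob(c(-0.4, 0, 0.1), 0.1)) * (head > 0)
  vol3d(array(img + 0, d))  # + 0 normalizes IEEE negative zeros
}
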