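#' First-order histogram features of a channel within the VOI
#'
#' The eight first-order statistics computed from the within-lesion
#' intensity histogram of a 256-gray-level channel: mean, SD (population),
#' skewness, excess kurtosis, median, 10th and 90th percentiles, and
#' Shannon entropy (bits) of the 256-level histogram. Zero-variance
#' regions return skewness and kurtosis 0 by convention (with a warning).
#'
#' @param channel normalized channel (`vol3d`).
#' @param voi `voi_mask` on the same grid.
#' @param entropy compute the 256-level histogram entropy (requires
#'   integer 0..255 data); set `FALSE` for continuous-valued channels.
#' @return named numeric vector of length 8 (7 if `entropy = FALSE`).
#' @export
first_order_features <- function(channel, voi, entropy = TRUE) {
  stopifnot_same_grid(channel, voi)
  v <- channel$data[voi$data > 0]
  if (length(v) == 0) stop("empty VOI")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s > 0) {
    skew <- mean((v - m)^3) / s^3
    kurt <- mean((v - m)^4) / s^4 - 3
  } else {
    warning("zero-variance region: skewness/kurtosis set to 0")
    skew <- 0; kurt <- 0
  }
  out <- c(mean = m, sd = s, skewness = skew, kurtosis = kurt,
           median = stats::median(v),
           p10 = stats::quantile(v, 0.10, names = FALSE),
           p90 = stats::quantile(v, 0.90, names = FALSE))
  if (entropy) {
    counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
    p <- counts[counts > 0] / length(v)
    out <- c(out, entropy = -sum(p * log2(p)))
  }
  out
}

# Separable Gaussian smoothing in voxel units (odd kernel, zero padding).
gauss_smooth3 <- function(x, sigma = 1, radius = 3L) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(x)
  conv1 <- function(a, axis) {
    out <- array(0, d)
    for (o in (-radius):radius) {
      w <- k[o + radius + 1L]
      src <- max(1, 1 - o):min(d[axis], d[axis] - o)
      idx_to <- list(1:d[1], 1:d[2], 1:d[3]); idx_from <- idx_to
      idx_to[[axis]] <- src; idx_from[[axis]] <- src + o
      out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
        out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] +
        w * a[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    }
    out
  }
  conv1(conv1(conv1(x, 1L), 2L), 3L)
}

# Surface area of a binary mask by the coarea (smoothed-gradient) rule:
# the mask indicator is mollified with a small Gaussian and the integral
# of the gradient magnitude approximates the surface integral. sigma is
# calibrated against analytic spheres (see the methods vignette).
mask_surface_area <- function(mask, spacing_mm, sigma = 0.7) {
  f <- gauss_smooth3(mask, sigma = sigma, radius = max(3L, ceiling(3 * sigma)))
  d <- dim(mask)
  grad_axis <- function(a, axis) {
    g <- array(0, d)
    n <- d[axis]
    idx <- function(r) { i <- list(1:d[1], 1:d[2], 1:d[3]); i[[axis]] <- r; i }
    ic <- idx(2:(n - 1)); ip <- idx(3:n); im <- idx(1:(n - 2))
    g[ic[[1]], ic[[2]], ic[[3]]] <-
      (a[ip[[1]], ip[[2]], ip[[3]]] - a[im[[1]], im[[2]], im[[3]]]) /
      (2 * spacing_mm[axis])
    g
  }
  gm <- sqrt(grad_axis(f, 1L)^2 + grad_axis(f, 2L)^2 + grad_axis(f, 3L)^2)
  sum(gm) * prod(spacing_mm)
}

#' Shape features of the lesion VOI
#'
#' Volume (voxel count times voxel volume, mm^3) and sphericity
#' `pi^(1/3) (6V)^(2/3) / A`, where the surface area `A` is estimated
#' from the smoothed mask gradient (coarea estimator). Sphericity is 1
#' for a perfect ball and decreases with elongation or surface
#' irregularity.
#'
#' @param voi `voi_mask` with known spacing.
#' @return named numeric vector `c(volume_mm3, sphericity)`.
#' @export
shape_features <- function(voi) {
  n <- sum(voi$data)
  if (n == 0) stop("empty VOI")
  vol <- n * prod(voi$spacing_mm)
  area <- mask_surface_area(voi$data, voi$spacing_mm)
  c(volume_mm3 = vol,
    sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area)
}

#' Enhancing-area fraction of the lesion
#'
#' Fraction of VOI voxels whose gadolinium z-score exceeds a threshold —
#' the magnitude-of-contrast-enhancement feature (`ara.of.Gd.`).
#'
#' @param z gadolinium z-score channel (`vol3d`).
#' @param voi `voi_mask` on the same grid.
#' @param z_thresh enhancement threshold in z units (default 2).
#' @return fraction in `[0, 1]`.
#' @export
enhancement_area <- function(z, voi, z_thresh = 2.0) {
  stopifnot_same_grid(z, voi)
  inside <- voi$data > 0
  if (!any(inside)) stop("empty VOI")
  mean(z$data[inside] > z_thresh)
}

#' Atlas-occupancy location features
#'
#' Encodes lesion location as the occupancy ratio of the VOI over a
#' labeled brain atlas: for each atlas label value `k` (including 0, the
#' white matter / background label), the fraction of lesion voxels
#' carrying that label. Entries are named `loc.01`, `loc.02`, ... where
#' `loc.(k+1)` corresponds to original atlas value `k`, so `loc.01` is
#' the white-matter fraction and, on the 10-label structural atlas,
#' `loc.04` (original value 3) the frontal-lobe fraction.
#'
#' @param voi_atlas `voi_mask` in atlas space.
#' @param atlas an `atlas_label_map` (see [make_toy_atlas()]).
#' @return numeric vector over all atlas labels, summing to 1.
#' @export
occupancy_features <- function(voi_atlas, atlas) {
  if (!identical(dim(voi_atlas$data), dim(atlas$data)))
    stop("grid mismatch between VOI and atlas")
  if (!is.null(voi_atlas$space) && voi_atlas$space != "atlas")
    stop("VOI must be in atlas space")
  inside <- voi_atlas$data > 0
  n <- sum(inside)
  if (n == 0) stop("empty VOI")
  labs <- atlas$labels$label
  counts <- tabulate(atlas$data[inside] + 1L, nbins = max(labs) + 1L)
  occ <- counts[labs + 1L] / n
  names(occ) <- sprintf("loc.%02d", labs + 1L)
  occ
}

#' The default 109-feature inventory
#'
#' Ordered list of the radiomic features extracted per case: 8
#' first-order statistics for each of T1, T2, FLAIR, Gd and T2Edge; for
#' the Gdzscore channel 7 first-order statistics plus the enhancing-area
#' fraction (`Gdzscore_ara.of.Gd.`); 2 shape features; 10 occupancy
#' ratios on the 10-label structural atlas (`MNI_str_loc.*`); and 49 on
#' the 49-label cortical atlas (`HrvdOxf_loc.*`) — 109 features in total.
#'
#' @return data.frame with columns `name`, `source`, `definition`.
#' @export
feature_inventory <- function() {
  fo <- c("mean", "sd", "skewness", "kurtosis", "median", "p10", "p90")
  rows <- list()
  for (ch in c("T1", "T2", "FLAIR", "Gd", "T2Edge")) {
    rows[[ch]] <- data.frame(name = paste0(ch, "_", c(fo, "entropy")),
                             source = ch,
                             definition = c(fo, "entropy"))
  }
  rows$Gdz <- data.frame(name = c(paste0("Gdzscore_", fo), "Gdzscore_ara.of.Gd."),
                         source = "Gdzscore",
                         definition = c(fo, "enhancement_area"))
  rows$shape <- data.frame(name = c("shape_volume_mm3", "shape_sphericity"),
                           source = "VOI",
                           definition = c("volume_mm3", "sphericity"))
  rows$mni <- data.frame(name = sprintf("MNI_str_loc.%02d", 1:10),
                         source = "mni10",
                         definition = sprintf("occupancy_label_%d", 0:9))
  rows$ho <- data.frame(name = sprintf("HrvdOxf_loc.%02d", 1:49),
                        source = "ho49",
                        definition = sprintf("occupancy_label_%d", 0:48))
  inv <- do.call(rbind, rows)
  rownames(inv) <- NULL
  stopifnot(!anyDuplicated(inv$name), nrow(inv) == 109L)
  inv
}

#' Extract the full radiomic feature vector for one case
#'
#' @param case a synthetic or loaded case: list with `channels` (named
#'   list of raw `vol3d` for T1, T2, FLAIR, Gd), `voi` (native-space
#'   `voi_mask`), `voi_atlas` (atlas-space `voi_mask`; defaults to `voi`
#'   when the case is generated directly in atlas space), and optional
#'   `brain_mask`.
#' @param atlas_mni,atlas_ho the two atlas label maps.
#' @param z_thresh enhancement threshold passed to [enhancement_area()].
#' @return named numeric vector following [feature_inventory()].
#' @export
extract_case_features <- function(case, atlas_mni, atlas_ho, z_thresh = 2.0) {
  ch <- case$channels
  need <- c("T1", "T2", "FLAIR", "Gd")
  if (!all(need %in% names(ch)))
    stop("missing channel(s): ", paste(setdiff(need, names(ch)), collapse = ", "))
  norm <- list(
    T1    = normalize_channel(ch$T1, "clip999"),
    T2    = normalize_channel(ch$T2, "t2_fullrange"),
    FLAIR = normalize_channel(ch$FLAIR, "clip999"),
    Gd    = normalize_channel(ch$Gd, "clip999"))
  norm$T2Edge <- prewitt_edge(norm$T2)
  brain <- if (!is.null(case$brain_mask)) case$brain_mask$data > 0 else
    array(TRUE, dim(ch$T1$data))
  ref <- voi_mask(brain & !(case$voi$data > 0), space = case$voi$space,
                  spacing_mm = case$voi$spacing_mm)
  gdz <- gd_zscore(norm$T1, norm$Gd, ref)

  voi <- case$voi
  voi_atlas <- if (!is.null(case$voi_atlas)) case$voi_atlas else voi
  feats <- c()
  for (nm in c("T1", "T2", "FLAIR", "Gd", "T2Edge")) {
    f <- first_order_features(norm[[nm]], voi)
    names(f) <- paste0(nm, "_", names(f))
    feats <- c(feats, f)
  }
  fz <- first_order_features(gdz, voi, entropy = FALSE)
  names(fz) <- paste0("Gdzscore_", names(fz))
  feats <- c(feats, fz,
             "Gdzscore_ara.of.Gd." = enhancement_area(gdz, voi, z_thresh))
  sh <- shape_features(voi)
  names(sh) <- paste0("shape_", names(sh))
  occ_m <- occupancy_features(voi_atlas, atlas_mni)
  names(occ_m) <- sub("^loc", "MNI_str_loc", names(occ_m))
  occ_h <- occupancy_features(voi_atlas, atlas_ho)
  names(occ_h) <- sub("^loc", "HrvdOxf_loc", names(occ_h))
  c(feats, sh, occ_m, occ_h)
}

#' Assemble the cohort feature table
#'
#' One row per case with the 109 inventory features plus `case_id`,
#' `institution` and `subtype` metadata. Cases missing one of the four
#' acquired channels are excluded with a warning, mirroring the
#' restriction of modeling to complete datasets.
#'
#' @param cases list of cases (see [extract_case_features()]).
#' @param atlas_mni,atlas_ho atlas label maps.
#' @param inventory feature inventory (defaults to [feature_inventory()]).
#' @param z_thresh enhancement threshold.
#' @return data.frame; feature columns in inventory order.
#' @export
assemble_feature_table <- function(cases, atlas_mni, atlas_ho,
                                   inventory = feature_inventory(),
                                   z_thresh = 2.0) {
  rows <- list(); meta <- list()
  dropped <- 0L
  for (case in cases) {
    ok <- all(c("T1", "T2", "FLAIR", "Gd") %in% names(case$channels))
    if (!ok) { dropped <- dropped + 1L; next }
    f <- extract_case_features(case, atlas_mni, atlas_ho, z_thresh)
    rows[[length(rows) + 1L]] <- f[inventory$name]
    meta[[length(meta) + 1L]] <-
      data.frame(case_id = case$case_id, institution = case$institution,
                 subtype = case$subtype)
  }
  if (dropped > 0)
    warning(sprintf("%d case(s) excluded for missing channels", dropped))
  if (length(rows) == 0) {
    empty <- as.data.frame(matrix(numeric(0), nrow = 0,
                                  ncol = nrow(inventory) + 3L))
    names(empty) <- c("case_id", "institution", "subtype", inventory$name)
    return(empty)
  }
  fmat <- do.call(rbind, rows)
  tab <- cbind(do.call(rbind, meta), as.data.frame(fmat))
  stopifnot(!anyNA(tab))
  rownames(tab) <- NULL
  tab
}

#' Names of the radiomic feature columns present in a table
#'
#' @param table a feature table.
#' @param inventory feature inventory defining the canonical order.
#' @return character vector in inventory order.
#' @export
feature_columns <- function(table, inventory = feature_inventory()) {
  intersect(inventory$name, names(table))
}

#' One-way ANOVA screen across molecular subtypes
#'
#' Per-feature one-way ANOVA F-test of differences among the subtype
#' groups, with p-values binned as in the significance screen
#' (`<0.001`, `0.001-0.01`, `0.01-0.05`, `>=0.05`). Features with zero
#' variance get p = 1 by convention.
#'
#' @param table feature table from [assemble_feature_table()].
#' @param group column name holding the grouping factor.
#' @return data.frame with `feature`, `F`, `p`, `bin`.
#' @export
anova_screen <- function(table, group = "subtype") {
  g <- factor(table[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(tabulate(g) < 2)) stop("each group needs at least 2 cases")
  feats <- feature_columns(table)
  res <- lapply(feats, function(nm) {
    y <- table[[nm]]
    if (stats::var(y) == 0) {
      warning(sprintf("constant feature '%s': p set to 1", nm))
      return(data.frame(feature = nm, F = 0, p = 1))
    }
    a <- stats::anova(stats::lm(y ~ g))
    data.frame(feature = nm, F = a$`F value`[1], p = a$`Pr(>F)`[1])
  })
  out <- do.call(rbind, res)
  out$bin <- cut(out$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                 labels = c("<0.001", "0.001-0.01", "0.01-0.05", ">=0.05"),
                 right = FALSE)
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix of the radiomic features
#'
#' @param table feature table.
#' @return symmetric correlation matrix; constant features contribute 0
#'   (with a warning), non-constant diagonal entries are 1.
#' @export
correlation_matrix <- function(table) {
  feats <- feature_columns(table)
  x <- as.matrix(table[, feats, drop = FALSE])
  if (nrow(x) < 2) stop("need at least 2 cases")
  const <- apply(x, 2, stats::var) == 0
  cm <- suppressWarnings(stats::cor(x))
  if (any(const)) {
    warning(sprintf("%d constant feature(s): correlations set to 0",
                    sum(const)))
    cm[const, ] <- 0; cm[, const] <- 0
  }
  cm
}
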