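#' Toy brain atlas label maps
#'
#' Deterministic geometric stand-ins for the two segmentation atlases the
#' location features are computed on. Both label every voxel of the grid:
#'
#' * `mni10`: 10 labels (0..9) mimicking a coarse structural atlas.
#'   Label 0 is a central deep white-matter core; the surrounding shell
#'   is partitioned into lobes, with label 3 the frontal lobe (so that
#'   occupancy feature `loc.04` carries the frontal fraction) and small
#'   deep-gray nuclei embedded in the core.
#' * `ho49`: 49 labels (0..48) mimicking a fine cortical parcellation;
#'   label 0 is again the central white matter and the shell is split
#'   into 48 slab-by-sector cortical parcels.
#'
#' These are synthetic label geometries, not the copyrighted atlas files;
#' real label maps with the same integer convention can be substituted.
#'
#' @param grid_shape integer length-3, at least 16 per axis.
#' @param scheme `"mni10"` or `"ho49"`.
#' @return `atlas_label_map`: list with `data` (integer 3D array),
#'   `labels` (data.frame label/name) and `scheme`.
#' @export
make_toy_atlas <- function(grid_shape, scheme = c("mni10", "ho49")) {
  scheme <- match.arg(scheme)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L) stop("grid_shape must have 3 entries")
  if (any(grid_shape < 16L)) stop("grid too small (need >= 16 per axis)")
  d <- grid_shape
  cx <- (d + 1) / 2
  ii <- slice.index(array(0L, d), 1); jj <- slice.index(array(0L, d), 2)
  kk <- slice.index(array(0L, d), 3)
  # normalized coordinates in [-1, 1]; y = anterior(+)/posterior(-)
  x <- (ii - cx[1]) / (d[1] / 2); y <- (jj - cx[2]) / (d[2] / 2)
  z <- (kk - cx[3]) / (d[3] / 2)
  core <- (x^2 + y^2 + z^2) < 0.45^2

  if (scheme == "mni10") {
    lab <- array(0L, d)
    # shell lobes by anterior-posterior position and height
    shell <- !core
    lab[shell & y >  0.25] <- 3L                       # frontal
    lab[shell & y < -0.25 & z >= 0] <- 5L              # occipital
    lab[shell & y < -0.25 & z < 0] <- 2L               # cerebellum
    mid <- shell & y >= -0.25 & y <= 0.25
    lab[mid & z >  0.15] <- 6L                         # parietal
    lab[mid & z < -0.15] <- 8L                         # temporal
    lab[mid & z >= -0.15 & z <= 0.15] <- 4L            # insula
    # deep nuclei: small spheres inside the core
    nuc <- function(c0, r) (x - c0[1])^2 + (y - c0[2])^2 + (z - c0[3])^2 < r^2
    lab[core & nuc(c(0.18, 0.12, 0.05), 0.10)] <- 1L   # caudate
    lab[core & nuc(c(-0.18, 0.05, -0.05), 0.10)] <- 7L # putamen
    lab[core & nuc(c(0, -0.15, 0), 0.10)] <- 9L        # thalamus
    labels <- data.frame(
      label = 0:9,
      name = c("white_matter", "caudate", "cerebellum", "frontal_lobe",
               "insula", "occipital_lobe", "parietal_lobe", "putamen",
               "temporal_lobe", "thalamus"))
  } else {
    # 48 cortical parcels: 8 anterior-posterior slabs x 6 angular sectors
    slab <- pmin(7L, pmax(0L, as.integer(floor((y + 1) / 2 * 8))))
    ang <- atan2(z, x)                       # sector around the AP axis
    sector <- pmin(5L, as.integer(floor((ang + pi) / (2 * pi) * 6)))
    lab <- array(1L + slab * 6L + sector, dim = d)
    lab[core] <- 0L
    labels <- data.frame(label = 0:48,
                         name = c("white_matter",
                                  sprintf("cortex_slab%d_sector%d",
                                          rep(0:7, each = 6), rep(0:5, 8))))
  }
  structure(list(data = lab, labels = labels, scheme = scheme),
            class = "atlas_label_map")
}

#' Cohort specification for the synthetic generator
#'
#' Defaults encode the study conditions the analysis assumes: 169 cases
#' with complete four-channel MRI from 11 institutions; three molecular
#' subtypes (IDH-mutant astrocytoma, IDH+TERT co-mutated
#' oligodendroglioma, IDH-wildtype astrocytoma) in roughly equal
#' proportions; subtype-biased lesion locations (astro frontotemporal,
#' oligo frontal, wildtype white-matter/parietal); subtype-dependent
#' channel intensities; and contrast enhancement enriched in the
#' IDH-wildtype group.
#'
#' @param n_cases number of cases.
#' @param n_institutions number of contributing institutions.
#' @param subtype_proportions length-3 probabilities (astro, oligo, wt).
#' @param grid_shape voxel grid (atlas space).
#' @param spacing_mm voxel size in mm.
#' @param location_weights 3x10 matrix of per-subtype probabilities over
#'   the `mni10` labels 0..9 from which lesion centers are drawn.
#' @param channel_means 3x4 matrix of lesion intensity offsets (rows =
#'   subtype, cols = T1, T2, FLAIR, Gd), arbitrary units.
#' @param channel_sds 3x4 matrix of within-lesion noise SDs.
#' @param enhancement_prob per-subtype probability of an enhancing core.
#' @param lesion_radius_mm length-2 range of mean lesion radii.
#' @param seed RNG seed.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 169L, n_institutions = 11L,
                        subtype_proportions = c(0.33, 0.33, 0.34),
                        grid_shape = c(40L, 40L, 40L),
                        spacing_mm = c(2.5, 2.5, 2.5),
                        location_weights = default_location_weights(),
                        channel_means = default_channel_means(),
                        channel_sds = default_channel_sds(),
                        enhancement_prob = c(0.1, 0.1, 0.6),
                        lesion_radius_mm = c(8, 15),
                        seed = 1L) {
  spec <- list(n_cases = as.integer(n_cases),
               n_institutions = as.integer(n_institutions),
               subtype_proportions = subtype_proportions,
               grid_shape = as.integer(grid_shape),
               spacing_mm = spacing_mm,
               location_weights = as.matrix(location_weights),
               channel_means = as.matrix(channel_means),
               channel_sds = as.matrix(channel_sds),
               enhancement_prob = enhancement_prob,
               lesion_radius_mm = lesion_radius_mm,
               seed = as.integer(seed))
  if (abs(sum(spec$subtype_proportions) - 1) > 1e-8)
    stop("subtype_proportions must sum to 1")
  if (any(abs(rowSums(spec$location_weights) - 1) > 1e-8))
    stop("location_weights rows must sum to 1")
  if (spec$n_cases > 0 &&
      (spec$n_institutions < 1 || spec$n_cases < spec$n_institutions))
    stop("need n_cases >= n_institutions >= 1")
  if (any(spec$lesion_radius_mm <= 0)) stop("lesion radius must be positive")
  if (spec$lesion_radius_mm[1] > spec$lesion_radius_mm[2])
    stop("lesion_radius_mm must be an increasing range")
  if (min(spec$lesion_radius_mm) / min(spec$spacing_mm) >
      max(spec$grid_shape))
    stop("impossible lesion radius for grid")
  class(spec) <- "cohort_spec"
  spec
}

subtype_levels <- function() c("IDHmt_astro", "IDHmt_TERTmt_oligo", "IDHwt")

#' @rdname cohort_spec
#' @export
default_location_weights <- function() {
  # rows: astro (frontotemporal), oligo (frontal),
  # wildtype (white matter + parietal, little frontal)
  w <- rbind(
    IDHmt_astro        = c(0.10, 0.01, 0.01, 0.25, 0.10, 0.05, 0.05, 0.01, 0.40, 0.02),
    IDHmt_TERTmt_oligo = c(0.10, 0.02, 0.01, 0.60, 0.08, 0.03, 0.05, 0.01, 0.08, 0.02),
    IDHwt              = c(0.35, 0.01, 0.01, 0.03, 0.03, 0.08, 0.30, 0.02, 0.15, 0.02))
  colnames(w) <- c("white_matter", "caudate", "cerebellum", "frontal_lobe",
                   "insula", "occipital_lobe", "parietal_lobe", "putamen",
                   "temporal_lobe", "thalamus")
  w
}

#' @rdname cohort_spec
#' @export
default_channel_means <- function() {
  m <- rbind(IDHmt_astro        = c(-15, 55, 45, -10),
             IDHmt_TERTmt_oligo = c(-10, 65, 50, -5),
             IDHwt              = c(-20, 50, 40, 0))
  colnames(m) <- c("T1", "T2", "FLAIR", "Gd")
  m
}

#' @rdname cohort_spec
#' @export
default_channel_sds <- function() {
  s <- rbind(IDHmt_astro        = c(10, 10, 10, 10),
             IDHmt_TERTmt_oligo = c(8, 8, 8, 8),
             IDHwt              = c(12, 12, 12, 12))
  colnames(s) <- c("T1", "T2", "FLAIR", "Gd")
  s
}

# largest-remainder integer allocation of n into shares p
largest_remainder <- function(n, p) {
  q <- n * p
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

ellipsoid_mask <- function(d, center, radii_vox) {
  ii <- slice.index(array(0L, d), 1); jj <- slice.index(array(0L, d), 2)
  kk <- slice.index(array(0L, d), 3)
  ((ii - center[1]) / radii_vox[1])^2 + ((jj - center[2]) / radii_vox[2])^2 +
    ((kk - center[3]) / radii_vox[3])^2 <= 1
}

#' Simulate a synthetic multi-institutional glioma cohort
#'
#' Generates per-case four-channel volumes and a T2-space lesion mask in
#' atlas space, with the statistical structure the downstream analysis
#' assumes: lesion centers drawn from the subtype's location
#' distribution over the toy structural atlas, ellipsoidal lesions with
#' mild anisotropy (axis ratio at most 2), subtype- and channel-specific
#' lesion intensity offsets on a tissue baseline, and an enhancing core
#' added with the subtype's enhancement probability. Institutions are
#' assigned round-robin and then shuffled. The generator is fully
#' deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional directory; when given, per-case NIfTI volumes and
#'   masks, a `manifest.csv` and `cohort_spec.yaml` are written there.
#' @return list with `cases` (list of case objects), `manifest`
#'   (data.frame case_id/institution/subtype plus file paths when
#'   written), and the two toy atlases.
#' @export
simulate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$grid_shape
  atlas_mni <- make_toy_atlas(d, "mni10")
  atlas_ho <- make_toy_atlas(d, "ho49")
  if (spec$n_cases == 0) {
    manifest <- data.frame(case_id = character(0), institution = character(0),
                           subtype = character(0))
    return(list(cases = list(), manifest = manifest,
                atlas_mni = atlas_mni, atlas_ho = atlas_ho))
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  n <- spec$n_cases
  subt <- rep(subtype_levels(), largest_remainder(n, spec$subtype_proportions))
  subt <- sample(subt)
  inst <- sample(rep_len(sprintf("inst%02d", seq_len(spec$n_institutions)), n))
  label_vox <- lapply(0:9, function(k) which(atlas_mni$data == k))
  # gentle label-dependent baseline modulation gives the brain structure
  base_mod <- (atlas_mni$data %% 5 - 2) * 4
  baseline <- c(T1 = 120, T2 = 100, FLAIR = 110, Gd = 120)
  noise_sd <- 6

  cases <- vector("list", n)
  for (i in seq_len(n)) {
    s <- match(subt[i], subtype_levels())
    lab <- sample.int(10L, 1L, prob = spec$location_weights[s, ]) - 1L
    vox_pool <- label_vox[[lab + 1L]]
    center <- arrayInd(vox_pool[sample.int(length(vox_pool), 1L)], d)[1, ]
    r_mm <- stats::runif(1, spec$lesion_radius_mm[1], spec$lesion_radius_mm[2])
    aniso <- stats::runif(3, 1 / sqrt(2), sqrt(2))   # axis ratio <= 2
    radii_vox <- pmax(r_mm * aniso / spec$spacing_mm, 0.51)
    mask <- ellipsoid_mask(d, center, radii_vox)
    enh <- stats::runif(1) < spec$enhancement_prob[s]
    core <- if (enh) ellipsoid_mask(d, center, pmax(radii_vox / 2, 0.51)) else NULL

    channels <- list()
    for (ci in 1:4) {
      ch <- colnames(spec$channel_means)[ci]
      img <- baseline[[ch]] + base_mod +
        array(stats::rnorm(prod(d), 0, noise_sd), d)
      img[mask] <- img[mask] + spec$channel_means[s, ci] +
        stats::rnorm(sum(mask), 0, spec$channel_sds[s, ci])
      if (ch == "Gd" && enh) img[core] <- img[core] + 60
      channels[[ch]] <- vol3d(img, spec$spacing_mm)
    }
    cases[[i]] <- list(
      case_id = sprintf("case%04d", i), institution = inst[i],
      subtype = subt[i],
      channels = channels,
      voi = voi_mask(mask, space = "atlas", spacing_mm = spec$spacing_mm),
      enhancing = enh, center_vox = center, center_label = lab)
  }
  manifest <- data.frame(
    case_id = vapply(cases, `[[`, "", "case_id"),
    institution = vapply(cases, `[[`, "", "institution"),
    subtype = vapply(cases, `[[`, "", "subtype"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- lapply(cases, function(case) {
      pp <- c(vapply(names(case$channels), function(ch) {
        p <- file.path(dir, sprintf("%s_%s.nii.gz", case$case_id, ch))
        write_volume(case$channels[[ch]], p); p
      }, ""), mask = {
        p <- file.path(dir, sprintf("%s_mask.nii.gz", case$case_id))
        write_volume(case$voi, p); p
      })
      pp
    })
    pm <- do.call(rbind, paths)
    colnames(pm) <- paste0("path_", colnames(pm))
    manifest <- cbind(manifest, as.data.frame(pm))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    yaml::write_yaml(spec_to_list(spec), file.path(dir, "cohort_spec.yaml"))
  }
  list(cases = cases, manifest = manifest,
       atlas_mni = atlas_mni, atlas_ho = atlas_ho)
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$location_weights <- apply(spec$location_weights, 1, as.list,
                                simplify = FALSE)
  out$channel_means <- apply(spec$channel_means, 1, as.list, simplify = FALSE)
  out$channel_sds <- apply(spec$channel_sds, 1, as.list, simplify = FALSE)
  out
}

#' Feature table with no class signal
#'
#' Generates a cohort-shaped feature table whose 109 features are pure
#' standard-normal noise, with balanced subtypes and round-robin
#' institutions — the null condition for chance-level checks of the
#' classification chain.
#'
#' @param n_cases number of cases.
#' @param n_institutions number of institutions.
#' @param seed RNG seed.
#' @return data.frame in the layout of [assemble_feature_table()].
#' @export
simulate_null_feature_table <- function(n_cases = 169L, n_institutions = 11L,
                                        seed = 1L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  inv <- feature_inventory()
  subt <- sample(rep_len(subtype_levels(), n_cases))
  inst <- sample(rep_len(sprintf("inst%02d", seq_len(n_institutions)), n_cases))
  x <- matrix(stats::rnorm(n_cases * nrow(inv)), nrow = n_cases,
              dimnames = list(NULL, inv$name))
  cbind(data.frame(case_id = sprintf("case%04d", seq_len(n_cases)),
                   institution = inst, subtype = subt),
        as.data.frame(x))
}
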