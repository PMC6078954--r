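#' Two-tailed Fisher exact test for a 3x2 table
#'
#' Exact conditional test of association in a 3x2 contingency table
#' (three molecular subtypes x lesion-positive/negative at a voxel). All
#' tables with the observed margins are enumerated; the two-tailed p is
#' the total hypergeometric probability of tables no more probable than
#' the observed one (probability-ordering rule). Exact by construction;
#' suitable for the small per-voxel counts of a lesion-mapping analysis.
#'
#' @param tab 3x2 matrix of nonnegative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_3x2_p <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(3L, 2L))) stop("need a 3x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  r <- rowSums(tab); K <- sum(tab[, 1]); N <- sum(tab)
  if (N == 0) stop("at least one positive margin required")
  if (K == 0 || K == N) return(1)  # degenerate column margin: single table
  enum <- enumerate_3x2_logprob(r, K)
  lp_obs <- lfirstcol_prob(r, K, tab[1, 1], tab[2, 1])
  # probability ordering with a relative tolerance against FP ties
  sum(exp(enum[enum <= lp_obs + 1e-7])) |> min(1)
}

# log P(first column = (a1,a2,K-a1-a2) | margins) up to the common
# normalizer log choose(N, K); normalizer included for absolute probs
lfirstcol_prob <- function(r, K, a1, a2) {
  a3 <- K - a1 - a2
  lchoose(r[1], a1) + lchoose(r[2], a2) + lchoose(r[3], a3) -
    lchoose(sum(r), K)
}

# log-probabilities of all 3x2 tables with row margins r and first
# column sum K (vectorized over the (a1, a2) grid)
enumerate_3x2_logprob <- function(r, K) {
  a1 <- 0:min(r[1], K)
  out <- vector("list", length(a1))
  for (i in seq_along(a1)) {
    a2 <- max(0, K - a1[i] - r[3]):min(r[2], K - a1[i])
    if (length(a2) == 0 || a2[1] > a2[length(a2)]) next
    out[[i]] <- lfirstcol_prob(r, K, a1[i], a2)
  }
  unlist(out)
}

#' Precomputed Fisher p lookup over all per-voxel count triples
#'
#' For fixed subtype group sizes `n = (n1, n2, n3)` the per-voxel 3x2
#' table is determined by the lesion-positive counts `(k1, k2, k3)`.
#' This computes the exact two-tailed p for every triple at once, sharing
#' the enumeration across triples with the same total, so that voxel-wise
#' maps and permutation replicates reduce to array lookups.
#'
#' @param n integer group sizes, length 3.
#' @return array of dim `n + 1`; entry `[k1+1, k2+1, k3+1]` is the p for
#'   the table with rows `(k_i, n_i - k_i)`.
#' @export
fisher_3x2_lookup <- function(n) {
  n <- as.integer(n)
  stopifnot(length(n) == 3L, all(n >= 1))
  p <- array(NA_real_, dim = n + 1L)
  k1 <- rep(0:n[1], times = (n[2] + 1L) * (n[3] + 1L))
  k2 <- rep(rep(0:n[2], each = n[1] + 1L), times = n[3] + 1L)
  k3 <- rep(0:n[3], each = (n[1] + 1L) * (n[2] + 1L))
  K_all <- k1 + k2 + k3
  for (K in 0:sum(n)) {
    sel <- which(K_all == K)
    if (K == 0 || K == sum(n)) { p[sel] <- 1; next }
    lp <- enumerate_3x2_logprob(n, K)
    o <- order(lp)
    lp_sorted <- lp[o]
    csum <- cumsum(exp(lp_sorted))
    lp_obs <- lfirstcol_prob(n, K, k1[sel], k2[sel])
    pos <- findInterval(lp_obs + 1e-7, lp_sorted)
    p[sel] <- pmin(csum[pos], 1)
  }
  p
}

#' Per-subtype lesion frequency maps
#'
#' @param vois list of atlas-space `voi_mask`s, one per case.
#' @param subtypes factor of subtype labels, one per case.
#' @return list with per-subtype `counts` (3D arrays), `freq`, and `n`.
#' @export
lesion_frequency_map <- function(vois, subtypes) {
  subtypes <- factor(subtypes)
  d <- dim(vois[[1]]$data)
  counts <- lapply(levels(subtypes), function(lv) {
    sel <- which(subtypes == lv)
    Reduce(`+`, lapply(vois[sel], function(v) v$data), array(0L, d))
  })
  names(counts) <- levels(subtypes)
  n <- tabulate(subtypes)
  names(n) <- levels(subtypes)
  list(counts = counts,
       freq = Map(function(cc, nn) cc / nn, counts, as.list(n)),
       n = n)
}

# per-case linear indices of lesion voxels (shared by map + permutations)
case_lesion_indices <- function(vois) lapply(vois, function(v) which(v$data > 0))

counts_from_indices <- function(idx, subtypes, nvox) {
  lapply(levels(subtypes), function(lv) {
    tabulate(unlist(idx[subtypes == lv], use.names = FALSE), nbins = nvox)
  })
}

#' Voxel-wise Fisher exact lesion map
#'
#' At every atlas voxel containing at least one lesion occurrence, tests
#' the 3x2 table (per subtype: lesion-positive count vs group size minus
#' count) with the exact two-tailed 3x2 Fisher test. Voxels never covered
#' by any lesion carry no p-value.
#'
#' @inheritParams lesion_frequency_map
#' @return list with `p` (3D array, NA where untested), `n` group sizes,
#'   and `tested` (logical 3D array).
#' @export
voxelwise_fisher_map <- function(vois, subtypes) {
  subtypes <- factor(subtypes)
  if (nlevels(subtypes) != 3L) stop("need exactly 3 subtypes in the cohort")
  if (any(tabulate(subtypes) == 0)) stop("subtype missing from cohort")
  d <- dim(vois[[1]]$data)
  for (v in vois) if (!identical(dim(v$data), d)) stop("grid mismatch among VOIs")
  idx <- case_lesion_indices(vois)
  nvox <- prod(d)
  k <- counts_from_indices(idx, subtypes, nvox)
  n <- tabulate(subtypes)
  lut <- fisher_3x2_lookup(n)
  tested <- (k[[1]] + k[[2]] + k[[3]]) > 0
  p <- rep(NA_real_, nvox)
  p[tested] <- lut[cbind(k[[1]][tested] + 1L, k[[2]][tested] + 1L,
                         k[[3]][tested] + 1L)]
  list(p = array(p, d), tested = array(tested, d), n = stats::setNames(n, levels(subtypes)))
}

neighbor_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  g <- switch(as.character(connectivity),
              "6" = g[ord == 1, ], "18" = g[ord <= 2, ], "26" = g,
              stop("connectivity must be 6, 18 or 26"))
  # keep one representative per +/- pair
  g[g$dx > 0 | (g$dx == 0 & g$dy > 0) | (g$dx == 0 & g$dy == 0 & g$dz > 0), ]
}

#' Label connected components of a binary 3D mask
#'
#' @param mask logical/0-1 3D array.
#' @param connectivity 6, 18 or 26 (face / face+edge / full neighborhood).
#' @return integer array of cluster ids (0 = background).
#' @export
label_clusters <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  fg <- which(mask != 0)
  lab <- array(0L, d)
  if (length(fg) == 0) return(lab)
  vid <- array(0L, d)
  vid[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  offs <- neighbor_offsets(connectivity)
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, as.numeric(offs[i, ]), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_id <- vid[nb[ok, , drop = FALSE]]
    hit <- nb_id > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(vid[fg][ok][hit], nb_id[hit])
  }
  if (length(edges) > 0) {
    e <- do.call(rbind, edges)
    gr <- igraph::graph_from_edgelist(e, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, length(fg) - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership
  } else {
    comp <- seq_along(fg)
  }
  lab[fg] <- as.integer(comp)
  lab
}

max_cluster_size <- function(mask, connectivity) {
  lab <- label_clusters(mask, connectivity)
  if (!any(lab > 0)) return(0L)
  max(tabulate(lab[lab > 0]))
}

#' Cluster-based permutation correction of the voxel-wise lesion map
#'
#' Suprathreshold voxels (`p < alpha`) of the observed Fisher map are
#' grouped into connected clusters; the null distribution of the maximum
#' cluster size is obtained by repeatedly reassigning the subtype labels
#' at random across cases (group sizes preserved) and recomputing the
#' map. A cluster is corrected-significant when its permutation-corrected
#' p-value, `(1 + #\{null max sizes >= size\}) / (1 + B)`, is at most
#' `alpha` — the finite-sample version of exceeding the null 95th
#' percentile that keeps the family-wise error rate controlled at
#' moderate permutation counts.
#'
#' @inheritParams lesion_frequency_map
#' @param n_permutations number of label permutations (study value: 500).
#' @param alpha voxel-level threshold (study value: 0.05).
#' @param connectivity cluster-defining connectivity (default 26).
#' @param seed RNG seed for the permutations.
#' @param flip_union if `TRUE`, each mask is unioned with its left-right
#'   mirror first, ignoring lesion laterality.
#' @return list with `sig_mask` (corrected-significant voxels),
#'   `clusters` (data.frame id/size/peak p/corrected p/significant),
#'   `null_max_sizes`, `threshold` (the null 95th percentile), and the
#'   observed map.
#' @export
cluster_permutation_correct <- function(vois, subtypes, n_permutations = 500L,
                                        alpha = 0.05, connectivity = 26L,
                                        seed = 1L, flip_union = FALSE) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  subtypes <- factor(subtypes)
  if (flip_union) vois <- lapply(vois, function(v) {
    fl <- flip_lr(v)
    voi_mask((v$data + fl$data) > 0, space = "atlas", spacing_mm = v$spacing_mm)
  })
  d <- dim(vois[[1]]$data)
  nvox <- prod(d)
  idx <- case_lesion_indices(vois)
  n <- tabulate(subtypes)
  lut <- fisher_3x2_lookup(n)

  pmap_from_labels <- function(labels) {
    k <- counts_from_indices(idx, labels, nvox)
    tested <- (k[[1]] + k[[2]] + k[[3]]) > 0
    p <- rep(NA_real_, nvox)
    p[tested] <- lut[cbind(k[[1]][tested] + 1L, k[[2]][tested] + 1L,
                           k[[3]][tested] + 1L)]
    p
  }

  p_obs <- pmap_from_labels(subtypes)
  supra <- array(!is.na(p_obs) & p_obs < alpha, d)
  lab <- label_clusters(supra, connectivity)
  sizes <- if (any(lab > 0)) tabulate(lab[lab > 0]) else integer(0)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  null_max <- integer(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- factor(sample(as.character(subtypes)), levels = levels(subtypes))
    pb <- pmap_from_labels(perm)
    null_max[b] <- max_cluster_size(array(!is.na(pb) & pb < alpha, d),
                                    connectivity)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  # finite-sample 95th percentile of the null: the ceiling(0.95(B+1))-th
  # order statistic; with the add-one corrected p this gives valid
  # family-wise control at finite B (the naive empirical quantile with
  # strict exceedance is anticonservative at B ~ 100)
  thr <- sort(null_max)[min(n_permutations,
                            ceiling(0.95 * (n_permutations + 1)))]
  clusters <- data.frame(
    cluster_id = seq_along(sizes), size = sizes,
    peak_p = vapply(seq_along(sizes),
                    function(i) min(p_obs[which(lab == i)]), numeric(1)),
    corrected_p = vapply(sizes, function(s)
      (1 + sum(null_max >= s)) / (1 + n_permutations), numeric(1)))
  clusters$significant <- clusters$corrected_p <= alpha
  sig <- array(FALSE, d)
  if (any(clusters$significant))
    sig[lab %in% clusters$cluster_id[clusters$significant]] <- TRUE
  list(sig_mask = sig, clusters = clusters, null_max_sizes = null_max,
       threshold = thr, p_map = array(p_obs, d), alpha = alpha,
       connectivity = connectivity)
}
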