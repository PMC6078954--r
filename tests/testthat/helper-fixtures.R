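# Shared fixtures, built in code and memoized across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# small complete cohort (12 cases, 3 institutions) used by feature tests
small_cohort <- function() {
  memo("small_cohort", function() {
    simulate_cohort(cohort_spec(n_cases = 12, n_institutions = 3, seed = 101))
  })
}

# planted-effect cohort: strong subtype-specific locations, weak texture
planted_cohort <- function() {
  memo("planted_cohort", function() {
    w <- matrix(0.02, 3, 10)
    w[1, 9] <- 0.5; w[1, 4] <- 0.34   # astro: temporal + frontal
    w[2, 4] <- 0.84                   # oligo: frontal
    w[3, 1] <- 0.42; w[3, 7] <- 0.42  # wildtype: white matter + parietal
    w <- w / rowSums(w)
    mu <- default_channel_means()
    mu[] <- rep(colMeans(mu), each = 3)  # same texture in every subtype
    simulate_cohort(cohort_spec(
      n_cases = 169, n_institutions = 11, location_weights = w,
      channel_means = mu, enhancement_prob = c(0.15, 0.15, 0.25),
      seed = 202))
  })
}

planted_feature_table <- function() {
  memo("planted_feature_table", function() {
    coh <- planted_cohort()
    assemble_feature_table(coh$cases, coh$atlas_mni, coh$atlas_ho)
  })
}

# random ball VOIs with no association to the (balanced) subtype labels
null_lesion_set <- function(n_per_group = 15, d = c(32, 32, 32), r = 8,
                            seed = 1) {
  set.seed(seed)
  co <- cbind(as.vector(slice.index(array(0L, d), 1)),
              as.vector(slice.index(array(0L, d), 2)),
              as.vector(slice.index(array(0L, d), 3)))
  subtypes <- rep(c("A", "B", "C"), each = n_per_group)
  vois <- lapply(seq_len(3 * n_per_group), function(i) {
    ctr <- stats::runif(3, r, d[1] - r + 1)
    voi_mask(array(as.integer(rowSums(sweep(co, 2, ctr)^2) <= r^2), d),
             space = "atlas")
  })
  list(vois = vois, subtypes = subtypes)
}

# digital ball mask, unit spacing
ball_mask <- function(r, n = 2 * r + 9, spacing = c(1, 1, 1)) {
  co <- expand.grid(1:n, 1:n, 1:n)
  cc <- (n + 1) / 2
  voi_mask(array(as.integer((co[, 1] - cc)^2 + (co[, 2] - cc)^2 +
                              (co[, 3] - cc)^2 <= r^2), c(n, n, n)),
           spacing_mm = spacing)
}

rand_vol <- function(d = c(8, 8, 8), seed = 1, lo = 0, hi = 100) {
  set.seed(seed)
  vol3d(array(stats::runif(prod(d), lo, hi), d))
}
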