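test_that("3x2 Fisher test matches the exhaustive-enumeration reference", {
  # degenerate tables: no association or an empty column margin
  expect_equal(fisher_3x2_p(rbind(c(2, 2), c(2, 2), c(2, 2))), 1)
  expect_equal(fisher_3x2_p(rbind(c(0, 3), c(0, 3), c(0, 3))), 1)

  # fully concentrated table vs the independent exact implementation
  tab <- rbind(c(3, 0), c(0, 3), c(0, 3))
  expect_equal(fisher_3x2_p(tab), fisher.test(tab)$p.value, tolerance = 1e-9)

  # row permutation invariance
  perm <- tab[c(2, 3, 1), ]
  expect_equal(fisher_3x2_p(tab), fisher_3x2_p(perm), tolerance = 1e-12)

  # random tables agree with fisher.test to enumeration accuracy
  set.seed(51)
  for (i in 1:50) {
    t2 <- matrix(rpois(6, 2.5), 3, 2)
    if (sum(t2) == 0) next
    expect_equal(fisher_3x2_p(t2), fisher.test(t2)$p.value, tolerance = 1e-9)
  }

  expect_error(fisher_3x2_p(rbind(c(-1, 2), c(1, 1), c(0, 0))), "nonnegative")
  expect_error(fisher_3x2_p(matrix(0, 3, 2)), "positive margin")
})

test_that("the count-triple lookup reproduces the per-table test", {
  n <- c(4L, 5L, 3L)
  lut <- fisher_3x2_lookup(n)
  expect_equal(dim(lut), n + 1L)
  for (k1 in 0:4) for (k2 in 0:5) for (k3 in 0:3) {
    tab <- cbind(c(k1, k2, k3), n - c(k1, k2, k3))
    expect_equal(lut[k1 + 1, k2 + 1, k3 + 1], fisher_3x2_p(tab),
                 tolerance = 1e-12)
  }
})

test_that("voxel-wise map tests exactly the lesion-covered voxels", {
  d <- c(12, 12, 12)
  mk <- function(ix) {
    m <- array(0L, d); m[ix] <- 1L
    voi_mask(m, space = "atlas")
  }
  # 5 cases per subtype; voxel 1 covered by everyone, voxel 2 only by
  # subtype B, voxel 3 by no one
  vois <- c(lapply(1:5, function(i) mk(1L)),
            lapply(1:5, function(i) mk(c(1L, 2L))),
            lapply(1:5, function(i) mk(1L)))
  subt <- rep(c("A", "B", "C"), each = 5)
  res <- voxelwise_fisher_map(vois, subt)
  expect_equal(res$p[1], 1)  # all rows (n_k, 0): no association
  oracle <- fisher.test(cbind(c(0, 5, 0), c(5, 0, 5)))$p.value
  expect_equal(res$p[2], oracle, tolerance = 1e-9)
  expect_true(is.na(res$p[3]))            # untested voxel: absent
  expect_false(res$tested[3])
  expect_true(all(res$p[res$tested] > 0 & res$p[res$tested] <= 1))

  expect_error(voxelwise_fisher_map(vois, rep(c("A", "B"), c(10, 5))),
               "3 subtypes")
})

test_that("cluster labeling respects the chosen connectivity", {
  m <- array(0L, c(8, 8, 8))
  m[2, 2, 2] <- 1L; m[3, 3, 3] <- 1L   # diagonal neighbors
  lab6 <- label_clusters(m, 6)
  expect_equal(max(lab6), 2L)          # separate under face connectivity
  lab26 <- label_clusters(m, 26)
  expect_equal(max(lab26), 1L)         # joined under full connectivity
  m[6, 6, 6] <- 1L
  lab <- label_clusters(m, 26)
  expect_equal(max(lab), 2L)
  expect_equal(sum(lab > 0), 3L)
  expect_equal(max(label_clusters(array(0L, c(4, 4, 4)), 26)), 0L)
})

test_that("permutation correction flags a planted regional effect", {
  # one subtype's lesions concentrated in a corner region
  d <- c(24, 24, 24)
  set.seed(61)
  co <- radglioma:::grid_coords(d)
  mk_ball <- function(ctr, r = 5) {
    voi_mask(array(as.integer(rowSums(sweep(co, 2, ctr)^2) <= r^2), d),
             space = "atlas")
  }
  vois <- c(lapply(1:10, function(i) mk_ball(runif(3, 6, 19))),
            lapply(1:10, function(i) mk_ball(c(7, 7, 7) + runif(3, -1, 1))),
            lapply(1:10, function(i) mk_ball(runif(3, 6, 19))))
  subt <- rep(c("A", "B", "C"), each = 10)
  res <- cluster_permutation_correct(vois, subt, n_permutations = 99, seed = 7)
  expect_length(res$null_max_sizes, 99L)
  expect_true(any(res$clusters$significant))
  # the significant cluster sits at the planted focus
  sig_vox <- which(res$sig_mask, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(sig_vox) - c(7, 7, 7))), 4)

  # reproducible given the seed
  res2 <- cluster_permutation_correct(vois, subt, n_permutations = 99, seed = 7)
  expect_identical(res$null_max_sizes, res2$null_max_sizes)

  expect_error(cluster_permutation_correct(vois, subt, n_permutations = 0),
               "n_permutations")
})

test_that("permutation null is exchangeable for label-shuffled cohorts", {
  # observed max cluster size on a null cohort behaves as a draw from its
  # own permutation null: the permutation p-value is roughly uniform
  pvals <- numeric(30)
  for (r in 1:30) {
    nl <- null_lesion_set(n_per_group = 10, d = c(24, 24, 24), r = 6,
                          seed = 700 + r)
    res <- cluster_permutation_correct(nl$vois, nl$subtypes,
                                       n_permutations = 60, seed = r)
    obs <- max(c(0L, res$clusters$size))
    pvals[r] <- (1 + sum(res$null_max_sizes >= obs)) / 61
  }
  # under exchangeability about half the p-values exceed 0.5 and few are tiny
  expect_gt(mean(pvals > 0.3), 0.4)
  expect_lt(mean(pvals < 0.05), 0.2)
})

test_that("lesion frequency maps count per-subtype occurrences", {
  nl <- null_lesion_set(n_per_group = 4, d = c(16, 16, 16), r = 4, seed = 9)
  fm <- lesion_frequency_map(nl$vois, nl$subtypes)
  expect_equal(unname(fm$n), rep(4L, 3))
  for (g in names(fm$counts)) {
    expect_true(all(fm$counts[[g]] <= 4))
    expect_true(all(fm$freq[[g]] >= 0 & fm$freq[[g]] <= 1))
  }
  # total counts match the summed masks
  tot <- Reduce(`+`, fm$counts)
  expect_equal(tot, Reduce(`+`, lapply(nl$vois, function(v) v$data)))
})
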