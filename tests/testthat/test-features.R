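test_that("first-order statistics match a brute-force oracle", {
  set.seed(11)
  d <- c(10, 10, 10)
  ch <- vol3d(array(sample(0:255, 1000, replace = TRUE), d))
  voi <- voi_mask(array(rbinom(1000, 1, 0.6), d))
  f <- first_order_features(ch, voi)
  v <- ch$data[voi$data > 0]
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / length(v))
  h <- table(v) / length(v)
  oracle <- c(mean = m, sd = s,
              skewness = (sum((v - m)^3) / length(v)) / s^3,
              kurtosis = (sum((v - m)^4) / length(v)) / s^4 - 3,
              median = median(v),
              p10 = quantile(v, 0.1, names = FALSE),
              p90 = quantile(v, 0.9, names = FALSE),
              entropy = -sum(h * log2(h)))
  expect_equal(f, oracle, tolerance = 1e-9)
})

test_that("first-order degenerate and analytic cases follow the conventions", {
  d <- c(4, 4, 4)
  voi <- voi_mask(array(1, d))
  cst <- vol3d(array(42, d))
  f <- suppressWarnings(first_order_features(cst, voi))
  expect_equal(unname(f[c("mean", "sd", "skewness", "kurtosis", "entropy")]),
               c(42, 0, 0, 0, 0))
  expect_equal(unname(f[c("median", "p10", "p90")]), c(42, 42, 42))
  expect_warning(first_order_features(cst, voi), "zero-variance")

  # two-level half/half region carries exactly 1 bit
  two <- vol3d(array(c(0, 255), d))
  expect_equal(unname(first_order_features(two, voi)["entropy"]), 1)

  # voxels outside the VOI are irrelevant
  ch <- rand_vol(d, seed = 12, lo = 0, hi = 255)
  ch$data[] <- floor(ch$data)
  voi2 <- voi_mask(array(c(1, 0), d))
  f1 <- first_order_features(ch, voi2)
  ch$data[voi2$data == 0] <- 0
  expect_identical(first_order_features(ch, voi2), f1)

  expect_error(first_order_features(ch, voi_mask(array(0, d))), "empty")
})

test_that("shape features: volume exact, sphericity calibrated and monotone", {
  one <- voi_mask(array(c(1, rep(0, 999)), c(10, 10, 10)))
  expect_equal(unname(shape_features(one)["volume_mm3"]), 1)

  ball <- ball_mask(10)
  sf <- shape_features(ball)
  expect_equal(unname(sf["volume_mm3"]), sum(ball$data))
  expect_gte(unname(sf["sphericity"]), 0.90)
  expect_lte(unname(sf["sphericity"]), 1.00)

  # elongated ellipsoid of similar volume is less spherical than the ball
  n <- 40; co <- expand.grid(1:n, 1:n, 1:n)
  el <- voi_mask(array(as.integer(((co[, 1] - 20.5) / 16)^2 +
                                    ((co[, 2] - 20.5) / 4)^2 +
                                    ((co[, 3] - 20.5) / 4)^2 <= 1), rep(n, 3)))
  expect_lt(unname(shape_features(el)["sphericity"]),
            unname(sf["sphericity"]))

  # spacing scales the volume
  mm <- voi_mask(ball$data, spacing_mm = c(2, 2, 2))
  expect_equal(unname(shape_features(mm)["volume_mm3"]), 8 * sum(ball$data))
})

test_that("enhancement area is the suprathreshold VOI fraction", {
  d <- c(6, 6, 6)
  voi <- voi_mask(array(rep(c(1, 0), 108), d))
  z0 <- vol3d(array(0, d))
  expect_equal(enhancement_area(z0, voi), 0)

  z <- vol3d(array(rep(c(5, 0), 108), d))
  half <- voi_mask(array(1, d))
  expect_equal(enhancement_area(z, half, 2), 0.5)

  set.seed(13)
  zr <- vol3d(array(rnorm(216), d))
  expect_equal(enhancement_area(zr, voi, 0.8),
               mean(zr$data[voi$data > 0] > 0.8))
})

test_that("occupancy features partition the lesion over atlas labels", {
  atlas <- make_toy_atlas(c(32, 32, 32), "mni10")
  # lesion entirely inside the frontal region (original label 3) -> loc.04 = 1
  frontal <- which(atlas$data == 3L)
  m <- array(0L, dim(atlas$data)); m[frontal[1:50]] <- 1L
  occ <- occupancy_features(voi_mask(m, space = "atlas"), atlas)
  expect_equal(unname(occ["loc.04"]), 1)
  expect_equal(sum(occ), 1)
  expect_true(all(occ[names(occ) != "loc.04"] == 0))

  # exact half/half split across two labels
  wm <- which(atlas$data == 0L)
  m2 <- array(0L, dim(atlas$data)); m2[frontal[1:25]] <- 1L; m2[wm[1:25]] <- 1L
  occ2 <- occupancy_features(voi_mask(m2, space = "atlas"), atlas)
  expect_equal(unname(occ2[c("loc.01", "loc.04")]), c(0.5, 0.5))

  # random VOI vs counting oracle, on both atlas schemes
  set.seed(14)
  m3 <- array(rbinom(prod(dim(atlas$data)), 1, 0.1), dim(atlas$data))
  for (scheme in c("mni10", "ho49")) {
    at <- make_toy_atlas(c(32, 32, 32), scheme)
    occ3 <- occupancy_features(voi_mask(m3, space = "atlas"), at)
    oracle <- vapply(at$labels$label, function(k)
      sum(at$data[m3 > 0] == k) / sum(m3), numeric(1))
    expect_equal(unname(occ3), oracle, tolerance = 1e-12)
    expect_equal(sum(occ3), 1, tolerance = 1e-9)
  }
})

test_that("feature table has the 109-column inventory and applies the exclusion rule", {
  coh <- small_cohort()
  tab <- assemble_feature_table(coh$cases, coh$atlas_mni, coh$atlas_ho)
  inv <- feature_inventory()
  expect_equal(nrow(inv), 109L)
  expect_identical(names(tab), c("case_id", "institution", "subtype", inv$name))
  expect_equal(nrow(tab), 12L)
  expect_false(anyNA(tab))

  # occupancy blocks are distributions
  expect_equal(unname(rowSums(tab[, grep("^MNI_str_loc", names(tab))])),
               rep(1, 12), tolerance = 1e-9)
  expect_equal(unname(rowSums(tab[, grep("^HrvdOxf_loc", names(tab))])),
               rep(1, 12), tolerance = 1e-9)

  # case order does not change the extracted values
  tab_rev <- assemble_feature_table(rev(coh$cases), coh$atlas_mni, coh$atlas_ho)
  expect_equal(tab_rev[match(tab$case_id, tab_rev$case_id), ], tab,
               ignore_attr = TRUE)

  # incomplete case is dropped with a warning
  broken <- coh$cases
  broken[[4]]$channels$Gd <- NULL
  expect_warning(tab2 <- assemble_feature_table(broken, coh$atlas_mni,
                                                coh$atlas_ho), "excluded")
  expect_equal(nrow(tab2), 11L)
  expect_false(broken[[4]]$case_id %in% tab2$case_id)

  # empty cohort keeps the header
  empty <- assemble_feature_table(list(), coh$atlas_mni, coh$atlas_ho)
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty), names(tab))
})

test_that("ANOVA screen matches the textbook F computation and bins p-values", {
  # hand-sized three-group oracle
  y <- c(1.1, 2.0, 1.4, 5.2, 4.8, 5.9, 9.1, 8.4, 9.9)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  gm <- mean(y)
  ssb <- sum(3 * (tapply(y, g, mean) - gm)^2)
  ssw <- sum((y - ave(y, g))^2)
  F_oracle <- (ssb / 2) / (ssw / 6)
  p_oracle <- pf(F_oracle, 2, 6, lower.tail = FALSE)

  tab <- data.frame(case_id = sprintf("c%d", 1:9),
                    institution = "i1", subtype = g,
                    T1_mean = y, T2_mean = rnorm(9), check.names = FALSE)
  res <- anova_screen(tab)
  expect_equal(res$F[res$feature == "T1_mean"], F_oracle, tolerance = 1e-9)
  expect_equal(res$p[res$feature == "T1_mean"], p_oracle, tolerance = 1e-9)

  # constant feature -> p = 1 by convention
  tab$T1_mean <- 5
  expect_warning(res2 <- anova_screen(tab), "constant")
  expect_equal(res2$p[res2$feature == "T1_mean"], 1)

  # planted 5-SD effect lands in the strongest significance bin
  set.seed(15)
  big <- data.frame(case_id = sprintf("c%d", 1:90), institution = "i1",
                    subtype = rep(c("a", "b", "c"), each = 30),
                    T1_mean = rnorm(90) + 5 * rep(c(0, 1, 0), each = 30),
                    check.names = FALSE)
  res3 <- anova_screen(big)
  expect_equal(as.character(res3$bin), "<0.001")

  expect_error(anova_screen(tab[1:4, ]), "at least 2")
})

test_that("correlation matrix is Pearson with the constant-column convention", {
  set.seed(16)
  n <- 20
  tab <- data.frame(case_id = sprintf("c%d", 1:n), institution = "i1",
                    subtype = "a",
                    T1_mean = rnorm(n), T2_mean = rnorm(n),
                    FLAIR_mean = rnorm(n), check.names = FALSE)
  tab$Gd_mean <- tab$T1_mean  # duplicated column
  cm <- correlation_matrix(tab)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 4))
  expect_equal(cm["T1_mean", "Gd_mean"], 1)

  # direct covariance-based oracle
  x <- tab$T2_mean; y <- tab$FLAIR_mean
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm["T2_mean", "FLAIR_mean"], r_oracle, tolerance = 1e-9)

  tab$FLAIR_mean <- 3
  expect_warning(cm2 <- correlation_matrix(tab), "constant")
  expect_true(all(cm2["FLAIR_mean", ] == 0))
  expect_error(correlation_matrix(tab[1, ]), "at least 2")
})
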