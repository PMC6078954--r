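test_that("institution-balanced split hits exact totals via largest remainder", {
  tab <- simulate_null_feature_table(169, 11, seed = 71)
  sp <- institution_balanced_split(tab, seed = 1)
  expect_length(sp$train, 111L)
  expect_length(sp$validation, 58L)
  expect_setequal(c(sp$train, sp$validation), tab$case_id)
  expect_length(intersect(sp$train, sp$validation), 0L)

  # per-institution counts stay within 1 of the exact share
  inst <- setNames(tab$institution, tab$case_id)
  for (i in unique(tab$institution)) {
    n_i <- sum(tab$institution == i)
    got <- sum(inst[sp$train] == i)
    expect_lt(abs(got - n_i * 111 / 169), 1)
  }

  # largest-remainder arithmetic on a single institution
  one <- data.frame(case_id = sprintf("c%d", 1:10), institution = "x")
  sp2 <- institution_balanced_split(one, train_fraction = 0.657, seed = 2)
  expect_length(sp2$train, 7L)
  expect_length(sp2$validation, 3L)

  expect_error(institution_balanced_split(one[0, ]), "empty")
  expect_error(institution_balanced_split(one, train_fraction = 1.2), "train_fraction")
})

test_that("LASSO path behaves: full shrinkage empty, planted signal selected", {
  tab <- simulate_null_feature_table(120, 6, seed = 72)
  X <- as.matrix(tab[, radglioma:::feature_columns(tab)])
  y <- factor(tab$subtype == "IDHwt", labels = c("neg", "pos"))

  fit <- fit_lasso_cv(X, y, family = "binomial", seed = 1)
  expect_gt(fit$lambda_min, 0)
  # at the top of the path (lambda_max) nothing is selected
  cf_top <- glmnet::coef.glmnet(fit$cv_fit$glmnet.fit,
                                s = max(fit$cv_fit$lambda))
  expect_length(setdiff(rownames(cf_top)[as.vector(cf_top != 0)],
                        "(Intercept)"), 0L)
  # active-set size grows (near-)monotonically as lambda decreases;
  # single-feature exchanges at a knot are a real property of the path
  path_sizes <- as.vector(fit$cv_fit$nzero)
  expect_equal(path_sizes[1], 0L)
  expect_true(all(diff(path_sizes) >= -1))
  expect_gt(cor(seq_along(path_sizes), path_sizes, method = "spearman"), 0.9)

  # planted 5-SD feature is picked up in most seeded runs
  X2 <- X
  X2[, "T2_mean"] <- X2[, "T2_mean"] + 5 * (y == "pos")
  hits <- 0L
  for (s in 1:10)
    if ("T2_mean" %in% fit_lasso_cv(X2, y, family = "binomial", seed = s)$selected)
      hits <- hits + 1L
  expect_gte(hits, 9L)

  expect_error(fit_lasso_cv(X, factor(rep("a", 120))), "single class")
  expect_error(fit_lasso_cv(X[1:8, ], y[1:8], n_folds = 10), "folds")
})

test_that("refit and metrics: separable data, identities, row conservation", {
  set.seed(73)
  n <- 80
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(ifelse(X[, 1] > 0, "b", "a"))
  X[, 1] <- X[, 1] + 3 * (y == "b")  # widely separable
  fit <- fit_lasso_cv(X, y, family = "binomial", seed = 1)
  ev <- refit_and_evaluate(fit, X, y, X, y)
  expect_equal(ev$train$accuracy, 1.0)
  expect_equal(ev$validation$accuracy, 1.0)

  # metric identities against a hand confusion matrix
  truth <- factor(c("p", "p", "p", "n", "n", "n", "n", "p"), levels = c("n", "p"))
  pred <- factor(c("p", "n", "p", "n", "p", "n", "n", "p"), levels = c("n", "p"))
  m <- classification_metrics(truth, pred, positive = "p")
  expect_equal(m$accuracy, 6 / 8)
  expect_equal(m$sensitivity, 3 / 4)
  expect_equal(m$specificity, 3 / 4)
  expect_equal(m$ppv, 3 / 4)
  expect_equal(m$npv, 3 / 4)
  expect_equal(unname(rowSums(m$confusion)), c(4, 4))  # truth counts

  # intercept-only fallback predicts the majority class
  fit0 <- fit
  fit0$selected <- character(0)
  ev0 <- refit_and_evaluate(fit0, X, y, X, y)
  expect_equal(length(unique(ev0$predictions$validation)), 1L)
})

test_that("3-class chain is near chance on label-shuffled data", {
  accs <- numeric(6)
  for (r in 1:6) {
    tab <- simulate_null_feature_table(169, 11, seed = 80 + r)
    sp <- institution_balanced_split(tab, seed = r)
    one <- radglioma:::run_model_once(tab, "subtype_3class", TRUE, sp, seed = r)
    accs[r] <- one$validation$accuracy
    # confusion-matrix row sums equal the true class counts
    y_val <- radglioma:::task_labels(tab, "subtype_3class")[
      match(sp$validation, tab$case_id)]
    expect_equal(unname(rowSums(one$validation$confusion)),
                 as.vector(table(y_val)))
  }
  expect_gt(mean(accs), 0.23)
  expect_lt(mean(accs), 0.43)
})

test_that("atlas choice per task keeps one occupancy block only", {
  tab <- simulate_null_feature_table(30, 3, seed = 74)
  f_idh <- radglioma:::task_feature_columns(tab, "idh_binary", TRUE)
  expect_true(any(grepl("^MNI_str_loc", f_idh)))
  expect_false(any(grepl("^HrvdOxf_loc", f_idh)))
  f_3c <- radglioma:::task_feature_columns(tab, "subtype_3class", TRUE)
  expect_true(any(grepl("^HrvdOxf_loc", f_3c)))
  expect_false(any(grepl("^MNI_str_loc", f_3c)))
  f_off <- radglioma:::task_feature_columns(tab, "idh_binary", FALSE)
  expect_false(any(grepl("loc\\.", f_off)))
  expect_length(f_idh, 50 + 10)
  expect_length(f_off, 50)
})

test_that("repeated comparison is degenerate for identical arms and errors on n_rep=1", {
  expect_equal(mcnemar_exact_p(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1)
  b <- 7; cc <- 1
  p_oracle <- binom.test(b, b + cc, 0.5)$p.value
  expect_equal(mcnemar_exact_p(c(rep(TRUE, b), rep(FALSE, cc), TRUE),
                               c(rep(FALSE, b), rep(TRUE, cc), TRUE)),
               p_oracle)
  tab <- simulate_null_feature_table(40, 4, seed = 75)
  expect_error(repeat_and_compare(tab, "idh_binary", n_rep = 1), "2 repetitions")
})
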