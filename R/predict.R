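#' Institution-balanced train/validation split
#'
#' Randomly partitions the cohort while balancing institutions: each
#' institution contributes `round(n_i * train_fraction)` training cases
#' up to largest-remainder adjustment, so the total training size equals
#' `round(N * train_fraction)` exactly. With the default fraction a
#' 169-case cohort splits into 111 training and 58 validation cases.
#'
#' @param manifest data.frame with `case_id` and `institution`.
#' @param train_fraction fraction of cases assigned to training
#'   (default 111/169).
#' @param seed RNG seed for the within-institution assignment.
#' @return list with `train` and `validation` case-id vectors.
#' @export
institution_balanced_split <- function(manifest, train_fraction = 111 / 169,
                                       seed = 1L) {
  if (nrow(manifest) == 0) stop("empty manifest")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  inst <- factor(manifest$institution)
  n_i <- tabulate(inst)
  total <- round(nrow(manifest) * train_fraction)
  q <- n_i * train_fraction
  alloc <- floor(q)
  rem <- total - sum(alloc)
  if (rem > 0) {
    extra <- order(q - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  } else if (rem < 0) {
    cut <- order(q - alloc)[seq_len(-rem)]
    alloc[cut] <- alloc[cut] - 1
  }
  train <- character(0)
  for (li in seq_along(levels(inst))) {
    ids <- manifest$case_id[inst == levels(inst)[li]]
    train <- c(train, sample(ids, alloc[li]))
  }
  list(train = sort(train),
       validation = sort(setdiff(manifest$case_id, train)))
}

#' L1-penalized logistic fit with cross-validated lambda
#'
#' LASSO feature selection via glmnet: binomial logistic regression for
#' the IDH task, multinomial logit for the 3-subtype task. The penalty is
#' chosen at `lambda.min`, the value minimizing the k-fold
#' cross-validated deviance; selected features are those with a nonzero
#' coefficient there (union over classes for multinomial). Features are
#' standardized internally on the training data.
#'
#' @param X numeric matrix or data.frame of features (cases x features).
#' @param y labels (2 or 3 classes).
#' @param family `"binomial"` or `"multinomial"`.
#' @param n_folds number of CV folds.
#' @param seed RNG seed for the fold assignment.
#' @return list with `selected` (feature names), `coefficients`,
#'   `lambda_min`, `family`, and the cv.glmnet object.
#' @export
fit_lasso_cv <- function(X, y, family = c("binomial", "multinomial"),
                         n_folds = 10L, seed = 1L) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing values in features")
  y <- factor(y)
  if (nlevels(y) < 2) stop("y has a single class")
  if (n_folds > nrow(X)) stop("more folds than samples")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  cv <- glmnet::cv.glmnet(X, y, family = family, nfolds = n_folds,
                          type.measure = "deviance", standardize = TRUE)
  cf <- glmnet::coef.glmnet(cv$glmnet.fit, s = cv$lambda.min)
  if (family == "multinomial") {
    nz <- unique(unlist(lapply(cf, function(m) rownames(m)[as.vector(m != 0)])))
  } else {
    nz <- rownames(cf)[as.vector(cf != 0)]
  }
  selected <- setdiff(nz, "(Intercept)")
  list(selected = selected, coefficients = cf, lambda_min = cv$lambda.min,
       family = family, cv_fit = cv, levels = levels(y))
}

majority_class <- function(y) names(which.max(table(y)))

#' Refit on selected features and evaluate
#'
#' Unpenalized refit of the model on the LASSO-selected features
#' (logistic for 2 classes, multinomial logit for 3), then evaluation on
#' the training and validation sets: accuracy, sensitivity, specificity,
#' PPV and NPV for the binary task; accuracy and the confusion matrix
#' for the 3-class task. If no feature was selected the model predicts
#' the training majority class. Classes are predicted by maximum
#' posterior probability (threshold 0.5 for binary).
#'
#' @param fit result of [fit_lasso_cv()].
#' @param X_train,y_train,X_val,y_val training and validation data.
#' @param positive for the binary task, the class treated as positive
#'   (default: the second factor level).
#' @return list with `train` and `validation` metric lists (see
#'   [classification_metrics()]) and the predicted labels.
#' @export
refit_and_evaluate <- function(fit, X_train, y_train, X_val, y_val,
                               positive = NULL) {
  y_train <- factor(y_train, levels = fit$levels)
  y_val <- factor(y_val, levels = fit$levels)
  if (any(is.na(y_val))) stop("validation contains a class absent at refit")
  sel <- fit$selected
  if (length(sel) == 0) {
    maj <- majority_class(y_train)
    pred_tr <- factor(rep(maj, nrow(X_train)), levels = fit$levels)
    pred_va <- factor(rep(maj, nrow(X_val)), levels = fit$levels)
  } else {
    dtr <- data.frame(.y = y_train, as.data.frame(X_train)[, sel, drop = FALSE],
                      check.names = FALSE)
    dva <- as.data.frame(X_val)[, sel, drop = FALSE]
    if (nlevels(y_train) == 2) {
      m <- suppressWarnings(stats::glm(.y ~ ., data = dtr, family = stats::binomial()))
      pr_tr <- suppressWarnings(stats::predict(m, type = "response"))
      pr_va <- suppressWarnings(stats::predict(m, newdata = dva, type = "response"))
      pred_tr <- factor(fit$levels[1 + (pr_tr > 0.5)], levels = fit$levels)
      pred_va <- factor(fit$levels[1 + (pr_va > 0.5)], levels = fit$levels)
    } else {
      cap <- utils::capture.output(
        m <- nnet::multinom(.y ~ ., data = dtr, trace = FALSE, maxit = 200))
      pred_tr <- factor(stats::predict(m), levels = fit$levels)
      pred_va <- factor(stats::predict(m, newdata = dva), levels = fit$levels)
    }
  }
  list(train = classification_metrics(y_train, pred_tr, positive),
       validation = classification_metrics(y_val, pred_va, positive),
       predictions = list(train = pred_tr, validation = pred_va))
}

#' Classification metrics from truth and prediction
#'
#' Binary: accuracy, sensitivity, specificity, PPV, NPV and the 2x2
#' confusion matrix. Multiclass: accuracy and the confusion matrix
#' (rows = truth, so row sums equal the true class counts).
#'
#' @param truth,pred factors on the same levels.
#' @param positive positive class for the binary metrics (default: last
#'   level).
#' @return list of metrics.
#' @export
classification_metrics <- function(truth, pred, positive = NULL) {
  truth <- factor(truth); pred <- factor(pred, levels = levels(truth))
  cm <- table(truth = truth, predicted = pred)
  acc <- sum(diag(cm)) / sum(cm)
  out <- list(accuracy = acc, confusion = cm)
  if (nlevels(truth) == 2) {
    if (is.null(positive)) positive <- levels(truth)[2]
    tp <- sum(truth == positive & pred == positive)
    tn <- sum(truth != positive & pred != positive)
    fp <- sum(truth != positive & pred == positive)
    fn <- sum(truth == positive & pred != positive)
    div <- function(a, b) if (b > 0) a / b else NA_real_
    out <- c(out, list(sensitivity = div(tp, tp + fn),
                       specificity = div(tn, tn + fp),
                       ppv = div(tp, tp + fp),
                       npv = div(tn, tn + fn),
                       positive = positive))
  }
  out
}

#' Exact McNemar test on paired predictions
#'
#' Exact binomial test on the discordant pairs of two classifiers
#' evaluated on the same cases (correct/incorrect per case).
#'
#' @param correct_a,correct_b logical vectors, same length.
#' @return two-sided p-value.
#' @export
mcnemar_exact_p <- function(correct_a, correct_b) {
  b <- sum(correct_a & !correct_b)
  c <- sum(!correct_a & correct_b)
  if (b + c == 0) return(1)
  stats::binom.test(b, b + c, 0.5)$p.value
}

task_feature_columns <- function(table, task, location) {
  feats <- feature_columns(table)
  occ <- grepl("^(MNI_str_loc|HrvdOxf_loc)\\.", feats)
  if (!location) return(feats[!occ])
  # atlas choice mirrors the modeling design: the binary IDH task uses
  # the 10-label structural occupancies (deep white matter retained),
  # the 3-class task the 49-label cortical occupancies; never both
  keep <- if (task == "idh_binary") "^MNI_str_loc\\." else "^HrvdOxf_loc\\."
  feats[!occ | grepl(keep, feats)]
}

task_labels <- function(table, task) {
  if (task == "idh_binary") {
    factor(ifelse(table$subtype == "IDHwt", "IDHwt", "IDHmt"),
           levels = c("IDHwt", "IDHmt"))
  } else {
    factor(table$subtype, levels = subtype_levels())
  }
}

run_model_once <- function(table, task, location, split, n_folds = 10L,
                           seed = 1L) {
  feats <- task_feature_columns(table, task, location)
  y <- task_labels(table, task)
  rownames(table) <- table$case_id
  tr <- match(split$train, table$case_id)
  va <- match(split$validation, table$case_id)
  X <- as.matrix(table[, feats, drop = FALSE])
  family <- if (task == "idh_binary") "binomial" else "multinomial"
  positive <- if (task == "idh_binary") "IDHmt" else NULL
  fit <- fit_lasso_cv(X[tr, , drop = FALSE], y[tr], family = family,
                      n_folds = n_folds, seed = seed)
  ev <- refit_and_evaluate(fit, X[tr, , drop = FALSE], y[tr],
                           X[va, , drop = FALSE], y[va], positive = positive)
  c(ev, list(fit = fit, split = split, task = task, location = location))
}

#' Repeated modeling with and without location features
#'
#' Runs the split / LASSO-select / refit / evaluate chain `n_rep` times
#' with fresh institution-balanced splits, once with the task's
#' atlas-occupancy location features and once without (texture + shape
#' only), and summarizes each metric as mean and SD over repetitions.
#' The two arms share each repetition's split, and their pooled
#' validation predictions are compared with an exact McNemar test.
#'
#' @param table feature table (see [assemble_feature_table()]).
#' @param task `"idh_binary"` or `"subtype_3class"`.
#' @param n_rep number of repetitions (study value: 5).
#' @param train_fraction,n_folds modeling parameters.
#' @param seed master seed; repetition r uses `seed + r`.
#' @return list with per-arm repetition metrics, `summary` (mean/sd per
#'   metric), and `comparison_p`.
#' @export
repeat_and_compare <- function(table, task = c("idh_binary", "subtype_3class"),
                               n_rep = 5L, train_fraction = 111 / 169,
                               n_folds = 10L, seed = 1L) {
  task <- match.arg(task)
  if (n_rep < 2) stop("need >= 2 repetitions")
  arms <- list(location_on = TRUE, location_off = FALSE)
  res <- list(location_on = list(), location_off = list())
  correct <- list(location_on = logical(0), location_off = logical(0))
  for (r in seq_len(n_rep)) {
    split <- institution_balanced_split(table, train_fraction, seed = seed + r)
    y_val <- task_labels(table, task)[match(split$validation, table$case_id)]
    for (arm in names(arms)) {
      one <- run_model_once(table, task, arms[[arm]], split,
                            n_folds = n_folds, seed = seed + r)
      res[[arm]][[r]] <- one
      correct[[arm]] <- c(correct[[arm]],
                          one$predictions$validation == y_val)
    }
  }
  metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  summarize <- function(arm, set) {
    vals <- sapply(metric_names, function(mn)
      vapply(res[[arm]], function(one) {
        v <- one[[set]][[mn]]
        if (is.null(v)) NA_real_ else v
      }, numeric(1)))
    data.frame(metric = metric_names,
               mean = colMeans(vals, na.rm = FALSE),
               sd = apply(vals, 2, stats::sd))
  }
  summary <- list()
  for (arm in names(arms)) for (set in c("train", "validation"))
    summary[[paste(arm, set, sep = ".")]] <- summarize(arm, set)
  list(results = res, summary = summary,
       comparison_p = mcnemar_exact_p(correct$location_on,
                                      correct$location_off),
       task = task, n_rep = n_rep)
}
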