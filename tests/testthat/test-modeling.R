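# Learners, cross-validation and greedy forward selection on controlled
# synthetic tabular data (chemistry-free for speed).

# small classification frame: f_signal separates classes, the rest is noise
make_classif <- function(n = 120, p_noise = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x <- as.data.frame(matrix(rnorm(n * p_noise), n,
                            dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  x$f_signal <- y + rnorm(n, 0, 0.05)
  x$label <- ifelse(y == 1, "active", "inactive")
  tibble::as_tibble(x)
}

test_that("constant-target regression predicts the constant", {
  d <- tibble::tibble(a = rnorm(30), b = rnorm(30), y = 5)
  for (lr in c("random_forest", "extra_trees", "knn")) {
    fit <- suppressWarnings(train_model(d, "y", "regression", learner = lr,
                                        seed = 1, num_trees = 30))
    expect_equal(predict(fit, d)$.pred, rep(5, 30), tolerance = 1e-8,
                 label = lr)
  }
})

test_that("same seed and data reproduce identical predictions", {
  d <- make_classif(seed = 3)
  for (lr in c("random_forest", "extra_trees", "gradient_boosting", "xgb", "knn")) {
    f1 <- train_model(d, "label", "classification", learner = lr, seed = 7,
                      num_trees = 40)
    f2 <- train_model(d, "label", "classification", learner = lr, seed = 7,
                      num_trees = 40)
    expect_identical(predict(f1, d)$.pred, predict(f2, d)$.pred, label = lr)
  }
})

test_that("model bundles round-trip through serialization", {
  d <- make_classif(seed = 5)
  fit <- train_model(d, "label", "classification", learner = "random_forest",
                     seed = 11, num_trees = 50)
  path <- tempfile(fileext = ".rds")
  save_model(fit, path)
  expect_true(file.exists(sub("\\.rds$", ".json", path)))
  restored <- load_model(path)
  expect_identical(predict(restored, d)$.pred, predict(fit, d)$.pred)
  expect_identical(restored$config_hash, fit$config_hash)
})

test_that("non-finite features and missing columns are rejected by name", {
  d <- make_classif(seed = 2)
  d$noise1[3] <- NA
  expect_error(train_model(d, "label", "classification"), "noise1")
  d2 <- make_classif(seed = 2)
  fit <- train_model(d2, "label", "classification", num_trees = 20)
  expect_error(predict(fit, d2[, c("noise2", "label")]), "missing")
})

test_that("cross-validation predicts every sample once in balanced folds", {
  d <- make_classif(n = 103, seed = 8)
  cv <- cross_validate(d, "label", "classification", learner = "extra_trees",
                       k = 10, seed = 2, num_trees = 50)
  expect_equal(nrow(cv$oof), 103)
  expect_true(all(table(cv$oof$fold) %in% c(10, 11)))
  sizes <- table(cv$oof$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  # near-perfect single informative feature drives AUC to 1
  expect_gte(cv$pooled$auc, 0.99)
  expect_gte(cv$pooled$accuracy, 0.95)
})

test_that("stratification failure on tiny unbalanced data is reported", {
  d <- tibble::tibble(a = rnorm(12), b = rnorm(12),
                      label = c(rep("active", 2), rep("inactive", 10)))
  expect_error(cross_validate(d, "label", "classification", k = 10, seed = 1,
                              num_trees = 10),
               "stratification|absent")
})

test_that("greedy selection finds the planted informative feature", {
  d <- make_classif(n = 100, p_noise = 20, seed = 13)
  sel <- greedy_select(d, "label", "classification", learner = "extra_trees",
                       cv_folds = 5, seed = 4, patience = 2, num_trees = 40,
                       max_features = 5)
  expect_true("f_signal" %in% sel$best_set)
  expect_gte(sel$best_metric, 0.99)
})

test_that("greedy selection matches a step-by-step forward oracle", {
  # 8 features, exhaustive forward selection with the same cv routine
  set.seed(17)
  n <- 60
  x <- as.data.frame(matrix(rnorm(n * 8), n,
                            dimnames = list(NULL, paste0("f", 1:8))))
  y <- x$f2 + 0.8 * x$f5 + rnorm(n, 0, 0.4)
  d <- tibble::as_tibble(cbind(x, y = y))

  sel <- greedy_select(d, "y", "regression", learner = "knn", cv_folds = 5,
                       seed = 9, patience = Inf, tolerance = 0,
                       num_trees = 10)
  # oracle: independent forward pass using cross_validate at each step
  chosen <- character(0)
  remaining <- paste0("f", 1:8)
  trace_metric <- numeric(0)
  while (length(remaining) > 0) {
    vals <- vapply(remaining, function(f) {
      cv <- cross_validate(d, "y", "regression", learner = "knn",
                           features = c(chosen, f), k = 5, seed = 9,
                           num_trees = 10)
      cv$pooled$pearson
    }, numeric(1))
    pick <- which.max(vals)
    chosen <- c(chosen, remaining[pick])
    trace_metric <- c(trace_metric, vals[pick])
    remaining <- remaining[-pick]
  }
  expect_equal(sel$trace$feature, chosen)
  expect_equal(sel$trace$metric, unname(trace_metric), tolerance = 1e-10)
  expect_equal(sel$best_set, chosen[seq_len(which.max(trace_metric))])
})

test_that("best-so-far selection metric is non-decreasing", {
  d <- make_classif(n = 80, p_noise = 10, seed = 23)
  sel <- greedy_select(d, "label", "classification", learner = "knn",
                       cv_folds = 5, seed = 3, patience = 3, num_trees = 10)
  best_so_far <- cummax(sel$trace$metric)
  expect_true(all(diff(best_so_far) >= 0))
  expect_equal(sel$best_metric, max(sel$trace$metric))
})

test_that("degenerate targets are rejected before any fitting", {
  d <- tibble::tibble(a = rnorm(20), b = rnorm(20), label = "active")
  expect_error(greedy_select(d, "label", "classification"), "degenerate")
  d2 <- tibble::tibble(a = rnorm(20), b = rnorm(20), y = 1)
  expect_error(greedy_select(d2, "y", "regression"), "degenerate")
})

test_that("cv Pearson rises as planted-signal noise falls", {
  aucs <- vapply(c(1.5, 0.6, 0.1), function(sigma) {
    set.seed(31)
    n <- 80
    x <- as.data.frame(matrix(rnorm(n * 5), n,
                              dimnames = list(NULL, paste0("s", 1:5))))
    y <- rowSums(x) + rnorm(n, 0, sigma)
    d <- tibble::as_tibble(cbind(x, y = y))
    cv <- cross_validate(d, "y", "regression", learner = "extra_trees",
                         k = 5, seed = 6, num_trees = 60)
    cv$pooled$pearson
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})
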