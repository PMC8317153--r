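# Learner abstraction, cross-validation, greedy forward feature selection
# and model bundles. Learners are established implementations (randomForest,
# ranger extra-trees, xgboost, k-nearest neighbors); hyperparameters are
# library defaults with a fixed tree count and explicit seed.

.LEARNERS <- c("random_forest", "extra_trees", "gradient_boosting", "xgb", "knn")

.check_matrix <- function(x) {
  bad <- colnames(x)[!apply(x, 2, function(v) all(is.finite(v)))]
  if (length(bad) > 0) {
    abort(sprintf("non-finite values in feature column(s): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
}

.fit_learner <- function(x, y, task, learner, seed, num_trees) {
  learner <- match.arg(learner, .LEARNERS)
  classif <- task == "classification"
  set.seed(seed)
  fit <- switch(learner,
    random_forest = randomForest::randomForest(
      x = x, y = if (classif) factor(y, levels = c(0, 1)) else y,
      ntree = num_trees),
    extra_trees = ranger::ranger(
      x = x, y = if (classif) factor(y, levels = c(0, 1)) else y,
      num.trees = num_trees, splitrule = "extratrees",
      probability = classif, seed = seed, num.threads = 1),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = if (classif) "binary:logistic" else "reg:squarederror",
                    eta = 0.1, max_depth = 3, subsample = 0.8, nthread = 1,
                    seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = num_trees),
    xgb = xgboost::xgb.train(
      params = list(objective = if (classif) "binary:logistic" else "reg:squarederror",
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = num_trees),
    knn = list(x = x, y = y, k = 5)  # lazy learner: keep the training set
  )
  structure(list(fit = fit, learner = learner, task = task,
                 features = colnames(x), seed = seed),
            class = "molsig_fit")
}

.predict_learner <- function(object, newx) {
  stopifnot(inherits(object, "molsig_fit"))
  newx <- newx[, object$features, drop = FALSE]
  classif <- object$task == "classification"
  switch(object$learner,
    random_forest = if (classif) {
      unname(predict(object$fit, newx, type = "prob")[, "1"])
    } else unname(predict(object$fit, newx)),
    extra_trees = {
      p <- predict(object$fit, data = as.data.frame(newx))$predictions
      if (classif) unname(p[, "1"]) else unname(p)
    },
    gradient_boosting = ,
    xgb = unname(predict(object$fit, xgboost::xgb.DMatrix(newx))),
    knn = {
      if (classif) {
        cl <- factor(object$fit$y, levels = c(0, 1))
        pr <- class::knn(object$fit$x, newx, cl, k = object$fit$k, prob = TRUE)
        win <- attr(pr, "prob")
        unname(ifelse(pr == "1", win, 1 - win))
      } else {
        fit <- caret::knnreg(object$fit$x, object$fit$y, k = object$fit$k)
        unname(predict(fit, as.data.frame(newx)))
      }
    })
}

# stratified (classification) or plain (regression) k-fold assignment
.make_folds <- function(y, k, seed, task) {
  n <- length(y)
  if (n < k) abort(sprintf("n = %d is smaller than k = %d folds", n, k))
  set.seed(seed)
  fold <- integer(n)
  if (task == "classification") {
    # round-robin continuing across classes: global fold sizes differ by <= 1
    # while each class stays as evenly spread as possible
    f <- 0L
    for (cls in sort(unique(y))) {
      for (idx in sample(which(y == cls))) {
        f <- (f %% k) + 1L
        fold[idx] <- f
      }
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

.feature_cols <- function(data, response, features) {
  pool <- setdiff(names(data), c(response, "mol_id", "smiles"))
  pool <- pool[vapply(data[pool], is.numeric, logical(1))]
  if (is.null(features)) return(pool)
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(sprintf("feature(s) not in data: %s", paste(head(missing, 10), collapse = ", ")))
  }
  features
}

.response_vector <- function(data, response, task, positive) {
  y <- data[[response]]
  if (is.null(y)) abort(sprintf("response column '%s' not found", response))
  if (task == "classification") {
    y <- .as_binary(y, positive)
    if (length(unique(y)) < 2) abort("degenerate target: fewer than 2 classes")
  } else {
    if (!is.numeric(y)) abort("regression response must be numeric")
  }
  y
}

# out-of-fold cv metric for one feature set; folds precomputed
.cv_metric <- function(x, y, fold, task, learner, seed, num_trees, metric) {
  oof <- numeric(length(y))
  for (f in sort(unique(fold))) {
    te <- fold == f
    fit <- .fit_learner(x[!te, , drop = FALSE], y[!te], task, learner,
                        seed, num_trees)
    oof[te] <- .predict_learner(fit, x[te, , drop = FALSE])
  }
  if (metric == "auc") .auc_rank(y, oof)
  else suppressWarnings(cor(y, oof))
}

#' K-fold cross-validation
#'
#' Stratified (classification) or plain (regression) k-fold
#' cross-validation; every sample is predicted exactly once out-of-fold.
#' Headline metrics are pooled over the out-of-fold predictions; per-fold
#' metrics are also reported.
#'
#' @param data Data frame of features plus the response column (an optional
#'   `mol_id`/`smiles` column is ignored as a feature).
#' @param response Name of the response column.
#' @param task `"classification"` or `"regression"`.
#' @param learner One of `"random_forest"`, `"extra_trees"`,
#'   `"gradient_boosting"`, `"xgb"`, `"knn"`.
#' @param features Optional character vector restricting the feature set.
#' @param k Number of folds (default 10).
#' @param seed Random seed controlling fold assignment and learner fits.
#' @param num_trees Trees/boosting rounds for tree ensembles (default 300).
#' @param positive Positive class label for factor/character responses.
#' @return An object of class `molsig_cv`: list with `pooled` (one-row
#'   tibble), `per_fold` (tibble), `oof` (tibble: `row`, `fold`, `y_true`,
#'   `y_score`), plus the run configuration.
#' @export
cross_validate <- function(data, response, task = c("classification", "regression"),
                           learner = "random_forest", features = NULL, k = 10,
                           seed = 42, num_trees = 300, positive = "active") {
  task <- match.arg(task)
  feats <- .feature_cols(data, response, features)
  if (length(feats) < 1) abort("no feature columns found")
  y <- .response_vector(data, response, task, positive)
  x <- as.matrix(data[feats])
  .check_matrix(x)
  fold <- .make_folds(y, k, seed, task)
  if (task == "classification") {
    for (f in seq_len(k)) {
      if (length(unique(y[fold == f])) < 2 || length(unique(y[fold != f])) < 2) {
        abort(sprintf("stratification failure: a class is absent from fold %d (n too small for %d folds)", f, k))
      }
    }
  }
  oof <- numeric(length(y))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- fold == f
    fit <- .fit_learner(x[!te, , drop = FALSE], y[!te], task, learner, seed, num_trees)
    oof[te] <- .predict_learner(fit, x[te, , drop = FALSE])
    per_fold[[f]] <- bind_cols(tibble(fold = f),
                               evaluate_metrics(y[te], oof[te], task))
  }
  structure(list(
    pooled = evaluate_metrics(y, oof, task),
    per_fold = bind_rows(per_fold),
    oof = tibble(row = seq_along(y), fold = fold, y_true = y, y_score = oof),
    task = task, learner = learner, k = k, seed = seed,
    num_trees = num_trees, features = feats
  ), class = "molsig_cv")
}

#' @export
print.molsig_cv <- function(x, ...) {
  cat(sprintf("<molsig_cv> %s / %s, %d-fold, %d features\n",
              x$task, x$learner, x$k, length(x$features)))
  print(x$pooled)
  invisible(x)
}

#' @method tidy molsig_cv
#' @export
tidy.molsig_cv <- function(x, ...) x$per_fold

#' @method glance molsig_cv
#' @export
glance.molsig_cv <- function(x, ...) {
  bind_cols(tibble(task = x$task, learner = x$learner, k = x$k,
                   n_features = length(x$features), seed = x$seed), x$pooled)
}

#' ROC curve / prediction scatter for a cross-validation result
#'
#' Classification results are drawn as the out-of-fold ROC curve;
#' regression results as predicted vs observed.
#'
#' @param object A `molsig_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot molsig_cv
#' @export
autoplot.molsig_cv <- function(object, ...) {
  oof <- object$oof
  if (object$task == "classification") {
    ord <- order(-oof$y_score)
    y <- oof$y_true[ord]
    roc <- tibble(fpr = c(0, cumsum(y == 0) / max(sum(y == 0), 1)),
                  tpr = c(0, cumsum(y == 1) / max(sum(y == 1), 1)))
    ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = 2, color = "grey60") +
      ggplot2::labs(x = "false positive rate", y = "true positive rate",
                    title = sprintf("Out-of-fold ROC (AUC = %.3f)",
                                    object$pooled$auc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(oof, ggplot2::aes(.data$y_true, .data$y_score)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_abline(linetype = 2, color = "grey60") +
      ggplot2::labs(x = "observed", y = "out-of-fold prediction",
                    title = sprintf("Pearson = %.3f", object$pooled$pearson)) +
      ggplot2::theme_minimal()
  }
}

#' Greedy forward feature selection
#'
#' Starts from zero features; each round evaluates adding every remaining
#' candidate to the current set by out-of-fold cross-validated metric (AUC
#' for classification, Pearson for regression), accepts the argmax (ties
#' resolved in manifest order), and stops after `patience` consecutive
#' rounds without an improvement greater than `tolerance`. The returned
#' best set is the prefix of accepted features achieving the maximum
#' recorded metric.
#'
#' @inheritParams cross_validate
#' @param metric `"auc"` or `"pearson"`; defaults by task.
#' @param cv_folds Folds for the selection cross-validation (default 10).
#' @param patience Rounds without improvement before stopping (default 5).
#' @param tolerance Minimal improvement that resets patience (default 1e-4).
#' @param max_features Hard cap on accepted features (default `Inf`).
#' @return An object of class `molsig_selection`: list with `trace`
#'   (tibble: `step`, `feature`, `metric`), `best_set`, `best_metric`,
#'   `metric_name` and the run configuration.
#' @export
greedy_select <- function(data, response, task = c("classification", "regression"),
                          learner = "extra_trees", metric = NULL, features = NULL,
                          cv_folds = 10, seed = 42, patience = 5,
                          tolerance = 1e-4, max_features = Inf,
                          num_trees = 100, positive = "active") {
  task <- match.arg(task)
  metric <- metric %||% if (task == "classification") "auc" else "pearson"
  metric <- match.arg(metric, c("auc", "pearson"))
  feats <- .feature_cols(data, response, features)
  if (length(feats) < 2) abort("need at least 2 candidate features")
  y <- .response_vector(data, response, task, positive)
  if (task == "regression" && sd(y) == 0) abort("degenerate target: constant response")
  x <- as.matrix(data[feats])
  .check_matrix(x)
  fold <- .make_folds(y, cv_folds, seed, task)

  selected <- character(0)
  remaining <- feats
  trace <- list()
  best_global <- -Inf
  stall <- 0L
  while (length(remaining) > 0 && length(selected) < max_features &&
         stall < patience) {
    vals <- vapply(remaining, function(f) {
      .cv_metric(x[, c(selected, f), drop = FALSE], y, fold, task, learner,
                 seed, num_trees, metric)
    }, numeric(1))
    vals[is.na(vals)] <- -Inf
    pick <- which.max(vals)  # first index on ties = manifest order
    selected <- c(selected, remaining[pick])
    trace[[length(trace) + 1]] <- tibble(step = length(selected),
                                         feature = unname(remaining[pick]),
                                         metric = unname(vals[pick]))
    if (vals[pick] > best_global + tolerance) {
      best_global <- vals[pick]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    remaining <- remaining[-pick]
  }
  trace <- bind_rows(trace)
  best_step <- which.max(trace$metric)
  structure(list(
    trace = trace,
    best_set = trace$feature[seq_len(best_step)],
    best_metric = trace$metric[best_step],
    metric_name = metric, task = task, learner = learner,
    cv_folds = cv_folds, seed = seed, patience = patience,
    tolerance = tolerance, num_trees = num_trees
  ), class = "molsig_selection")
}

#' @export
print.molsig_selection <- function(x, ...) {
  cat(sprintf("<molsig_selection> %d features evaluated, best %s = %.4f with %d features\n",
              nrow(x$trace), x$metric_name, x$best_metric, length(x$best_set)))
  invisible(x)
}

#' @method tidy molsig_selection
#' @export
tidy.molsig_selection <- function(x, ...) x$trace

#' @method glance molsig_selection
#' @export
glance.molsig_selection <- function(x, ...) {
  tibble(metric_name = x$metric_name, best_metric = x$best_metric,
         n_selected = length(x$best_set), n_steps = nrow(x$trace),
         learner = x$learner, cv_folds = x$cv_folds, seed = x$seed)
}

#' Selection trace plot
#'
#' @param object A `molsig_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot molsig_selection
#' @export
autoplot.molsig_selection <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$step, .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = length(object$best_set),
                        linetype = 2, color = "grey50") +
    ggplot2::labs(x = "features added", y = object$metric_name,
                  title = "Greedy forward selection trace") +
    ggplot2::theme_minimal()
}

#' Train a model bundle
#'
#' Fits the chosen learner on the full data with an explicit seed and a
#' frozen tree count, and wraps everything needed to reproduce predictions:
#' the fitted model, the ordered selected features, the seed and a
#' configuration hash. The same seed and data give identical predictions,
#' and a bundle round-trips through [save_model()]/[load_model()].
#'
#' @inheritParams cross_validate
#' @return An object of class `molsig_model`.
#' @export
train_model <- function(data, response, task = c("classification", "regression"),
                        learner = "random_forest", features = NULL, seed = 42,
                        num_trees = 300, positive = "active") {
  task <- match.arg(task)
  feats <- .feature_cols(data, response, features)
  if (length(feats) < 1) abort("no feature columns found")
  y <- .response_vector(data, response, task, positive)
  x <- as.matrix(data[feats])
  .check_matrix(x)
  fit <- .fit_learner(x, y, task, learner, seed, num_trees)
  structure(list(
    fit = fit, task = task, learner = learner, features = feats,
    response = response, positive = positive, seed = seed,
    num_trees = num_trees, n_train = nrow(x),
    config_hash = rlang::hash(list(task, learner, feats, seed, num_trees,
                                   config_hash()))
  ), class = "molsig_model")
}

#' @export
print.molsig_model <- function(x, ...) {
  cat(sprintf("<molsig_model> %s / %s: %d features, n = %d, seed = %d, config %s\n",
              x$task, x$learner, length(x$features), x$n_train, x$seed,
              substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Predict from a model bundle
#'
#' @param object A `molsig_model`.
#' @param newdata Data frame containing all of the bundle's feature columns
#'   (extra columns are ignored; features are realigned by name).
#' @param ... Unused.
#' @return A tibble with `.pred` (class-1 probability or predicted value),
#'   plus `mol_id` when present in `newdata`.
#' @export
predict.molsig_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("newdata is missing %d required feature(s): %s",
                  length(missing), paste(head(missing, 10), collapse = ", ")))
  }
  x <- as.matrix(newdata[object$features])
  .check_matrix(x)
  out <- tibble(.pred = .predict_learner(object$fit, x))
  if ("mol_id" %in% names(newdata)) {
    out <- bind_cols(tibble(mol_id = newdata$mol_id), out)
  }
  out
}

#' @method tidy molsig_model
#' @export
tidy.molsig_model <- function(x, ...) {
  imp <- switch(x$learner,
    random_forest = {
      m <- randomForest::importance(x$fit$fit)
      tibble(feature = rownames(m), importance = unname(m[, 1]))
    },
    extra_trees = {
      v <- x$fit$fit$variable.importance
      if (is.null(v)) tibble(feature = x$features, importance = NA_real_)
      else tibble(feature = names(v), importance = unname(v))
    },
    tibble(feature = x$features, importance = NA_real_))
  arrange(imp, dplyr::desc(.data$importance))
}

#' @method glance molsig_model
#' @export
glance.molsig_model <- function(x, ...) {
  tibble(task = x$task, learner = x$learner, n_features = length(x$features),
         n_train = x$n_train, seed = x$seed, num_trees = x$num_trees,
         config_hash = x$config_hash)
}

#' Save / load a model bundle
#'
#' Bundles serialize with `saveRDS`; a JSON sidecar carrying the feature
#' list, seed, configuration hash and learner is written next to the model
#' file for provenance.
#'
#' @param object A `molsig_model`.
#' @param path File path for the bundle (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `molsig_model`.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "molsig_model"))
  saveRDS(object, path)
  sidecar <- paste0(sub("\\.rds$", "", path), ".json")
  jsonlite::write_json(list(
    task = object$task, learner = object$learner, features = object$features,
    seed = object$seed, num_trees = object$num_trees,
    config_hash = object$config_hash), sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "molsig_model")) abort("file is not a molsig model bundle")
  object
}
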