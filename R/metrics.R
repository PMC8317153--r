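# Evaluation metrics. AUC is computed as the Mann-Whitney rank statistic
# (midranks for ties), MCC from the 2x2 confusion table closed form;
# correlation metrics delegate to stats::cor.

# coerce activity labels to 0/1
.as_binary <- function(y, positive = "active") {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) abort("numeric class labels must be 0/1")
    return(as.integer(y))
  }
  as.integer(as.character(y) == positive)
}

.auc_rank <- function(y, score) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.mcc <- function(tp, fp, tn, fn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(NA_real_)
  (tp * tn - fp * fn) / denom
}

#' Evaluate predictions
#'
#' Classification (binary): accuracy, precision, sensitivity (TPR), false
#' positive rate, Matthews correlation coefficient at the given score
#' threshold, plus the threshold-free AUC computed as a rank statistic over
#' score pairs. With a single observed class the AUC is reported as `NA`
#' (undefined), never 0. Regression: Pearson and Kendall correlations and
#' RMSE.
#'
#' @param y_true Observed values. For classification: logical, 0/1 numeric,
#'   or factor/character (positive class = `positive`).
#' @param y_score Predicted scores (class-1 probability for classification,
#'   predicted value for regression).
#' @param task `"classification"` or `"regression"`.
#' @param threshold Score cutoff for the confusion-table metrics.
#' @param positive Positive class label when `y_true` is factor/character.
#' @return A one-row tibble of metrics.
#' @export
#' @examples
#' evaluate_metrics(c(0, 0, 1, 1), c(.1, .4, .6, .9), "classification")
evaluate_metrics <- function(y_true, y_score, task = c("classification", "regression"),
                             threshold = 0.5, positive = "active") {
  task <- match.arg(task)
  if (length(y_true) != length(y_score)) abort("y_true and y_score lengths differ")
  if (length(y_true) < 2) abort("need at least 2 observations")
  if (task == "classification") {
    y <- .as_binary(y_true, positive)
    pred <- as.integer(y_score >= threshold)
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
    tibble(
      n = length(y),
      accuracy = (tp + tn) / length(y),
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
      mcc = .mcc(tp, fp, tn, fn),
      auc = .auc_rank(y, y_score))
  } else {
    if (!is.numeric(y_true) || !is.numeric(y_score)) {
      abort("regression metrics need numeric vectors")
    }
    tibble(
      n = length(y_true),
      pearson = if (sd(y_true) > 0 && sd(y_score) > 0)
        cor(y_true, y_score) else NA_real_,
      kendall = if (sd(y_true) > 0 && sd(y_score) > 0)
        cor(y_true, y_score, method = "kendall") else NA_real_,
      rmse = sqrt(mean((y_true - y_score)^2)))
  }
}

#' Outlier-trimmed regression metrics
#'
#' Recomputes Pearson, Kendall and RMSE after removing the
#' `ceiling(fraction * n)` points with the largest absolute residual
#' |y_true - y_pred| — i.e. performance on the data minus its worst-predicted
#' points. Among equal residuals the higher index is removed first, so the
#' lower index is retained. With fewer than 10 points trimming is refused
#' and untrimmed metrics are returned flagged `trimmed = FALSE`.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @param fraction Fraction of points to remove (default 0.10).
#' @return A one-row tibble: `trimmed`, `n_retained`, `pearson`, `kendall`,
#'   `rmse`.
#' @export
trimmed_evaluation <- function(y_true, y_pred, fraction = 0.10) {
  if (length(y_true) != length(y_pred)) abort("y_true and y_pred lengths differ")
  n <- length(y_true)
  if (n < 10) {
    warn("fewer than 10 points; returning untrimmed metrics")
    m <- evaluate_metrics(y_true, y_pred, "regression")
    return(tibble(trimmed = FALSE, n_retained = n,
                  pearson = m$pearson, kendall = m$kendall, rmse = m$rmse))
  }
  resid <- abs(y_true - y_pred)
  n_drop <- ceiling(fraction * n)
  drop <- order(-resid, -seq_len(n))[seq_len(n_drop)]
  keep <- setdiff(seq_len(n), drop)
  m <- evaluate_metrics(y_true[keep], y_pred[keep], "regression")
  tibble(trimmed = TRUE, n_retained = length(keep),
         pearson = m$pearson, kendall = m$kendall, rmse = m$rmse)
}
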