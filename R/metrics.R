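#' Classification metrics from confusion counts
#'
#' Computes accuracy and F1 directly from the four confusion counts:
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)` and
#' `F1 = 2TP / (2TP + FP + FN)`. When the F1 denominator is zero
#' (no positives anywhere) F1 is defined as 0 and flagged, so pipelines
#' stay total.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return A one-row tibble with `accuracy`, `f1` and `f1_defined`.
#' @export
#' @examples
#' classification_metrics(tp = 2, fp = 1, tn = 6, fn = 1)
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) abort("no evaluated samples (all counts zero)")
  denom <- 2 * tp + fp + fn
  tibble(
    accuracy   = (tp + tn) / total,
    f1         = if (denom == 0) 0 else 2 * tp / denom,
    f1_defined = denom > 0
  )
}

#' Weighted F1 score over classes
#'
#' Per-class F1 (one-vs-rest), averaged with weights proportional to the
#' class support in `truth`. Used to score categorical imputation models.
#' On a balanced two-class problem it equals macro F1.
#'
#' @param truth,pred Vectors of class labels (coerced to character).
#' @return A single numeric score in `[0, 1]`.
#' @export
weighted_f1 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.character(truth)
  pred <- as.character(pred)
  classes <- sort(unique(truth))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    d <- 2 * tp + fp + fn
    if (d == 0) 0 else 2 * tp / d
  }, numeric(1))
  sum(f1s * support) / sum(support)
}

#' Regression metrics
#'
#' Mean absolute error, root mean squared error and the R2 score:
#' `MAE = sum(|y - yhat|)/n`, `RMSE = sqrt(sum((y - yhat)^2)/n)`,
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`. R2 is undefined for a
#' constant target; it is then returned as `NaN` with `r2_defined = FALSE`.
#'
#' @param y Observed values.
#' @param y_hat Predicted values, same length.
#' @return A one-row tibble with `mae`, `rmse`, `r2`, `r2_defined`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(1.5, 2, 2.5))
regression_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1)
    abort("y and y_hat must have equal length >= 1")
  resid <- y - y_hat
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble(
    mae  = mean(abs(resid)),
    rmse = sqrt(mean(resid^2)),
    r2   = if (ss_tot > 0) 1 - ss_res / ss_tot else NaN,
    r2_defined = ss_tot > 0
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties counted as 1/2. Equivalent to
#' exhaustive pairwise concordance counting.
#'
#' @param labels Binary labels (0/1 or logical).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`; `NaN` (with a warning) if only one class present.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warn("AUC undefined: only one class present")
    return(NaN)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' TPR/FPR at every distinct score threshold (prediction counted positive
#' when `score >= threshold`), plus the degenerate endpoints.
#'
#' @inheritParams auc_score
#' @return A tibble with `threshold`, `tpr`, `fpr`, `tnr`.
#' @export
roc_points <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  purrr::map_dfr(thr, function(t) {
    pred <- as.integer(scores >= t)
    tibble(
      threshold = t,
      tpr = if (n1 > 0) sum(pred == 1 & labels == 1) / n1 else NaN,
      fpr = if (n0 > 0) sum(pred == 1 & labels == 0) / n0 else NaN
    )
  }) %>% mutate(tnr = 1 - .data$fpr)
}

#' Operating point at a given threshold
#'
#' @inheritParams auc_score
#' @param threshold Decision threshold; scores `>= threshold` are positive.
#' @return One-row tibble with tpr, tnr, fpr, fnr, accuracy, f1 at threshold.
#' @export
threshold_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  cm <- classification_metrics(tp, fp, tn, fn)
  tibble(
    threshold = threshold,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NaN,
    tnr = if (tn + fp > 0) tn / (tn + fp) else NaN,
    fpr = if (tn + fp > 0) fp / (tn + fp) else NaN,
    fnr = if (tp + fn > 0) fn / (tp + fn) else NaN,
    accuracy = cm$accuracy, f1 = cm$f1
  )
}
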