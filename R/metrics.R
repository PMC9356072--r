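#' Confusion-matrix classification metrics
#'
#' Sensitive (1) is the positive class. Statistical sensitivity is
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)`, and the Matthews
#' correlation coefficient is
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, set to 0 when any
#' factor of the denominator is zero.
#'
#' @param truth Integer 0/1 vector of true classes.
#' @param estimate Integer 0/1 vector of predicted classes, same length.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity` and `mcc`.
#' @export
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
classification_metrics <- function(truth, estimate) {
  if (length(truth) != length(estimate)) abort("`truth` and `estimate` must match in length")
  if (length(truth) < 1) abort("need at least one observation")
  truth <- as.integer(truth)
  estimate <- as.integer(estimate)
  if (!all(truth %in% 0:1) || !all(estimate %in% 0:1)) abort("classes must be 0/1")
  tp <- sum(truth == 1L & estimate == 1L)
  fp <- sum(truth == 0L & estimate == 1L)
  tn <- sum(truth == 0L & estimate == 0L)
  fn <- sum(truth == 1L & estimate == 0L)
  denom2 <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    mcc = if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0
  )
}

#' Per-class regression error metrics
#'
#' Mean squared error and median squared error over all samples and over the
#' true sensitive and resistant subsets separately, to expose regression
#' imbalance. An empty class subset yields `NA`, not 0.
#'
#' @param truth Numeric vector of true continuous responses.
#' @param estimate Numeric vector of predictions, same length.
#' @param class Integer 0/1 vector of true classes, same length.
#' @return A one-row tibble with `mse`, `medse`, `mse_sens`, `medse_sens`,
#'   `mse_res`, `medse_res`.
#' @export
regression_metrics <- function(truth, estimate, class) {
  n <- length(truth)
  if (length(estimate) != n || length(class) != n) {
    abort("`truth`, `estimate` and `class` must match in length")
  }
  se <- (truth - estimate)^2
  sub <- function(f, keep) if (any(keep)) f(se[keep]) else NA_real_
  tibble::tibble(
    mse = mean(se), medse = median(se),
    mse_sens = sub(mean, class == 1L), medse_sens = sub(median, class == 1L),
    mse_res = sub(mean, class == 0L), medse_res = sub(median, class == 0L)
  )
}

#' Combined classification and regression report
#'
#' @param y_true,y_pred Continuous responses, truth and prediction.
#' @param class_true,class_pred Binary classes, truth and prediction.
#' @return A one-row tibble combining [regression_metrics()] (per true-class
#'   subsets) and [classification_metrics()].
#' @export
evaluation_report <- function(y_true, y_pred, class_true, class_pred) {
  dplyr::bind_cols(
    regression_metrics(y_true, y_pred, class_true),
    classification_metrics(class_true, class_pred)
  )
}
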