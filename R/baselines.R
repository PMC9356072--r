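#' Threshold classification for a regression forest
#'
#' The conventional regression forest (rRF) baseline has no class notion;
#' its class call is obtained by comparing the predicted log IC50 to the
#' drug-specific threshold with the same rule used to binarize the training
#' response (strictly below the threshold = sensitive).
#'
#' @param y_pred Numeric vector of predicted continuous responses.
#' @param t Binarization threshold.
#' @inheritParams binarize
#' @return Integer 0/1 vector of class calls.
#' @export
rrf_classify <- function(y_pred, t, sensitive_low = TRUE) {
  binarize(y_pred, t, sensitive_low = sensitive_low)
}

#' Fit the hierarchical classify-then-regress baseline
#'
#' Fits one classification forest on the full training data and two separate
#' regression forests on the sensitive and resistant subsets. A query is
#' first classified; its continuous prediction then comes from the regressor
#' matching the predicted class (class-vote ties route to the resistant
#' regressor).
#'
#' @inheritParams sauron_rf
#' @return An object of class `hierarchical_rf`.
#' @export
hierarchical_rf <- function(data, trees = 500L, mtry = NULL, min_node = 5L, seed = 1L) {
  validate_drug_dataset(data)
  for (cls in 0:1) {
    n_cls <- sum(data$Y == cls)
    if (n_cls < 2L * min_node) {
      abort(sprintf("too few %s training samples (%d) to fit the class-specific regressor",
                    if (cls == 1L) "sensitive" else "resistant", n_cls))
    }
  }
  classifier <- classification_rf(data, trees = trees, mtry = mtry,
                                  min_node = min_node, seed = seed)
  reg <- lapply(0:1, function(cls) {
    sauron_rf(ds_subset(data, which(data$Y == cls)), sample_weights = "uniform",
              tree_weighting = "uniform", trees = trees, mtry = mtry,
              min_node = min_node, seed = seed + 1L + cls)
  })
  structure(list(classifier = classifier, regressors = reg,
                 gene_ids = data$gene_ids, t = data$t,
                 params = classifier$params),
            class = "hierarchical_rf")
}

#' @export
print.hierarchical_rf <- function(x, ...) {
  cat(sprintf("<hierarchical_rf> classifier + 2 class-specific regressors, %d trees each\n",
              x$params$trees))
  invisible(x)
}

#' @rdname hierarchical_rf
#' @param object A fitted `hierarchical_rf`.
#' @param new_data Query data, as in [predict.sauron_rf()].
#' @param ... Unused.
#' @export
predict.hierarchical_rf <- function(object, new_data, ...) {
  cls <- predict(object$classifier, new_data)$.pred_class
  preds <- lapply(object$regressors, function(m) predict(m, new_data)$.pred_value)
  tibble::tibble(
    sample_id = predict(object$classifier, new_data)$sample_id,
    .pred_class = cls,
    .pred_value = ifelse(cls == 1L, preds[[2]], preds[[1]])
  )
}
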