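#' Tidy a fitted forest into its feature importances
#'
#' @param x A fitted `sauron_rf`.
#' @param ... Unused.
#' @return A tibble of per-gene normalized impurity-decrease importances,
#'   see [feature_importance()].
#' @export
tidy.sauron_rf <- function(x, ...) {
  feature_importance(x)
}

#' One-row summary of a fitted forest
#'
#' @param x A fitted `sauron_rf`.
#' @param ... Unused.
#' @return A one-row tibble with the forest configuration and training-set
#'   composition.
#' @export
glance.sauron_rf <- function(x, ...) {
  cc <- class_counts(x$train)
  tibble::tibble(
    trees = x$params$trees, mtry = x$params$mtry, min_node = x$params$min_node,
    sample_weights = x$params$sample_weights, resampling = x$params$resampling,
    tree_weighting = x$params$tree_weighting,
    n_train = cc$n, n_sens = cc$n_sens, n_res = cc$n_res,
    n_genes = length(x$gene_ids), seed = x$params$seed
  )
}

#' Augment query data with forest predictions
#'
#' @param x A fitted `sauron_rf`.
#' @param data A `drug_dataset` or query table, see [predict.sauron_rf()].
#' @param ... Passed to [predict.sauron_rf()].
#' @return A tibble with `sample_id`, the true `response` and `class` when
#'   available, and `.pred_class`, `.pred_value`.
#' @export
augment.sauron_rf <- function(x, data, ...) {
  pr <- predict(x, data, ...)
  if (inherits(data, "drug_dataset")) {
    pr <- dplyr::bind_cols(
      tibble::tibble(sample_id = data$sample_ids, response = data$y, class = data$Y),
      pr[c(".pred_class", ".pred_value")]
    )
  }
  pr
}

#' Tidy an experiment into its per-fold cross-validation results
#'
#' @param x A `sauron_experiment`.
#' @param ... Unused.
#' @return The per-grid-point, per-fold validation metric tibble.
#' @export
tidy.sauron_experiment <- function(x, ...) {
  x$cv_results
}

#' One-row test-set report of an experiment
#'
#' @param x A `sauron_experiment`.
#' @param ... Unused.
#' @return The one-row test-set evaluation report tibble.
#' @export
glance.sauron_experiment <- function(x, ...) {
  x$report
}
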