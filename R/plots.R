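#' Plot predicted against observed drug response
#'
#' Scatter of predicted versus observed log IC50 on the test set, colored by
#' the confusion-matrix category of the class call (TP/FP/TN/FN, with
#' sensitive as the positive class). The dashed lines mark the binarization
#' threshold; the diagonal is the identity.
#'
#' @param object A `sauron_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sauron_experiment <- function(object, ...) {
  t <- object$fit$t
  df <- object$predictions |>
    dplyr::mutate(outcome = dplyr::case_when(
      .data$class == 1L & .data$.pred_class == 1L ~ "TP",
      .data$class == 0L & .data$.pred_class == 1L ~ "FP",
      .data$class == 0L & .data$.pred_class == 0L ~ "TN",
      TRUE ~ "FN"
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$.pred_value,
                                   colour = .data$outcome)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "solid", colour = "grey60") +
    ggplot2::geom_vline(xintercept = t, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = t, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(TP = "#1b9e77", FN = "#d95f02",
                                            FP = "#7570b3", TN = "grey40")) +
    ggplot2::labs(x = "observed ln(IC50)", y = "predicted ln(IC50)",
                  colour = NULL,
                  title = sprintf("%s: test-set predictions", object$model))
}

#' Bar chart of the top feature importances
#'
#' @param object A fitted `sauron_rf`.
#' @param top_n Number of genes shown (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sauron_rf <- function(object, top_n = 20, ...) {
  df <- feature_importance(object) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(gene_id = factor(.data$gene_id, levels = rev(.data$gene_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$gene_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "normalized impurity decrease", y = NULL,
                  title = "Feature importance")
}

#' Gain/loss comparison of two evaluation reports
#'
#' Visualizes the trade-off a class-aware model makes against a baseline:
#' the reduction in sensitive-class error against the increase in
#' resistant-class error, one point per (paired) report row.
#'
#' @param reference A data frame of evaluation reports for the baseline
#'   (rows pair with `comparison`), with columns `mse_sens` and `mse_res`.
#' @param comparison Matching reports for the model under study.
#' @return A ggplot object.
#' @export
plot_gain_loss <- function(reference, comparison) {
  stopifnot(nrow(reference) == nrow(comparison))
  df <- tibble::tibble(
    gain_sens = reference$mse_sens - comparison$mse_sens,
    loss_res = comparison$mse_res - reference$mse_res
  )
  lim <- max(abs(c(df$gain_sens, df$loss_res)), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loss_res, y = .data$gain_sens)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
    ggplot2::labs(x = "MSE increase, resistant lines",
                  y = "MSE reduction, sensitive lines")
}
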