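#' Plot domain estimates by state and ethnic group
#'
#' Dot-and-interval chart of the benchmarked domain estimates, one panel per
#' indicator, states on the vertical axis and colour by ethnic group;
#' intervals are plus/minus one bootstrap RMSE when MSEs are present.
#'
#' @param estimates A domain-estimate tibble from [run_pipeline()] (columns
#'   `indicator`, `ethnic_group`, `state`, `estimate`, optionally `mse`).
#' @param indicator Optional subset of indicators to show.
#' @return A ggplot object.
#' @export
plot_domain_estimates <- function(estimates, indicator = NULL) {
  df <- estimates
  if (!is.null(indicator)) df <- df[df$indicator %in% indicator, ]
  has_mse <- "mse" %in% names(df) && any(is.finite(df$mse))
  gg <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$estimate, y = factor(.data$state),
    colour = .data$ethnic_group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::facet_wrap(~indicator, scales = "free_x") +
    ggplot2::labs(x = "estimated proportion", y = "state",
                  colour = "ethnic group") +
    ggplot2::theme_minimal()
  if (has_mse) {
    gg <- gg + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - sqrt(.data$mse),
                   xmax = .data$estimate + sqrt(.data$mse)),
      height = 0, position = ggplot2::position_dodge(width = 0.6))
  }
  gg
}

#' Plot calibration constraint residuals
#'
#' @param weights An `fp_weights` solution from [calibrate_weights()].
#' @return A ggplot object showing the absolute residual per constraint on a
#'   log scale.
#' @export
plot_calibration_residuals <- function(weights) {
  df <- weights$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$residual),
                                   y = stats::reorder(.data$level,
                                                      abs(.data$residual)))) +
    ggplot2::geom_col() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "|weighted mean - direct estimate| (log scale)",
                  y = "benchmark level") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for bootstrap MSE results
#'
#' Relative RMSE (percent of the estimate) per domain.
#'
#' @param object An `fp_mse` tibble from [bootstrap_mse()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_mse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$state), y = .data$rrmse_pct,
    fill = .data$ethnic_group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "state", y = "relative RMSE (% of estimate)",
                  fill = "ethnic group") +
    ggplot2::theme_minimal()
}
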