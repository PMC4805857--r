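#' Forest plot of per-SNP causal estimates
#'
#' Displays each SNP's Wald-ratio estimate with its confidence interval,
#' with the pooled estimates drawn as reference lines.
#'
#' @param instrument An `mr_instrument`.
#' @param methods Pooled estimators to overlay.
#' @param level Confidence level.
#' @return A ggplot object.
#' @export
plot_forest <- function(instrument, methods = c("ivw", "egger"),
                        level = 0.95) {
  wr <- wald_ratios(instrument, level = level)
  pooled <- mr_all(instrument, methods = methods, level = level)
  ggplot2::ggplot(wr, ggplot2::aes(x = .data$ratio,
                                   y = stats::reorder(.data$snp, .data$ratio))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_vline(
      data = pooled,
      ggplot2::aes(xintercept = .data$beta, colour = .data$method),
      linewidth = 0.6
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(shape = 15) +
    ggplot2::labs(
      x = "Causal estimate per SD of exposure (log scale)",
      y = NULL, colour = "Pooled"
    ) +
    ggplot2::theme_minimal()
}

#' Funnel plot of per-SNP causal estimates
#'
#' Plots each SNP's Wald ratio against its precision (`1 / se`). Asymmetry
#' about the pooled estimate suggests directional pleiotropy — the visual
#' counterpart of the Egger intercept test.
#'
#' @inheritParams plot_forest
#' @return A ggplot object.
#' @export
plot_funnel <- function(instrument, methods = c("ivw", "egger"),
                        level = 0.95) {
  wr <- wald_ratios(instrument, level = level)
  pooled <- mr_all(instrument, methods = methods, level = level)
  ggplot2::ggplot(wr, ggplot2::aes(x = .data$ratio, y = .data$precision)) +
    ggplot2::geom_vline(
      data = pooled,
      ggplot2::aes(xintercept = .data$beta, colour = .data$method),
      linewidth = 0.6
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Per-SNP causal estimate (log scale)",
      y = "Precision (1/SE)", colour = "Pooled"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of a resampled estimate distribution
#'
#' @param object An `mr_resample`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_resample
#' @export
autoplot.mr_resample <- function(object, bins = 60, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$estimate, linewidth = 0.7) +
    ggplot2::geom_vline(
      xintercept = c(object$ci_low, object$ci_high), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = sprintf("Resampled %s estimate (%s scheme)",
                  object$method, object$scheme),
      y = "Count"
    ) +
    ggplot2::theme_minimal()
}
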