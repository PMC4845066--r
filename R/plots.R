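#' Log-log plot of a degree-conditioned curve
#'
#' @param object A tibble from [degree_curve()].
#' @param fit Optional `loglog_fit` to draw as a line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.curve_family <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$k, .data$value,
                               colour = factor(.data$level))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "k", y = attr(object, "metric") %||% "value",
                  colour = "level") +
    ggplot2::theme_minimal()
}

#' Collapse plot of a scaling result
#'
#' Pooled points `(k * xi, Lambda)` with the fitted master power law.
#'
#' @param object A `scaling_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scaling_result <- function(object, ...) {
  mf <- object$master_fit
  ggplot2::ggplot(object$pooled,
                  ggplot2::aes(.data$x, .data$value,
                               colour = factor(.data$level))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_function(
      fun = function(x) 10^mf$intercept * x^mf$exponent,
      colour = "black", linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(k %.% xi), y = object$metric %||% "value",
      colour = "level",
      subtitle = sprintf("master exponent %.3f", mf$exponent)) +
    ggplot2::theme_minimal()
}

#' Level-wise fractal scaling plot
#'
#' Mean module mass, intra-module edges and inter-modular edges versus mean
#' module diameter, on log-log axes with the fitted dimensions.
#'
#' @param object A `fractal_dims`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fractal_dims <- function(object, ...) {
  agg <- object$aggregates
  long <- tidyr::pivot_longer(agg, c("N", "E", "Gamma"),
                              names_to = "quantity", values_to = "y")
  long <- long[!is.na(long$y) & long$y > 0 & long$r > 0, ]
  ggplot2::ggplot(long, ggplot2::aes(.data$r, .data$y,
                                     colour = .data$quantity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean module diameter r", y = "level mean") +
    ggplot2::theme_minimal()
}

#' LCP decomposition plot
#'
#' Per-edge common neighbors versus the square root of local-community
#' links, with the parabolic upper bound `LCL = CN(CN-1)/2` drawn as a
#' reference curve.
#'
#' @param object An `lcp_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lcp_summary <- function(object, ...) {
  rec <- object$records
  bound <- tibble(CN = seq(0, max(rec$CN)),
                  LCL = pmax(0, seq(0, max(rec$CN)) *
                               (seq(0, max(rec$CN)) - 1) / 2))
  ggplot2::ggplot(rec, ggplot2::aes(.data$CN, sqrt(.data$LCL))) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = bound, ggplot2::aes(y = sqrt(.data$LCL)),
                       linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "CN", y = expression(sqrt(LCL)),
                  subtitle = sprintf("LCP-corr = %.3f%s", object$lcp_corr,
                                     if (object$degenerate)
                                       " (degenerate)" else "")) +
    ggplot2::theme_minimal()
}
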