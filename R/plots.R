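#' Plot an autocorrelation curve
#'
#' Lag axis in milliseconds on a log scale, matching the conventional
#' presentation of FCS curves.
#'
#' @param object A [correlation_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_curve <- function(object, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$lag * 1000, y = .data$g)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(ms)"), y = expression(G(tau))) +
    ggplot2::theme_minimal()
  if ("sd" %in% names(d))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$g - .data$sd, ymax = .data$g + .data$sd),
      linewidth = 0.3, alpha = 0.4)
  p
}

#' Plot an ACF fit with residuals
#'
#' Data, fitted model and residuals; the two panels are stacked with
#' patchwork when available, otherwise only the fit panel is returned.
#'
#' @param object An `acf_fit`.
#' @param ... Unused.
#' @return A ggplot (or patchwork) object.
#' @export
autoplot.acf_fit <- function(object, ...) {
  d <- object$residuals
  top <- ggplot2::ggplot(d, ggplot2::aes(x = .data$lag * 1000)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$g), size = 0.8, alpha = 0.6,
                        colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "darkgreen") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = NULL, y = expression(G(tau)), title = object$model_id) +
    ggplot2::theme_minimal()
  bottom <- ggplot2::ggplot(d, ggplot2::aes(x = .data$lag * 1000,
                                            y = .data$resid)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(ms)"), y = "R") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE))
    return(patchwork::wrap_plots(top, bottom, ncol = 1, heights = c(3, 1)))
  top
}

#' Plot a FRAP fit with residuals
#'
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @return A ggplot (or patchwork) object.
#' @export
autoplot.frap_fit <- function(object, ...) {
  d <- object$residuals
  lab <- if (!is.null(object$params))
    sprintf("t1/2 = %.2g s, mobile = %.0f%%", object$t_half,
            object$mobile_fraction_pct) else "not converged"
  top <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$f), size = 0.8, alpha = 0.6,
                        colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "darkgreen") +
    ggplot2::labs(x = NULL, y = "normalized F", title = lab) +
    ggplot2::theme_minimal()
  bottom <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$resid)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "t (s)", y = "R") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE))
    return(patchwork::wrap_plots(top, bottom, ncol = 1, heights = c(3, 1)))
  top
}
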