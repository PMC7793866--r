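#' Tidy an ACF fit into a parameter table
#'
#' @param x An `acf_fit` from [fit_acf()] or [select_model()].
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter (`term`,
#'   `estimate`).
#' @export
tidy.acf_fit <- function(x, ...) {
  if (is.null(x$params))
    return(tibble::tibble(term = character(0), estimate = numeric(0)))
  tibble::tibble(term = names(x$params),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' One-row summary of an ACF fit
#'
#' @param x An `acf_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, derived diffusion coefficients
#'   (um^2/s), slow (membrane) fraction in percent, SSE, AIC, number of
#'   fitted lags and convergence flag.
#' @export
glance.acf_fit <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, d_fast = x$d_fast, d_slow = x$d_slow,
                 slow_fraction_pct = x$slow_fraction_pct, sse = x$sse,
                 aic = x$aic, n_lags = x$n_lags, converged = x$converged)
}

#' Tidy a FRAP fit into a parameter table
#'
#' @param x A `frap_fit` from [fit_frap()].
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter.
#' @export
tidy.frap_fit <- function(x, ...) {
  if (is.null(x$params))
    return(tibble::tibble(term = character(0), estimate = numeric(0)))
  tibble::tibble(term = names(x$params),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' One-row summary of a FRAP fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `t_half` (s), `mobile_fraction_pct`,
#'   `alpha`, `sse`, `converged`.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(t_half = x$t_half,
                 mobile_fraction_pct = x$mobile_fraction_pct,
                 alpha = x$params$alpha %||% NA_real_,
                 sse = x$sse, converged = x$converged)
}
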