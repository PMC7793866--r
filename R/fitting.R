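#' Fitting configuration
#'
#' Options shared by the ACF and FRAP fitting routines.
#'
#' @param min_lag Smallest lag (s) entering an ACF fit. Default `1e-5`
#'   (0.01 ms): shorter lags are dominated by detector artefacts and fast
#'   photophysics not described by the diffusion models, and are excluded.
#' @param max_lag Largest lag (s) entering an ACF fit; default unbounded.
#' @param multistart_count Number of optimizer starts over log-spaced
#'   diffusion-time initializations spanning 1 us to 1 s. Default 8.
#' @param rng_seed Seed for the (small, multiplicative) jitter applied to
#'   multistart initializations.
#' @param tolerance Relative convergence tolerance passed to the
#'   Levenberg-Marquardt optimizer.
#' @param model_selection_criterion `"aic"` (default) or
#'   `"aic_plus_runs_test"`: the latter additionally requires the
#'   one-component residuals to fail a Wald-Wolfowitz runs test for
#'   randomness at level 0.05 before the two-component model is preferred.
#' @param use_weights If `TRUE` and the curve carries a per-lag `sd`
#'   column, fit with weights `1/sd`; default unit weights.
#' @param offset If `TRUE`, add a free additive baseline term to ACF fits
#'   (off by default: the diffusion models have none).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(min_lag = 1e-5, max_lag = Inf, multistart_count = 8L,
                       rng_seed = 1L, tolerance = 1e-10,
                       model_selection_criterion = c("aic", "aic_plus_runs_test"),
                       use_weights = FALSE, offset = FALSE) {
  if (min_lag < 0) abort("`min_lag` must be >= 0.")
  if (multistart_count < 1) abort("`multistart_count` must be >= 1.")
  structure(list(
    min_lag = min_lag, max_lag = max_lag,
    multistart_count = as.integer(multistart_count),
    rng_seed = rng_seed, tolerance = tolerance,
    model_selection_criterion = match.arg(model_selection_criterion),
    use_weights = isTRUE(use_weights), offset = isTRUE(offset)
  ), class = "fit_config")
}

# AIC with the SSE floored just above the optimizer's convergence level
# (1e-8 relative; far below any measurement noise) so that on noiseless
# data the parameter penalty, not residual convergence noise, decides
# nested comparisons.
aic_from_sse <- function(sse, n, k, scale) {
  floor_sse <- n * (1e-8 * max(scale, .Machine$double.xmin))^2
  n * log(max(sse, floor_sse) / n) + 2 * (k + 1)
}

# Two-sided Wald-Wolfowitz runs test on residual signs (normal approximation).
runs_test_p <- function(resid) {
  s <- sign(resid)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  n <- n1 + n2
  if (n1 < 2 || n2 < 2) return(1)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (sigma2 <= 0) return(1)
  2 * pnorm(-abs((runs - mu) / sqrt(sigma2)))
}

# Run nls.lm from a list of start vectors; keep the best (lowest sse)
# converged fit, falling back to the best non-converged one.
multistart_lm <- function(starts, resid_fn, lower, upper, tolerance) {
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          ftol = tolerance, ptol = tolerance, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:3
    if (is.null(best) ||
        (conv && !best$conv) ||
        (conv == best$conv && sse < best$sse))
      best <- list(par = fit$par, sse = sse, conv = conv)
  }
  best
}

acf_window <- function(curve, config) {
  keep <- curve$lag >= config$min_lag & curve$lag <= config$max_lag
  dat <- curve[keep, , drop = FALSE]
  if (nrow(dat) < 8) abort("fewer than 8 lags inside [min_lag, max_lag].")
  wt <- rep(1, nrow(dat))
  if (config$use_weights && "sd" %in% names(dat) && all(dat$sd > 0))
    wt <- 1 / dat$sd
  list(lag = dat$lag, g = dat$g, wt = wt)
}

#' Fit an autocorrelation curve to a diffusion model
#'
#' Weighted least-squares fit of [acf_one_component()] or
#' [acf_two_component()] to a measured curve over lags in
#' `[min_lag, max_lag]`, with the structure parameter `s` held fixed at its
#' calibrated value (set `fix_s = FALSE` only for calibration fits, where
#' `s` is a free parameter). Positivity is enforced by fitting `N` and the
#' diffusion times on the log scale; in the two-component model the
#' ordering `tau_d1 < tau_d2` is built into the parameterization (log
#' `tau_d1` plus log of the ratio), so the fast/slow labels cannot swap.
#' A multistart scheme over log-spaced diffusion-time initializations
#' guards against local minima of the two-time-scale model.
#'
#' @param curve A [correlation_curve()].
#' @param model_id `"one_component_3d"` or `"two_component_3d2d"`.
#' @param geom A [beam_geometry()] from calibration.
#' @param config A [fit_config()].
#' @param fix_s Keep `s` fixed at `geom$s` (default). When `FALSE`, `s` is
#'   fitted and returned in `geom_fitted`.
#' @return An object of class `acf_fit`: fitted parameters, derived
#'   diffusion coefficients (um^2/s) via [diffusion_from_tau()], the slow
#'   (membrane) fraction in percent for the two-component model, per-lag
#'   residuals, SSE, AIC and a convergence flag. Non-convergence is
#'   reported through the flag, not an error.
#' @export
fit_acf <- function(curve, model_id = c("two_component_3d2d", "one_component_3d"),
                    geom, config = fit_config(), fix_s = TRUE) {
  stopifnot(inherits(curve, "correlation_curve"), inherits(geom, "beam_geometry"))
  model_id <- match.arg(model_id)
  w <- acf_window(curve, config)

  if (max(w$g) <= 0) {
    return(new_acf_fit(model_id, params = NULL, geom = geom, window = w,
                       fitted = rep(NA_real_, length(w$lag)), sse = NA_real_,
                       aic = NA_real_, converged = FALSE, config = config))
  }

  n0 <- 1 / max(w$g[1:min(3, length(w$g))])
  if (!is.finite(n0) || n0 <= 0) n0 <- 1
  two <- model_id == "two_component_3d2d"
  grid <- 10^seq(-6, 0, length.out = config$multistart_count)
  jit <- with_seed(config$rng_seed,
                   matrix(exp(rnorm(config$multistart_count * 2, 0, 0.1)),
                          ncol = 2))

  # parameter layout: log_n, [f1], log_taud1, [log_ratio], [log(s-1)], [offset]
  eval_model <- function(p) {
    i <- 1
    n <- exp(p[[i]]); i <- i + 1
    if (two) { f1 <- p[[i]]; i <- i + 1 }
    td1 <- exp(p[[i]]); i <- i + 1
    if (two) { td2 <- td1 * (1 + exp(p[[i]])); i <- i + 1 }
    s <- if (fix_s) geom$s else 1 + exp(p[[i]])
    if (!fix_s) i <- i + 1
    off <- if (config$offset) p[[i]] else 0
    x1 <- w$lag / td1
    core <- if (two) {
      x2 <- w$lag / td2
      (f1 / (1 + x1) / sqrt(1 + x1 / s^2) + (1 - f1) / (1 + x2)) / n
    } else {
      1 / n / (1 + x1) / sqrt(1 + x1 / s^2)
    }
    core + off
  }
  resid_fn <- function(p) (eval_model(p) - w$g) * w$wt

  starts <- lapply(seq_len(config$multistart_count), function(i) {
    p <- c(log(n0 * jit[i, 1]))
    if (two) p <- c(p, 0.5)
    p <- c(p, log(grid[i] * jit[i, 2]))
    if (two) p <- c(p, log(30))
    if (!fix_s) p <- c(p, log(5 - 1))
    if (config$offset) p <- c(p, 0)
    p
  })
  np <- length(starts[[1]])
  lower <- rep(-Inf, np); upper <- rep(Inf, np)
  if (two) { lower[2] <- 1e-8; upper[2] <- 1 }

  best <- multistart_lm(starts, resid_fn, lower, upper, config$tolerance)
  if (is.null(best)) {
    return(new_acf_fit(model_id, params = NULL, geom = geom, window = w,
                       fitted = rep(NA_real_, length(w$lag)), sse = NA_real_,
                       aic = NA_real_, converged = FALSE, config = config))
  }

  p <- best$par
  i <- 1
  params <- list(n_particles = exp(p[[i]])); i <- i + 1
  if (two) { params$f1 <- p[[i]]; i <- i + 1 }
  params$tau_d1 <- exp(p[[i]]); i <- i + 1
  if (two) { params$tau_d2 <- params$tau_d1 * (1 + exp(p[[i]])); i <- i + 1 }
  s_fit <- if (fix_s) geom$s else 1 + exp(p[[i]])
  if (!fix_s) i <- i + 1
  if (config$offset) params$offset <- p[[i]]
  geom_fit <- beam_geometry(geom$wxy, s_fit)

  new_acf_fit(model_id, params = params, geom = geom_fit, window = w,
              fitted = eval_model(p), sse = best$sse,
              aic = aic_from_sse(best$sse, length(w$lag), np, max(abs(w$g))),
              converged = best$conv, config = config)
}

new_acf_fit <- function(model_id, params, geom, window, fitted, sse, aic,
                        converged, config) {
  two <- model_id == "two_component_3d2d" && !is.null(params)
  d_fast <- if (is.null(params)) NA_real_ else diffusion_from_tau(params$tau_d1, geom)
  d_slow <- if (two) diffusion_from_tau(params$tau_d2, geom) else NA_real_
  slow_pct <- if (two) 100 * (1 - params$f1) else NA_real_
  structure(list(
    model_id = model_id, params = params, geom = geom,
    d_fast = d_fast, d_slow = d_slow, slow_fraction_pct = slow_pct,
    residuals = tibble::tibble(lag = window$lag, g = window$g,
                               fitted = fitted, resid = window$g - fitted),
    sse = sse, aic = aic, n_lags = length(window$lag),
    converged = converged, config = config
  ), class = "acf_fit")
}

#' @export
print.acf_fit <- function(x, ...) {
  cat(sprintf("<acf_fit> model: %s (%s)\n", x$model_id,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$params)) {
    cat(sprintf("  N = %.4g", x$params$n_particles))
    if (!is.null(x$params$f1)) cat(sprintf(", F1 = %.3f", x$params$f1))
    cat(sprintf(", tau_d1 = %.4g s", x$params$tau_d1))
    if (!is.null(x$params$tau_d2)) cat(sprintf(", tau_d2 = %.4g s", x$params$tau_d2))
    cat("\n")
    cat(sprintf("  D_fast = %.3g um^2/s", x$d_fast))
    if (!is.na(x$d_slow)) cat(sprintf(", D_slow = %.3g um^2/s", x$d_slow))
    if (!is.na(x$slow_fraction_pct))
      cat(sprintf(", slow fraction = %.1f%%", x$slow_fraction_pct))
    cat("\n")
  }
  cat(sprintf("  %d lags, SSE = %.3g, AIC = %.4g\n", x$n_lags, x$sse, x$aic))
  invisible(x)
}

#' Select between the one- and two-component diffusion models
#'
#' Fits both [acf_one_component()] and [acf_two_component()] to the curve
#' and returns the preferred fit. Preference operationalizes the
#' qualitative judgement that a curve "cannot be fitted" by the simpler
#' model: the two-component model is chosen only when its AIC is lower
#' (and, under `"aic_plus_runs_test"`, the one-component residuals
#' additionally fail a runs test for randomness at level 0.05, i.e. show
#' the systematic structure of a misspecified fit).
#'
#' @inheritParams fit_acf
#' @return The selected `acf_fit`; the rejected fit is attached as
#'   attribute `"alternative"`.
#' @export
select_model <- function(curve, geom, config = fit_config()) {
  f1c <- fit_acf(curve, "one_component_3d", geom, config)
  f2c <- fit_acf(curve, "two_component_3d2d", geom, config)
  prefer_two <- isTRUE(f2c$converged) && is.finite(f2c$aic) &&
    (!is.finite(f1c$aic) || f2c$aic < f1c$aic)
  if (prefer_two && config$model_selection_criterion == "aic_plus_runs_test" &&
      is.finite(f1c$aic))
    prefer_two <- runs_test_p(f1c$residuals$resid) < 0.05
  out <- if (prefer_two) f2c else f1c
  attr(out, "alternative") <- if (prefer_two) f1c else f2c
  out
}

#' Bleach-corrected FRAP normalization
#'
#' Corrects a bleached-ROI recovery for acquisition photobleaching and
#' background using the whole-cell signal,
#' \eqn{\mathrm{FRAP}(t) = (I_b - B_g)/(I_c - B_g)}, then normalizes to the
#' plateau: the curve is divided by the highest value of a 3-frame moving
#' average within the plateau window (the last 20\% of frames), so a single
#' noise spike cannot set the normalization.
#'
#' @param times Frame times (s), first frame = first post-bleach frame.
#' @param i_bleach,i_cell,i_background Equal-length intensity vectors for
#'   the bleached ROI, the whole cell, and a cell-free background area.
#' @return A tibble with columns `time` and `f` (normalized fluorescence).
#' @export
normalize_frap <- function(times, i_bleach, i_cell, i_background) {
  n <- length(times)
  if (length(i_bleach) != n || length(i_cell) != n || length(i_background) != n)
    abort("`times`, `i_bleach`, `i_cell`, `i_background` must have equal length.")
  bad <- which(i_cell <= i_background)
  if (length(bad) > 0)
    abort(sprintf("cell intensity <= background at frame %d.", bad[1]))
  f <- (i_bleach - i_background) / (i_cell - i_background)
  plateau <- plateau_value(f)
  if (plateau <= 0) abort("non-positive plateau; cannot normalize.")
  tibble::tibble(time = as.numeric(times), f = f / plateau)
}

# highest 3-frame moving average within the last 20% of frames
plateau_value <- function(f) {
  n <- length(f)
  win <- seq.int(max(1L, n - ceiling(0.2 * n) + 1L), n)
  mov3 <- vapply(win, function(i) mean(f[max(1L, i - 1L):min(n, i + 1L)]),
                 numeric(1))
  max(mov3)
}

#' Fit a normalized FRAP recovery curve
#'
#' Least-squares fit of the anomalous-diffusion recovery model
#' [frap_model()] to a normalized curve (see [normalize_frap()]). The
#' plateau is parameterized as `fd + dfi` with `dfi > 0`, so the fitted
#' plateau can never fall below the post-bleach level. Derived quantities:
#' `t_half = m` and the mobile fraction `(fi - fd)/(1 - fd)` in percent.
#'
#' @param times Frame times since end of bleach (s), >= 8 frames.
#' @param f Normalized fluorescence values.
#' @param config A [fit_config()] (`multistart_count` and `tolerance` are
#'   used).
#' @return An object of class `frap_fit` with elements `params`
#'   (`fd`, `fi`, `m`, `alpha`), `t_half`, `mobile_fraction_pct`,
#'   `residuals`, `sse`, `aic`, `converged`.
#' @export
fit_frap <- function(times, f, config = fit_config()) {
  if (is.data.frame(times)) { f <- times$f; times <- times$time }
  if (length(times) < 8) abort("need at least 8 frames.")
  if (length(f) != length(times)) abort("`times` and `f` must match in length.")
  if (any(times < 0)) abort("`times` must be non-negative.")

  fd0 <- min(max(f[1], 0), 0.98)
  pl0 <- min(max(plateau_value(f), fd0 + 0.01), 1.05)
  half <- (fd0 + pl0) / 2
  above <- which(f >= half & times > 0)
  m0 <- if (length(above) > 0) max(times[above[1]], min(times[times > 0])) else
    median(times)

  # par = (fd, dfi, log_m, alpha)
  eval_model <- function(p) {
    x <- (times / exp(p[[3]]))^p[[4]]
    (p[[1]] + (p[[1]] + p[[2]]) * x) / (1 + x)
  }
  resid_fn <- function(p) eval_model(p) - f

  starts <- list()
  for (mm in unique(c(m0, m0 / 4, m0 * 4)))
    for (aa in c(1, 0.6, 1.6))
      starts[[length(starts) + 1]] <- c(fd0, max(pl0 - fd0, 1e-3), log(mm), aa)
  starts <- starts[seq_len(min(length(starts), max(config$multistart_count, 1) + 4))]
  lower <- c(0, 1e-9, -Inf, 1e-3)
  upper <- c(0.999, 1.05, Inf, 2)

  best <- multistart_lm(starts, resid_fn, lower, upper, config$tolerance)
  if (is.null(best)) {
    return(structure(list(params = NULL, t_half = NA_real_,
                          mobile_fraction_pct = NA_real_,
                          residuals = tibble::tibble(time = times, f = f,
                                                     fitted = NA_real_,
                                                     resid = NA_real_),
                          sse = NA_real_, aic = NA_real_, converged = FALSE,
                          config = config), class = "frap_fit"))
  }
  p <- best$par
  params <- list(fd = p[[1]], fi = p[[1]] + p[[2]], m = exp(p[[3]]),
                 alpha = p[[4]])
  fitted <- eval_model(p)
  structure(list(
    params = params, t_half = params$m,
    mobile_fraction_pct = 100 * mobile_fraction(params$fd, params$fi),
    residuals = tibble::tibble(time = times, f = f, fitted = fitted,
                               resid = f - fitted),
    sse = best$sse,
    aic = aic_from_sse(best$sse, length(f), 4, max(abs(f))),
    converged = best$conv, config = config
  ), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> %s\n",
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$params))
    cat(sprintf("  fd = %.3f, fi = %.3f, t1/2 = %.3g s, alpha = %.3f\n  mobile fraction = %.1f%%\n",
                x$params$fd, x$params$fi, x$t_half, x$params$alpha,
                x$mobile_fraction_pct))
  cat(sprintf("  %d frames, SSE = %.3g\n", nrow(x$residuals), x$sse))
  invisible(x)
}
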