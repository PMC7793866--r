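#' Binned photon-count intensity trace
#'
#' Container for a detector trace binned at constant width, the input to
#' [multitau_autocorrelate()]. Stored as a tibble with a `counts` column and
#' a `bin_width` attribute.
#'
#' @param counts Non-negative integer photon counts per bin.
#' @param bin_width Bin width in seconds, positive.
#' @return A tibble of class `intensity_trace` with column `counts` and
#'   attributes `bin_width` (s) and `duration` (s).
#' @examples
#' intensity_trace(rpois(1000, 5), bin_width = 1e-5)
#' @export
intensity_trace <- function(counts, bin_width) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || !is.finite(bin_width) ||
      bin_width <= 0)
    abort("`bin_width` must be a positive scalar (seconds).")
  if (!is.numeric(counts) || length(counts) < 1 || any(!is.finite(counts)) ||
      any(counts < 0))
    abort("`counts` must be non-negative photon counts.")
  out <- tibble::tibble(counts = as.numeric(counts))
  attr(out, "bin_width") <- bin_width
  attr(out, "duration") <- bin_width * length(counts)
  class(out) <- c("intensity_trace", class(out))
  out
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %d bins x %.3g s = %.4g s, mean %.3g counts/bin\n",
              nrow(x), attr(x, "bin_width"), attr(x, "duration"),
              mean(x$counts)))
  invisible(x)
}

#' Autocorrelation curve
#'
#' The central FCS object: autocorrelation amplitudes on a grid of lag
#' times. `g` is fluctuation-normalized, i.e.
#' \eqn{g(\tau) = \langle\delta I(t)\,\delta I(t+\tau)\rangle / \langle I\rangle^2},
#' so an uncorrelated signal gives 0 and \eqn{g(0^+) \approx 1/N} for
#' Poisson-emitting diffusers, matching [acf_one_component()] /
#' [acf_two_component()] without an offset.
#'
#' @param lags Strictly increasing positive lag times (s).
#' @param g Autocorrelation amplitudes, same length as `lags`.
#' @param sd Optional per-lag standard deviations (e.g. across replicates).
#' @param n_replicates Number of measurements averaged into the curve.
#' @return A tibble of class `correlation_curve` with columns `lag`, `g`
#'   (and `sd` if given) and attribute `n_replicates`.
#' @export
correlation_curve <- function(lags, g, sd = NULL, n_replicates = 1L) {
  if (!is.numeric(lags) || any(!is.finite(lags)) || any(lags <= 0) ||
      any(diff(lags) <= 0))
    abort("`lags` must be strictly increasing positive lag times (s).")
  if (!is.numeric(g) || length(g) != length(lags) || any(!is.finite(g)))
    abort("`g` must be finite and match `lags` in length.")
  out <- tibble::tibble(lag = as.numeric(lags), g = as.numeric(g))
  if (!is.null(sd)) {
    if (length(sd) != length(lags) || any(!is.finite(sd)) || any(sd < 0))
      abort("`sd` must be non-negative and match `lags` in length.")
    out$sd <- as.numeric(sd)
  }
  attr(out, "n_replicates") <- as.integer(n_replicates)
  class(out) <- c("correlation_curve", class(out))
  out
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %d lags in [%.3g, %.3g] s, %d replicate(s)\n",
              nrow(x), min(x$lag), max(x$lag), attr(x, "n_replicates")))
  NextMethod()
}

# multi-tau lag plan: level 0 has lag indices 1..2m at the base bin width,
# every further level rebins by 2 and adds indices m+1..2m
multitau_plan <- function(n_bins, m) {
  levels <- list()
  lev <- 0L
  n <- n_bins
  repeat {
    idx <- if (lev == 0L) seq_len(2L * m) else (m + 1L):(2L * m)
    if (n < 2L * max(idx)) break
    levels[[lev + 1L]] <- list(level = lev, idx = idx)
    lev <- lev + 1L
    n <- n %/% 2L
  }
  levels
}

#' Multi-tau autocorrelation of a photon-count trace
#'
#' Computes the fluctuation autocorrelation
#' \eqn{g(\tau) = \langle\delta I\,\delta I_\tau\rangle/\langle I\rangle^2}
#' on a quasi-logarithmic lag grid: the first `2 * channels_per_octave`
#' lags at the native bin width, then the trace is rebinned by averaging
#' pairs of bins and each further octave contributes
#' `channels_per_octave` lags at the doubled width. Symmetric (per-lag)
#' normalization is used — each lag's product mean is divided by the means
#' of the left and right segments actually entering the sum — which
#' suppresses the baseline bias caused by slow drifts such as acquisition
#' photobleaching.
#'
#' Lags are reported at k times the current bin width, the centre of the
#' triangular averaging kernel induced by mean-rebinning.
#'
#' @param trace An [intensity_trace()] (or bare numeric vector of counts,
#'   with `bin_width` supplied).
#' @param channels_per_octave Lag channels per octave (default 16).
#' @param bin_width Bin width in seconds when `trace` is a bare vector.
#' @param max_lag Optional largest lag (s) to compute; octaves beyond it are
#'   dropped.
#' @return A [correlation_curve()].
#' @examples
#' tr <- intensity_trace(rpois(20000, 10), 1e-5)
#' multitau_autocorrelate(tr)
#' @export
multitau_autocorrelate <- function(trace, channels_per_octave = 16L,
                                   bin_width = NULL, max_lag = Inf) {
  if (!inherits(trace, "intensity_trace")) {
    if (is.null(bin_width))
      abort("supply an `intensity_trace` or a counts vector plus `bin_width`.")
    trace <- intensity_trace(trace, bin_width)
  }
  m <- as.integer(channels_per_octave)
  if (m < 2L) abort("`channels_per_octave` must be >= 2.")
  x <- trace$counts
  dt <- attr(trace, "bin_width")
  if (length(x) < 4L * m)
    abort(sprintf("trace too short: need at least %d bins.", 4L * m))
  if (mean(x) == 0) abort("trace has zero mean intensity; nothing to correlate.")

  plan <- multitau_plan(length(x), m)
  lags <- numeric(0)
  g <- numeric(0)
  for (lv in plan) {
    w <- dt * 2^lv$level
    if (min(lv$idx) * w > max_lag) break
    n <- length(x)
    for (k in lv$idx) {
      lag <- k * w
      if (lag > max_lag) break
      left <- x[1:(n - k)]
      right <- x[(k + 1):n]
      ml <- mean(left)
      mr <- mean(right)
      gv <- if (ml == 0 || mr == 0) 0 else mean(left * right) / (ml * mr) - 1
      lags <- c(lags, lag)
      g <- c(g, gv)
    }
    # mean-rebin by factor 2 for the next octave
    n2 <- length(x) %/% 2L
    if (n2 < 1L) break
    x <- (x[seq(1L, 2L * n2, by = 2L)] + x[seq(2L, 2L * n2, by = 2L)]) / 2
  }
  correlation_curve(lags, g, n_replicates = 1L)
}

#' Average replicate correlation curves
#'
#' Pointwise arithmetic mean of curves sharing one lag grid, mirroring the
#' acquisition scheme of averaging repeated short measurements per cell
#' (e.g. 10 x 10 s). The per-lag standard deviation across replicates is
#' attached as `sd` when more than one curve is given.
#'
#' @param curves List of [correlation_curve()] objects on an identical lag
#'   grid.
#' @return A [correlation_curve()] with `n_replicates` equal to the total
#'   number of averaged measurements.
#' @export
average_curves <- function(curves) {
  if (!is.list(curves) || length(curves) == 0 ||
      !all(vapply(curves, inherits, logical(1), "correlation_curve")))
    abort("`curves` must be a non-empty list of correlation_curve objects.")
  lag0 <- curves[[1]]$lag
  same <- vapply(curves, function(cu) {
    length(cu$lag) == length(lag0) && all(abs(cu$lag - lag0) <= 1e-12 * lag0)
  }, logical(1))
  if (!all(same)) abort("all curves must share an identical lag grid.")
  gm <- vapply(curves, function(cu) cu$g, numeric(length(lag0)))
  gm <- matrix(gm, nrow = length(lag0))
  nrep <- sum(vapply(curves, function(cu) attr(cu, "n_replicates"), integer(1)))
  sdv <- if (length(curves) > 1) apply(gm, 1, sd) else NULL
  correlation_curve(lag0, rowMeans(gm), sd = sdv, n_replicates = nrep)
}
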