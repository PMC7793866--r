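#' Calibrate the confocal volume from a reference-dye curve
#'
#' Fits the one-component 3D model to a calibration curve measured on a
#' dye of known diffusion coefficient with the structure parameter free,
#' then converts the fitted diffusion time to the lateral beam waist via
#' [beam_waist_from_calibration()]. The returned geometry (waist plus
#' fitted `s`) is what cell fits hold fixed.
#'
#' @param curve A [correlation_curve()] measured on the standard, or a
#'   path to an ACF CSV (see [read_acf_csv()]).
#' @param standard A [calibration_standard()].
#' @param config A [fit_config()].
#' @return A list of class `calibration_report`: `geom` (a
#'   [beam_geometry()]), `wxy_nm`, `tau_d` (s), `s`, and the underlying
#'   `fit` (an `acf_fit`).
#' @export
run_calibration <- function(curve, standard = calibration_standard(400),
                            config = fit_config()) {
  if (is.character(curve)) curve <- read_acf_csv(curve)
  stopifnot(inherits(curve, "correlation_curve"))
  # waist placeholder: only `s` matters during the calibration fit itself
  fit <- fit_acf(curve, "one_component_3d", beam_geometry(0.145, 5),
                 config, fix_s = FALSE)
  if (!fit$converged) abort("calibration fit did not converge.")
  tau_d <- fit$params$tau_d1
  wxy <- beam_waist_from_calibration(tau_d, standard)
  geom <- beam_geometry(wxy, fit$geom$s)
  structure(list(geom = geom, wxy_nm = 1000 * wxy, tau_d = tau_d,
                 s = fit$geom$s, standard = standard, fit = fit),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %s (D = %g um^2/s): wxy = %.1f nm, s = %.3g, tau_d = %.4g s\n",
              x$standard$label, x$standard$d_ref, x$wxy_nm, x$s, x$tau_d))
  invisible(x)
}

#' End-to-end FCS analysis of one or more cells
#'
#' For each cell: averages its replicate curves ([average_curves()]), runs
#' [select_model()], and extracts the fitted parameters and derived
#' diffusion coefficients. Per-cell failures are caught and reported in
#' the output rather than aborting the batch.
#'
#' @param cells A named list; each element is a [correlation_curve()], a
#'   list of replicate curves sharing a lag grid, or a path to an ACF CSV.
#' @param geom Calibrated [beam_geometry()].
#' @param config A [fit_config()].
#' @return A tibble with one row per cell (`cell`, `model_id`,
#'   `n_particles`, `f1`, `tau_d1`, `tau_d2`, `d_fast`, `d_slow`,
#'   `slow_fraction_pct`, `sse`, `converged`, `error`) with the
#'   across-cell mean and SD of the diffusion coefficients attached as
#'   attribute `summary`, and the fit objects as attribute `fits`.
#' @export
run_fcs_analysis <- function(cells, geom, config = fit_config()) {
  if (!is.list(cells) || length(cells) == 0) {
    if (inherits(cells, "correlation_curve")) cells <- list(cells)
    else abort("`cells` must be a non-empty list.")
  }
  if (inherits(cells, "correlation_curve")) cells <- list(cells)
  nm <- names(cells)
  if (is.null(nm)) nm <- sprintf("cell_%02d", seq_along(cells))
  fits <- vector("list", length(cells))
  rows <- purrr::map2(cells, nm, function(x, label) {
    tryCatch({
      if (is.character(x)) x <- read_acf_csv(x)
      if (is.list(x) && !inherits(x, "correlation_curve")) x <- average_curves(x)
      fit <- select_model(x, geom, config)
      p <- fit$params
      tibble::tibble(
        cell = label, model_id = fit$model_id,
        n_particles = p$n_particles %||% NA_real_, f1 = p$f1 %||% NA_real_,
        tau_d1 = p$tau_d1 %||% NA_real_, tau_d2 = p$tau_d2 %||% NA_real_,
        d_fast = fit$d_fast, d_slow = fit$d_slow,
        slow_fraction_pct = fit$slow_fraction_pct,
        sse = fit$sse, converged = fit$converged, error = NA_character_,
        fit = list(fit))
    }, error = function(e) {
      tibble::tibble(cell = label, model_id = NA_character_,
                     n_particles = NA_real_, f1 = NA_real_,
                     tau_d1 = NA_real_, tau_d2 = NA_real_, d_fast = NA_real_,
                     d_slow = NA_real_, slow_fraction_pct = NA_real_,
                     sse = NA_real_, converged = FALSE,
                     error = conditionMessage(e), fit = list(NULL))
    })
  })
  out <- dplyr::bind_rows(rows)
  fits <- out$fit
  names(fits) <- out$cell
  out$fit <- NULL
  ok <- out[is.na(out$error), , drop = FALSE]
  attr(out, "summary") <- tibble::tibble(
    n_cells = nrow(ok),
    d_fast_mean = mean(ok$d_fast, na.rm = TRUE),
    d_fast_sd = sd(ok$d_fast, na.rm = TRUE),
    d_slow_mean = mean(ok$d_slow, na.rm = TRUE),
    d_slow_sd = sd(ok$d_slow, na.rm = TRUE),
    slow_fraction_mean = mean(ok$slow_fraction_pct, na.rm = TRUE),
    slow_fraction_sd = sd(ok$slow_fraction_pct, na.rm = TRUE))
  attr(out, "fits") <- fits
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' End-to-end FRAP analysis of one or more cells
#'
#' Normalizes each cell's raw series ([normalize_frap()]), averages the
#' normalized curves on their common time grid (mean and SD per frame),
#' and fits the recovery model to the group-average curve — mirroring the
#' workflow of fitting the averaged recovery rather than averaging
#' per-cell fits. Per-cell fits are also returned.
#'
#' @param cells A named list; each element is a data frame with columns
#'   `time_s,i_bleach,i_cell,i_background` (or a path to such a CSV).
#' @param config A [fit_config()].
#' @return A list of class `frap_report`: `average_curve` (tibble `time`,
#'   `f`, `sd`, `n`), `fit` (the `frap_fit` of the average), `t_half`,
#'   `mobile_fraction_pct`, `per_cell` (tibble of per-cell fit summaries)
#'   and `failures`.
#' @export
run_frap_analysis <- function(cells, config = fit_config()) {
  if (is.data.frame(cells)) cells <- list(cells)
  if (!is.list(cells) || length(cells) == 0) abort("`cells` must be a non-empty list.")
  nm <- names(cells)
  if (is.null(nm)) nm <- sprintf("cell_%02d", seq_along(cells))
  curves <- list()
  failures <- character(0)
  per_cell <- list()
  for (i in seq_along(cells)) {
    res <- tryCatch({
      x <- cells[[i]]
      if (is.character(x)) x <- read_frap_csv(x)
      nc <- normalize_frap(x$time_s, x$i_bleach, x$i_cell, x$i_background)
      pf <- fit_frap(nc$time, nc$f, config)
      list(curve = nc, fit = pf)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", nm[i], conditionMessage(res)))
    } else {
      curves[[nm[i]]] <- res$curve
      per_cell[[nm[i]]] <- tibble::tibble(
        cell = nm[i], t_half = res$fit$t_half,
        mobile_fraction_pct = res$fit$mobile_fraction_pct,
        alpha = res$fit$params$alpha %||% NA_real_,
        converged = res$fit$converged)
    }
  }
  if (length(curves) == 0) abort("no FRAP series could be processed.")
  t0 <- curves[[1]]$time
  same <- vapply(curves, function(cu)
    length(cu$time) == length(t0) && all(abs(cu$time - t0) < 1e-9), logical(1))
  if (!all(same)) abort("FRAP series do not share a common time grid.")
  fm <- vapply(curves, function(cu) cu$f, numeric(length(t0)))
  fm <- matrix(fm, nrow = length(t0))
  avg <- tibble::tibble(time = t0, f = rowMeans(fm),
                        sd = if (ncol(fm) > 1) apply(fm, 1, sd) else NA_real_,
                        n = ncol(fm))
  fit <- fit_frap(avg$time, avg$f, config)
  structure(list(average_curve = avg, fit = fit, t_half = fit$t_half,
                 mobile_fraction_pct = fit$mobile_fraction_pct,
                 per_cell = dplyr::bind_rows(per_cell), failures = failures,
                 config = config), class = "frap_report")
}

#' @export
print.frap_report <- function(x, ...) {
  cat(sprintf("<frap_report> %d cell(s); group-average fit: t1/2 = %.3g s, mobile fraction = %.1f%%\n",
              max(x$average_curve$n), x$t_half, x$mobile_fraction_pct))
  if (length(x$failures) > 0)
    cat("  failures:\n", paste0("   - ", x$failures, collapse = "\n"), "\n")
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Serializes fit results and reports (including the resolved
#' configuration, for reproducibility) to a JSON file.
#'
#' @param x An `acf_fit`, `frap_fit`, `calibration_report`, `frap_report`
#'   or tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  stripped <- strip_for_json(x)
  jsonlite::write_json(stripped, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

strip_for_json <- function(x) {
  if (inherits(x, "acf_fit") || inherits(x, "frap_fit"))
    return(lapply(unclass(x), strip_for_json))
  if (inherits(x, "calibration_report"))
    return(list(wxy_nm = x$wxy_nm, s = x$s, tau_d = x$tau_d,
                standard = unclass(x$standard), fit = strip_for_json(x$fit)))
  if (inherits(x, "frap_report"))
    return(list(t_half = x$t_half, mobile_fraction_pct = x$mobile_fraction_pct,
                average_curve = as.data.frame(x$average_curve),
                per_cell = as.data.frame(x$per_cell), failures = x$failures,
                fit = strip_for_json(x$fit), config = unclass(x$config)))
  if (inherits(x, "beam_geometry") || inherits(x, "fit_config")) return(unclass(x))
  if (is.data.frame(x)) return(as.data.frame(x))
  x
}
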