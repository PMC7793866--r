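#' Read an autocorrelation curve from CSV
#'
#' Expects columns `lag_ms,g` and optionally `sd`; lags are converted to
#' seconds on input (curves are reported in milliseconds at I/O
#' boundaries, but all internal computation is in seconds and um).
#'
#' @param path CSV file path.
#' @return A [correlation_curve()].
#' @export
read_acf_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("lag_ms", "g") %in% names(d)))
    abort(sprintf("%s: need columns `lag_ms,g`.", path))
  if (any(d$lag_ms <= 0)) abort(sprintf("%s: non-positive lags.", path))
  correlation_curve(d$lag_ms / 1000, d$g,
                    sd = if ("sd" %in% names(d)) d$sd else NULL)
}

#' Write an autocorrelation curve to CSV (lags in ms)
#'
#' @param curve A [correlation_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_acf_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  d <- tibble::tibble(lag_ms = curve$lag * 1000, g = curve$g)
  if ("sd" %in% names(curve)) d$sd <- curve$sd
  readr::write_csv(d, path)
  invisible(path)
}

#' Read a binned photon-count trace from CSV
#'
#' Accepts either two columns `time_s,counts` (bin width inferred from the
#' time spacing) or a single `counts` column preceded by a header line
#' `# bin_width_s=<value>`.
#'
#' @param path CSV file path.
#' @return An [intensity_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1)
  if (grepl("^#\\s*bin_width_s\\s*=", header)) {
    bw <- as.numeric(sub("^#\\s*bin_width_s\\s*=\\s*", "", header))
    d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
    if (!"counts" %in% names(d)) abort(sprintf("%s: need a `counts` column.", path))
    return(intensity_trace(d$counts, bw))
  }
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "counts") %in% names(d)))
    abort(sprintf("%s: need `time_s,counts` or a `# bin_width_s=` header.", path))
  dt <- diff(d$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * dt[1])
    abort(sprintf("%s: time grid is not uniform.", path))
  intensity_trace(d$counts, mean(dt))
}

#' Read a raw FRAP time series from CSV
#'
#' Expects columns `time_s,i_bleach,i_cell,i_background`.
#'
#' @param path CSV file path.
#' @return A tibble with those columns.
#' @export
read_frap_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("time_s", "i_bleach", "i_cell", "i_background")
  if (!all(need %in% names(d)))
    abort(sprintf("%s: need columns `%s`.", path, paste(need, collapse = ",")))
  d[need]
}

#' Read a single-plane TIFF image as a numeric matrix
#'
#' @param path TIFF file path.
#' @param as_mask Return a logical mask (pixel > 0) instead of intensities.
#' @return Numeric (or logical) matrix.
#' @export
read_image_tiff <- function(path, as_mask = FALSE) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort("the `tiff` package is required to read TIFF images.")
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (as_mask) img > 0 else img
}

#' Write a numeric matrix as a single-plane TIFF image
#'
#' Intensities are rescaled to the unit range expected by the TIFF writer.
#'
#' @param image Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort("the `tiff` package is required to write TIFF images.")
  rng <- range(image)
  scaled <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}
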