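check_mask <- function(mask, dims, name) {
  if (!is.logical(mask) || !is.matrix(mask) || !all(dim(mask) == dims))
    abort(sprintf("`%s` must be a logical matrix matching the image dimensions.", name))
  if (!any(mask)) abort(sprintf("`%s` is empty.", name))
  mask
}

#' ROI set for membrane/total quantification
#'
#' @param membrane_rois A logical mask, or list of logical masks, marking
#'   plasma-membrane regions (pooled for the mean).
#' @param total_roi Logical mask of the whole cell.
#' @param background_roi Logical mask of a cell-free area; must be disjoint
#'   from `total_roi`.
#' @return A list of class `roi_set`.
#' @export
roi_set <- function(membrane_rois, total_roi, background_roi) {
  if (is.matrix(membrane_rois)) membrane_rois <- list(membrane_rois)
  dims <- dim(total_roi)
  membrane_rois <- lapply(seq_along(membrane_rois), function(i)
    check_mask(membrane_rois[[i]], dims, sprintf("membrane_rois[[%d]]", i)))
  check_mask(total_roi, dims, "total_roi")
  check_mask(background_roi, dims, "background_roi")
  if (any(background_roi & total_roi))
    abort("`background_roi` must be disjoint from `total_roi`.")
  structure(list(membrane_rois = membrane_rois, total_roi = total_roi,
                 background_roi = background_roi), class = "roi_set")
}

#' Plasma-membrane to total intensity ratio
#'
#' Quantifies membrane enrichment as the ratio of the mean intensity over
#' membrane ROIs to the mean over the whole cell, each after subtraction
#' of the mean background:
#' \deqn{\mathrm{ratio} = \frac{\langle m\mathrm{ROIs}\rangle - \langle bg\rangle}
#'   {\langle t\mathrm{ROIs}\rangle - \langle bg\rangle}}
#'
#' @param image Numeric intensity matrix.
#' @param rois A [roi_set()].
#' @return A one-row tibble with `membrane_mean`, `total_mean`,
#'   `background_mean` and `ratio`.
#' @export
membrane_total_ratio <- function(image, rois) {
  stopifnot(is.matrix(image), is.numeric(image), inherits(rois, "roi_set"))
  mem_px <- unlist(lapply(rois$membrane_rois, function(m) image[m]))
  membrane_mean <- mean(mem_px)
  total_mean <- mean(image[rois$total_roi])
  background_mean <- mean(image[rois$background_roi])
  if (total_mean <= background_mean)
    abort("total-cell mean does not exceed background; ratio undefined.")
  tibble::tibble(
    membrane_mean = membrane_mean, total_mean = total_mean,
    background_mean = background_mean,
    ratio = (membrane_mean - background_mean) / (total_mean - background_mean))
}

#' Pearson colocalization of two channels over an ROI
#'
#' Plain mode computes Pearson's correlation of pixel intensities over the
#' mask. Auto-threshold mode performs a Costes-style search: channel-2
#' thresholds are tied to channel-1 thresholds through the orthogonal
#' least-squares regression of channel 2 on channel 1, the threshold is
#' lowered from the maximum until the correlation of the pixels *below*
#' both thresholds drops to zero or less, and Pearson's coefficient is
#' then computed over pixels above threshold in either channel.
#'
#' @param ch1,ch2 Numeric intensity matrices of identical dimensions.
#' @param mask Logical matrix selecting the analysed pixels (default: all).
#' @param mode `"plain"` or `"auto_threshold"`.
#' @param n_steps Threshold search resolution for auto-threshold mode.
#' @return A one-row tibble with `pearson_r`, `threshold_ch1`,
#'   `threshold_ch2` (NA in plain mode) and `n_pixels`.
#' @export
pearson_colocalization <- function(ch1, ch2, mask = NULL,
                                   mode = c("plain", "auto_threshold"),
                                   n_steps = 256) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(ch1), is.matrix(ch2), all(dim(ch1) == dim(ch2)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  check_mask(mask, dim(ch1), "mask")
  x <- ch1[mask]
  y <- ch2[mask]
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    abort("a channel is constant within the mask; Pearson's r is undefined.")

  if (mode == "plain") {
    return(tibble::tibble(pearson_r = cor(x, y), threshold_ch1 = NA_real_,
                          threshold_ch2 = NA_real_, n_pixels = length(x)))
  }

  # Costes: ch2 threshold tied to ch1 via orthogonal regression y = a x + b
  v <- stats::var(cbind(x, y))
  a <- if (abs(v[1, 2]) > 0) {
    (v[2, 2] - v[1, 1] + sqrt((v[2, 2] - v[1, 1])^2 + 4 * v[1, 2]^2)) /
      (2 * v[1, 2])
  } else sd(y) / sd(x)
  b <- mean(y) - a * mean(x)
  t1_grid <- seq(max(x), min(x), length.out = n_steps)
  t1_sel <- min(x)  # fall through to plain if never decorrelated
  for (t1 in t1_grid) {
    t2 <- a * t1 + b
    below <- x < t1 & y < t2
    if (sum(below) < 3) next
    if (length(unique(x[below])) < 2 || length(unique(y[below])) < 2) next
    if (cor(x[below], y[below]) <= 0) { t1_sel <- t1; break }
  }
  t2_sel <- a * t1_sel + b
  sel <- x >= t1_sel | y >= t2_sel
  if (sum(sel) < 3 || length(unique(x[sel])) < 2 || length(unique(y[sel])) < 2)
    sel <- rep(TRUE, length(x))
  tibble::tibble(pearson_r = cor(x[sel], y[sel]), threshold_ch1 = t1_sel,
                 threshold_ch2 = t2_sel, n_pixels = sum(sel))
}
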