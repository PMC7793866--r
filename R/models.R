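#' Confocal detection-volume geometry
#'
#' The detection volume of a confocal FCS instrument is modelled as a 3D
#' Gaussian with lateral 1/e\eqn{^2} radius `wxy` (the beam waist) and axial
#' radius `s * wxy`, where `s` is the structure parameter (axial-to-lateral
#' extent ratio). `wxy` is obtained by calibration against a dye of known
#' diffusion coefficient (see [beam_waist_from_calibration()]); `s` is fitted
#' during calibration and then held fixed for cell measurements.
#'
#' @param wxy Lateral beam-waist radius in micrometres. Must be positive.
#' @param s Structure parameter (dimensionless). Must exceed 1: the focal
#'   volume is always elongated along the optical axis.
#' @return An object of class `beam_geometry`.
#' @examples
#' beam_geometry(wxy = 0.145, s = 5)
#' @export
beam_geometry <- function(wxy, s) {
  stopifnot(is.numeric(wxy), length(wxy) == 1, is.numeric(s), length(s) == 1)
  if (!is.finite(wxy) || wxy <= 0) abort("`wxy` must be a positive beam-waist radius (um).")
  if (!is.finite(s) || s <= 1) abort("`s` must exceed 1 (axial/lateral extent ratio).")
  structure(list(wxy = wxy, s = s), class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> wxy = %.4g um (%.1f nm), s = %.3g\n",
              x$wxy, 1000 * x$wxy, x$s))
  invisible(x)
}

#' Calibration standard for confocal-volume calibration
#'
#' A dye of known diffusion coefficient used to calibrate the beam waist,
#' e.g. Atto-488 with D = 400 um^2/s at 37 degrees C.
#'
#' @param d_ref Reference diffusion coefficient (um^2/s), positive.
#' @param label Dye name.
#' @param temperature Temperature in degrees C at which `d_ref` applies.
#' @return An object of class `calibration_standard`.
#' @examples
#' atto488 <- calibration_standard(400, "Atto-488", 37)
#' @export
calibration_standard <- function(d_ref, label = "Atto-488", temperature = 37) {
  stopifnot(is.numeric(d_ref), length(d_ref) == 1)
  if (!is.finite(d_ref) || d_ref <= 0) abort("`d_ref` must be positive (um^2/s).")
  structure(list(d_ref = d_ref, label = label, temperature = temperature),
            class = "calibration_standard")
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau < 0))
    abort("lag times `tau` must be finite and non-negative (seconds).")
  tau
}

#' One-component 3D free-diffusion autocorrelation model
#'
#' Normalized fluorescence autocorrelation of a single species diffusing
#' freely in three dimensions through a 3D-Gaussian detection volume:
#' \deqn{G(\tau) = \frac{1}{N}\,\frac{1}{1+\tau/\tau_d}\,
#'   \frac{1}{\sqrt{1+\tau/(s^2\tau_d)}}}
#' where N is the mean number of particles in the detection volume and
#' \eqn{\tau_d} the translational diffusion time. G(0) = 1/N.
#'
#' @param tau Lag times in seconds (vector, >= 0).
#' @param n_particles Mean occupancy N, positive.
#' @param tau_d Translational diffusion time in seconds, positive.
#' @param geom A [beam_geometry()].
#' @return Numeric vector of autocorrelation amplitudes.
#' @examples
#' g <- beam_geometry(0.145, 5)
#' acf_one_component(1e-4, n_particles = 1, tau_d = 1e-4, geom = g)
#' @export
acf_one_component <- function(tau, n_particles, tau_d, geom) {
  check_tau(tau)
  if (!is.finite(n_particles) || n_particles <= 0) abort("`n_particles` must be positive.")
  if (!is.finite(tau_d) || tau_d <= 0) abort("`tau_d` must be positive (s).")
  stopifnot(inherits(geom, "beam_geometry"))
  x <- tau / tau_d
  (1 / n_particles) / (1 + x) / sqrt(1 + x / geom$s^2)
}

#' Two-component 3D + 2D free-diffusion autocorrelation model
#'
#' Autocorrelation of a mixture of a fast, freely 3D-diffusing pool
#' (amplitude fraction `f1`, diffusion time `tau_d1`; e.g. cytosolic
#' protein) and a slow, freely 2D-diffusing pool (fraction `1 - f1`,
#' diffusion time `tau_d2`; e.g. a membrane-bound pool moving laterally in
#' the bilayer plane):
#' \deqn{G(\tau) = \frac{1}{N}\left[
#'   \frac{F_1}{(1+\tau/\tau_{d1})\sqrt{1+\tau/(s^2\tau_{d1})}}
#'   + \frac{1-F_1}{1+\tau/\tau_{d2}}\right]}
#' The 2D term has no axial factor: lateral membrane diffusion does not
#' carry the particle out of the volume along the optical axis.
#'
#' @inheritParams acf_one_component
#' @param f1 Fraction of the fast 3D component, in (0, 1].
#' @param tau_d1,tau_d2 Diffusion times (s) of the fast and slow components;
#'   `tau_d1 < tau_d2` is required.
#' @return Numeric vector of autocorrelation amplitudes.
#' @examples
#' g <- beam_geometry(0.145, 5)
#' acf_two_component(1e-4, n_particles = 1, f1 = 0.73,
#'                   tau_d1 = 135.8e-6, tau_d2 = 4.043e-3, geom = g)
#' @export
acf_two_component <- function(tau, n_particles, f1, tau_d1, tau_d2, geom) {
  check_tau(tau)
  if (!is.finite(n_particles) || n_particles <= 0) abort("`n_particles` must be positive.")
  if (!is.finite(f1) || f1 <= 0 || f1 > 1) abort("`f1` must lie in (0, 1].")
  if (!is.finite(tau_d1) || tau_d1 <= 0 || !is.finite(tau_d2) || tau_d2 <= tau_d1)
    abort("need 0 < tau_d1 < tau_d2 (seconds).")
  stopifnot(inherits(geom, "beam_geometry"))
  x1 <- tau / tau_d1
  x2 <- tau / tau_d2
  (1 / n_particles) *
    (f1 / (1 + x1) / sqrt(1 + x1 / geom$s^2) + (1 - f1) / (1 + x2))
}

#' Anomalous-diffusion FRAP recovery model
#'
#' Normalized fluorescence recovery after photobleaching in the crowded
#' intracellular environment:
#' \deqn{F(t) = \frac{f_d + f_i\,(t/m)^\alpha}{1 + (t/m)^\alpha}}
#' `fd` is the normalized fluorescence immediately after the bleach,
#' `fi` the plateau fluorescence, `m` the half-recovery time
#' (\eqn{F(m) = (f_d+f_i)/2} for any \eqn{\alpha}) and `alpha` the anomalous
#' exponent (\eqn{\alpha = 1} recovers simple diffusion-like kinetics).
#'
#' @param t Time since end of bleach, seconds (vector, >= 0).
#' @param fd Normalized post-bleach fluorescence, in \[0, 1).
#' @param fi Normalized plateau fluorescence, `fd < fi <= 1.05` (small
#'   headroom above 1 for noisy normalization).
#' @param m Half-recovery time t1/2 in seconds, positive.
#' @param alpha Anomalous exponent, in (0, 2].
#' @return Numeric vector of normalized fluorescence values.
#' @examples
#' frap_model(c(0, 2, 60), fd = 0.1, fi = 0.91, m = 2, alpha = 1)
#' @export
frap_model <- function(t, fd, fi, m, alpha) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    abort("`t` must be finite and non-negative (seconds).")
  check_frap_params(fd, fi, m, alpha)
  x <- (t / m)^alpha
  (fd + fi * x) / (1 + x)
}

check_frap_params <- function(fd, fi, m, alpha) {
  if (!is.finite(fd) || fd < 0 || fd >= 1) abort("`fd` must lie in [0, 1).")
  if (!is.finite(fi) || fi <= fd || fi > 1.05) abort("`fi` must lie in (fd, 1.05].")
  if (!is.finite(m) || m <= 0) abort("`m` (half-recovery time) must be positive.")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 2) abort("`alpha` must lie in (0, 2].")
  invisible(TRUE)
}

#' Convert a diffusion time to a diffusion coefficient
#'
#' For a Gaussian detection volume the translational diffusion time and
#' diffusion coefficient are linked by \eqn{D = W_{xy}^2 / (4 \tau_d)}.
#'
#' @param tau_d Translational diffusion time(s) in seconds, positive.
#' @param geom A [beam_geometry()] with calibrated `wxy`.
#' @return Diffusion coefficient(s) in um^2/s.
#' @examples
#' diffusion_from_tau(135.8e-6, beam_geometry(0.145, 5)) # ~38.7 um^2/s
#' @export
diffusion_from_tau <- function(tau_d, geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  if (any(!is.finite(tau_d)) || any(tau_d <= 0)) abort("`tau_d` must be positive (s).")
  geom$wxy^2 / (4 * tau_d)
}

#' Calibrate the beam waist from a reference-dye measurement
#'
#' Inverts \eqn{D = W_{xy}^2/(4\tau_d)}: given the diffusion time measured
#' for a dye of known diffusion coefficient, the lateral beam waist is
#' \eqn{W_{xy} = \sqrt{4 D_{ref} \tau_d}}.
#'
#' @param tau_d_measured Measured diffusion time of the standard (s), positive.
#' @param standard A [calibration_standard()].
#' @return Beam-waist radius in micrometres.
#' @examples
#' beam_waist_from_calibration(13.14e-6, calibration_standard(400)) # 0.145 um
#' @export
beam_waist_from_calibration <- function(tau_d_measured, standard) {
  stopifnot(inherits(standard, "calibration_standard"))
  if (!is.finite(tau_d_measured) || tau_d_measured <= 0)
    abort("`tau_d_measured` must be positive (s).")
  sqrt(4 * standard$d_ref * tau_d_measured)
}

#' Mobile fraction of a FRAP recovery
#'
#' The proportion of bleached molecules exchanged for unbleached ones at the
#' recovery plateau, using the standard convention
#' \eqn{(f_i - f_d)/(1 - f_d)}. Clipped to \[0, 1.05\] to tolerate plateau
#' normalization noise slightly above 1.
#'
#' @inheritParams frap_model
#' @return Mobile fraction (dimensionless, 0 to 1.05).
#' @examples
#' mobile_fraction(fd = 0.1, fi = 0.91) # 0.9
#' @export
mobile_fraction <- function(fd, fi, m = 1, alpha = 1) {
  if (!is.finite(fd) || fd >= 1) abort("`fd` must be < 1.")
  if (fd < 0) abort("`fd` must be non-negative.")
  if (!is.finite(fi)) abort("`fi` must be finite.")
  min(max((fi - fd) / (1 - fd), 0), 1.05)
}
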