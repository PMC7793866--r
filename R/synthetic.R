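#' Analytic autocorrelation curve with optional noise
#'
#' Evaluates one of the diffusion ACF models on a lag grid and optionally
#' perturbs it with i.i.d. multiplicative Gaussian noise,
#' \eqn{g(\tau) = G(\tau)(1+\epsilon)}, \eqn{\epsilon \sim N(0,
#' \mathrm{noise\_scale}^2)} — the noise structure of a well-averaged FCS
#' curve, whose relative error is roughly lag-independent. The generating
#' parameters are attached as attribute `truth`.
#'
#' @param params Named list of model parameters: `n_particles` and `tau_d`
#'   for the one-component model, or `n_particles`, `f1`, `tau_d1`,
#'   `tau_d2` for the two-component model.
#' @param geom A [beam_geometry()].
#' @param lag_grid Lag times in seconds (strictly increasing, positive).
#' @param noise_model `"none"` or `"multiplicative_gaussian"`.
#' @param noise_scale Relative noise SD for the multiplicative model.
#' @param rng_seed Seed for the noise draw (`NULL`: use current RNG state).
#' @return A [correlation_curve()] with attribute `truth`.
#' @examples
#' g <- beam_geometry(0.145, 5)
#' generate_analytic_acf(list(n_particles = 1, tau_d = 2e-4), g,
#'                       lag_grid = 10^seq(-5, 0, length.out = 50))
#' @export
generate_analytic_acf <- function(params, geom,
                                  lag_grid = 10^seq(-5, 0, length.out = 200),
                                  noise_model = c("none", "multiplicative_gaussian"),
                                  noise_scale = 0.01, rng_seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (length(lag_grid) == 0) abort("`lag_grid` must be non-empty.")
  two <- !is.null(params$f1)
  g <- if (two) {
    acf_two_component(lag_grid, params$n_particles, params$f1,
                      params$tau_d1, params$tau_d2, geom)
  } else {
    acf_one_component(lag_grid, params$n_particles, params$tau_d, geom)
  }
  if (noise_model == "multiplicative_gaussian") {
    eps <- with_seed(rng_seed, rnorm(length(g), 0, noise_scale))
    g <- g * (1 + eps)
  }
  out <- correlation_curve(lag_grid, g)
  attr(out, "truth") <- c(params, list(geom = geom, noise_model = noise_model,
                                       noise_scale = noise_scale))
  out
}

#' Configuration for the Brownian-dynamics FCS simulator
#'
#' Defaults emulate the measured live-cell system: a fast cytosolic pool
#' (D around 39 um^2/s), a slower membrane pool (D around 1.3 um^2/s)
#' diffusing in a plane through the focus, a 145 nm beam waist with
#' structure parameter 5, and 10 us binning over 60 s (the cumulative
#' duration of ten 10 s measurements but uninterrupted, which averaging of
#' replicate curves then emulates).
#'
#' @param box_size Periodic cubic box edge (um); must be at least 10 beam
#'   waists so boundary effects are negligible.
#' @param n_cytosolic,d_cytosolic Count and diffusion coefficient
#'   (um^2/s) of the 3D pool.
#' @param n_membrane,d_membrane Count and diffusion coefficient of the 2D
#'   (membrane) pool.
#' @param membrane_z z-position (um) of the membrane plane relative to the
#'   focus; 0 puts the plane through the focal centre, as for a focal spot
#'   positioned on the plasma membrane.
#' @param geom A [beam_geometry()] for the detection volume.
#' @param brightness Photons/s per particle at the focus centre.
#' @param background_rate Uncorrelated background photons/s.
#' @param bin_width Bin width (s); also the integration time step, valid
#'   while the r.m.s. step stays well below the beam waist (warned
#'   otherwise).
#' @param duration Trace duration (s); at least 1e4 bins are required for
#'   usable statistics.
#' @param rng_seed Seed (`NULL`: current RNG state).
#' @return A list of class `fcs_sim_config`.
#' @export
fcs_sim_config <- function(box_size = 3, n_cytosolic = 20, d_cytosolic = 38.7,
                           n_membrane = 10, d_membrane = 1.3, membrane_z = 0,
                           geom = beam_geometry(0.145, 5),
                           brightness = 1e5, background_rate = 0,
                           bin_width = 1e-5, duration = 60, rng_seed = NULL) {
  stopifnot(inherits(geom, "beam_geometry"))
  if (box_size < 10 * geom$wxy)
    abort("`box_size` must be at least 10 beam waists.")
  if (n_cytosolic < 0 || n_membrane < 0 || d_cytosolic < 0 || d_membrane < 0 ||
      brightness < 0 || background_rate < 0)
    abort("counts and rates must be non-negative.")
  if (bin_width <= 0 || duration <= 0 || duration / bin_width < 1e4)
    abort("need duration/bin_width >= 1e4 bins.")
  step <- sqrt(2 * max(d_cytosolic, d_membrane) * bin_width)
  if (step > geom$wxy / 2)
    warn(sprintf(
      "r.m.s. step %.3g um per bin is not small against wxy = %.3g um; reduce bin_width.",
      step, geom$wxy))
  structure(list(box_size = box_size, n_cytosolic = as.integer(n_cytosolic),
                 d_cytosolic = d_cytosolic, n_membrane = as.integer(n_membrane),
                 d_membrane = d_membrane, membrane_z = membrane_z, geom = geom,
                 brightness = brightness, background_rate = background_rate,
                 bin_width = bin_width, duration = duration,
                 rng_seed = rng_seed), class = "fcs_sim_config")
}

#' Simulate a photon-count trace by Brownian dynamics
#'
#' Propagates cytosolic particles by free 3D Brownian steps (SD
#' \eqn{\sqrt{2 D \Delta t}} per axis, periodic wrap) and membrane
#' particles by in-plane steps at fixed `membrane_z`; per bin, the expected
#' photon count is the sum of per-particle brightnesses weighted by a 3D
#' Gaussian detection profile (lateral waist `wxy`, axial waist `s * wxy`)
#' plus background, and the emitted count is a Poisson draw.
#'
#' @param config An [fcs_sim_config()].
#' @return An [intensity_trace()] with attribute `truth` (generating
#'   diffusion coefficients, pool sizes and geometry).
#' @export
simulate_fcs_trace <- function(config = fcs_sim_config()) {
  stopifnot(inherits(config, "fcs_sim_config"))
  n_bins <- as.integer(round(config$duration / config$bin_width))
  counts <- with_seed(config$rng_seed,
    bd_photon_trace(n_bins, config$bin_width, config$box_size,
                    config$n_cytosolic, config$d_cytosolic,
                    config$n_membrane, config$d_membrane, config$membrane_z,
                    config$geom$wxy, config$geom$s,
                    config$brightness, config$background_rate))
  out <- intensity_trace(counts, config$bin_width)
  attr(out, "truth") <- list(
    d_cytosolic = config$d_cytosolic, d_membrane = config$d_membrane,
    n_cytosolic = config$n_cytosolic, n_membrane = config$n_membrane,
    tau_d_cytosolic = config$geom$wxy^2 / (4 * max(config$d_cytosolic, 1e-300)),
    tau_d_membrane = config$geom$wxy^2 / (4 * max(config$d_membrane, 1e-300)),
    geom = config$geom, config = config)
  out
}

#' Expected mean count rate of the simulator
#'
#' Analytic expectation of the per-bin photon count of
#' [simulate_fcs_trace()]: background plus each pool's brightness times the
#' detection-profile volume integral over the box (3D Gaussian for the
#' cytosolic pool; its 2D in-plane integral at the membrane z-offset for
#' the membrane pool).
#'
#' @param config An [fcs_sim_config()].
#' @return Expected counts per bin.
#' @export
expected_mean_counts <- function(config) {
  stopifnot(inherits(config, "fcs_sim_config"))
  w <- config$geom$wxy
  wz <- config$geom$s * w
  v_psf3 <- (pi / 2)^(3 / 2) * w^2 * wz          # integral of exp(-2r^2/w^2...)
  a_psf2 <- (pi / 2) * w^2 * exp(-2 * config$membrane_z^2 / wz^2)
  rate <- config$background_rate +
    config$brightness * config$n_cytosolic * v_psf3 / config$box_size^3 +
    config$brightness * config$n_membrane * a_psf2 / config$box_size^2
  rate * config$bin_width
}

#' Configuration for the FRAP time-series generator
#'
#' Defaults emulate the measured recoveries: half-time 2 s, around 90
#' percent mobile fraction (`fd = 0.1`, `fi = 0.91`), 1 s frames over
#' 60 s, mild acquisition photobleaching of the whole-cell signal and
#' additive Gaussian detection noise.
#'
#' @param frap_params Named list with `fd`, `fi`, `m`, `alpha` (see
#'   [frap_model()]).
#' @param frame_interval Frame spacing (s).
#' @param n_frames Number of post-bleach frames.
#' @param acquisition_bleach_rate Exponential decay rate (1/s) of the
#'   whole-cell signal caused by imaging.
#' @param cell_intensity0 Initial background-subtracted cell intensity.
#' @param background_level Constant background intensity.
#' @param noise_sd Additive Gaussian SD on every reported intensity.
#' @param rng_seed Seed (`NULL`: current RNG state).
#' @return A list of class `frap_sim_config`.
#' @export
frap_sim_config <- function(frap_params = list(fd = 0.1, fi = 0.91, m = 2, alpha = 1),
                            frame_interval = 1, n_frames = 60,
                            acquisition_bleach_rate = 0.005,
                            cell_intensity0 = 1000, background_level = 50,
                            noise_sd = 0, rng_seed = NULL) {
  check_frap_params(frap_params$fd, frap_params$fi, frap_params$m,
                    frap_params$alpha)
  if (frame_interval <= 0 || n_frames < 8) abort("need >= 8 frames at positive spacing.")
  if (cell_intensity0 <= 0 || background_level < 0 || noise_sd < 0 ||
      acquisition_bleach_rate < 0)
    abort("intensities must be positive and rates/noise non-negative.")
  structure(list(frap_params = frap_params, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 cell_intensity0 = cell_intensity0,
                 background_level = background_level, noise_sd = noise_sd,
                 rng_seed = rng_seed), class = "frap_sim_config")
}

#' Generate a raw FRAP intensity time series
#'
#' Builds the three raw vectors a FRAP experiment yields — bleached-ROI,
#' whole-cell and background intensity per frame — from a known recovery:
#' \eqn{I_c(t) = B + C_0 e^{-kt} + \epsilon},
#' \eqn{I_b(t) = B + (I_c^{(0)}(t) - B)\,F(t) + \epsilon},
#' \eqn{B_g(t) = B + \epsilon}, with \eqn{F(t)} from [frap_model()] and
#' \eqn{k} the acquisition bleach rate, so the bleach correction of
#' [normalize_frap()] cancels \eqn{e^{-kt}} exactly in the noiseless case.
#' Frame times are `frame_interval * (0:(n_frames - 1))`: the first frame
#' is acquired at the end of the bleach (t = 0, where \eqn{F(0) = f_d}),
#' which anchors the post-bleach level in downstream fits.
#'
#' @param config A [frap_sim_config()].
#' @return A tibble with columns `time`, `i_bleach`, `i_cell`,
#'   `i_background` and attribute `truth` (the generating `frap_params`).
#' @export
generate_frap_timeseries <- function(config = frap_sim_config()) {
  stopifnot(inherits(config, "frap_sim_config"))
  p <- config$frap_params
  t <- config$frame_interval * (seq_len(config$n_frames) - 1)
  f <- frap_model(t, p$fd, p$fi, p$m, p$alpha)
  decay <- config$cell_intensity0 * exp(-config$acquisition_bleach_rate * t)
  noise <- function(n) if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0
  out <- with_seed(config$rng_seed, {
    n <- length(t)
    tibble::tibble(
      time = t,
      i_bleach = config$background_level + decay * f + noise(n),
      i_cell = config$background_level + decay + noise(n),
      i_background = config$background_level + noise(n))
  })
  attr(out, "truth") <- p
  out
}

#' Configuration for the two-channel synthetic cell-image generator
#'
#' A circular cell (cytosol disc plus a brighter membrane ring) with
#' punctate endosome-like structures, imaged in two channels at 40 nm
#' pixels (channel 1: membrane + cytosol + puncta; channel 2: puncta only,
#' a fraction of which are co-placed with channel-1 puncta).
#'
#' @param image_size Image edge in pixels.
#' @param pixel_size Pixel size (um), default 0.04.
#' @param cell_radius Cell radius (um).
#' @param membrane_ring_width Membrane ring thickness in pixels.
#' @param membrane_intensity,cytosol_intensity,background_intensity
#'   Channel-1 intensity levels (arbitrary units).
#' @param n_endosomes Number of punctate structures.
#' @param endosome_intensity Peak amplitude of each punctum.
#' @param channel2_coloc_fraction Fraction of channel-2 puncta co-placed
#'   with channel-1 puncta (the rest are placed independently).
#' @param noise_sd Additive Gaussian noise SD per pixel.
#' @param rng_seed Seed (`NULL`: current RNG state).
#' @return A list of class `image_sim_config`.
#' @export
image_sim_config <- function(image_size = 256, pixel_size = 0.04,
                             cell_radius = 4, membrane_ring_width = 3,
                             membrane_intensity = 200, cytosol_intensity = 100,
                             background_intensity = 10, n_endosomes = 8,
                             endosome_intensity = 150,
                             channel2_coloc_fraction = 0.5, noise_sd = 0,
                             rng_seed = NULL) {
  r_px <- cell_radius / pixel_size
  if (2 * r_px + 4 > image_size) abort("cell does not fit in the image.")
  if (membrane_ring_width < 1 || membrane_ring_width >= r_px)
    abort("invalid membrane ring width.")
  if (min(membrane_intensity, cytosol_intensity, background_intensity,
          endosome_intensity) < 0 || noise_sd < 0)
    abort("intensities and noise must be non-negative.")
  if (channel2_coloc_fraction < 0 || channel2_coloc_fraction > 1)
    abort("`channel2_coloc_fraction` must lie in [0, 1].")
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 cell_radius = cell_radius,
                 membrane_ring_width = membrane_ring_width,
                 membrane_intensity = membrane_intensity,
                 cytosol_intensity = cytosol_intensity,
                 background_intensity = background_intensity,
                 n_endosomes = as.integer(n_endosomes),
                 endosome_intensity = endosome_intensity,
                 channel2_coloc_fraction = channel2_coloc_fraction,
                 noise_sd = noise_sd, rng_seed = rng_seed),
            class = "image_sim_config")
}

gaussian_spot <- function(nr, nc, row0, col0, amp, sigma) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  amp * exp(-((r - row0)^2 + (c - col0)^2) / (2 * sigma^2))
}

#' Generate a two-channel synthetic cell image with ROI masks
#'
#' @param config An [image_sim_config()].
#' @return A list with elements `channel1`, `channel2` (numeric matrices),
#'   `rois` (logical matrices `membrane`, `total`, `background`) and
#'   `truth` (placements and the generating config).
#' @export
generate_colocalization_images <- function(config = image_sim_config()) {
  stopifnot(inherits(config, "image_sim_config"))
  n <- config$image_size
  ctr <- (n + 1) / 2
  r_px <- config$cell_radius / config$pixel_size
  rw <- config$membrane_ring_width
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  dist <- sqrt((rr - ctr)^2 + (cc - ctr)^2)

  cell <- dist <= r_px
  ring <- cell & dist > (r_px - rw)
  cytosol <- dist <= (r_px - rw)
  bg_mask <- dist > 1.25 * r_px

  ch1 <- matrix(config$background_intensity, n, n)
  ch1[cytosol] <- config$cytosol_intensity
  ch1[ring] <- config$membrane_intensity
  ch2 <- matrix(0, n, n)

  placements <- with_seed(config$rng_seed, {
    ne <- config$n_endosomes
    sigma <- 2
    pl <- list(pos1 = NULL, pos2 = NULL, coplaced = logical(0))
    if (ne > 0) {
      theta <- runif(ne, 0, 2 * pi)
      rad <- sqrt(runif(ne)) * 0.7 * (r_px - rw)
      pos1 <- cbind(row = ctr + rad * sin(theta), col = ctr + rad * cos(theta))
      co <- runif(ne) < config$channel2_coloc_fraction
      theta2 <- runif(ne, 0, 2 * pi)
      rad2 <- sqrt(runif(ne)) * 0.7 * (r_px - rw)
      pos2 <- pos1
      pos2[!co, 1] <- ctr + (rad2 * sin(theta2))[!co]
      pos2[!co, 2] <- ctr + (rad2 * cos(theta2))[!co]
      for (i in seq_len(ne)) {
        ch1 <- ch1 + gaussian_spot(n, n, pos1[i, 1], pos1[i, 2],
                                   config$endosome_intensity, sigma)
        ch2 <- ch2 + gaussian_spot(n, n, pos2[i, 1], pos2[i, 2],
                                   config$endosome_intensity, sigma)
      }
      pl <- list(pos1 = pos1, pos2 = pos2, coplaced = co)
    }
    if (config$noise_sd > 0) {
      ch1 <- pmax(ch1 + matrix(rnorm(n * n, 0, config$noise_sd), n), 0)
      ch2 <- pmax(ch2 + matrix(rnorm(n * n, 0, config$noise_sd), n), 0)
    }
    pl$ch1 <- ch1
    pl$ch2 <- ch2
    pl
  })
  ch1 <- placements$ch1
  ch2 <- placements$ch2
  placements$ch1 <- NULL
  placements$ch2 <- NULL
  list(channel1 = ch1, channel2 = ch2,
       rois = list(membrane = ring, total = cell, background = bg_mask),
       truth = c(placements, list(config = config)))
}
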