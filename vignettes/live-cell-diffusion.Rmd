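---
title: "Live-cell diffusion analysis with FCS and FRAP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Live-cell diffusion analysis with FCS and FRAP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcstools)
```

## The measurement problem

A prenylated peripheral membrane protein typically exists in (at least)
two dynamic pools in a live cell: one diffusing freely in the cytosol at
tens of µm²/s, and one bound to membranes and moving laterally in the
bilayer plane at around 1 µm²/s. Whether plasma-membrane enrichment of
such a protein is maintained by vesicular traffic or by direct exchange
with the cytosolic pool is a question about *rates*, and two
complementary fluorescence measurements resolve it:

* **FCS** watches equilibrium concentration fluctuations in a femtoliter
  confocal volume. The decay of the intensity autocorrelation function
  G(τ) reports how fast molecules transit the volume; its amplitude
  reports their number. With ~µs resolution it cleanly separates a fast
  cytosolic and a slow membrane component.
* **FRAP** destroys fluorescence in a region and watches replacement.
  Its half-recovery time t₁/₂ and mobile fraction integrate all exchange
  processes at the bleached site on a seconds time scale.

`fcstools` implements both analyses end to end, plus the image
quantifications (membrane/total ratio, Pearson colocalization) that
typically accompany them, and a synthetic-data layer that regenerates
every input with known ground truth.

## Models

### Autocorrelation models

For a 3D Gaussian detection volume with lateral 1/e² radius $w_{xy}$ and
structure parameter $s$ (axial/lateral ratio; `beam_geometry()` enforces
$s > 1$), free 3D diffusion of a single species gives

$$G(\tau) = \frac{1}{N}\,\Big(1+\frac{\tau}{\tau_d}\Big)^{-1}
  \Big(1+\frac{\tau}{s^2\tau_d}\Big)^{-1/2},$$

and a mixture of a fast 3D pool (amplitude fraction $F_1$) with a slow
2D pool diffusing in a membrane plane gives

$$G(\tau) = \frac{1}{N}\left[
  \frac{F_1}{\big(1+\tau/\tau_{d1}\big)\sqrt{1+\tau/(s^2\tau_{d1})}}
  + \frac{1-F_1}{1+\tau/\tau_{d2}}\right].$$

The 2D term carries no axial factor: lateral motion in the membrane does
not move the molecule out of the volume along the optical axis. Both
models satisfy $G(0) = 1/N$ and decay monotonically to zero; the test
suite asserts these invariants on log-spaced grids. $1-F_1$ is reported
as the membrane (slow) fraction in percent.

Translational times convert to diffusion coefficients through
$D = w_{xy}^2/(4\tau_d)$. The beam waist comes from calibration: fitting
the one-component model to a dye of known $D$ (Atto-488, 400 µm²/s at
37 °C) and inverting the same relation,
$w_{xy} = \sqrt{4 D_\mathrm{ref} \tau_d}$. The calibration fit is the
only fit in which $s$ is free; cell fits hold it fixed
(`fit_acf(..., fix_s = TRUE)`, the default).

No triplet/photophysics term and no baseline offset are included in the
models; an optional additive offset is available at fit time
(`fit_config(offset = TRUE)`) to absorb a residual baseline, off by
default.

### FRAP model

Recovery in the crowded intracellular environment is described by

$$F(t) = \frac{f_d + f_i\,(t/m)^\alpha}{1 + (t/m)^\alpha},$$

with $f_d$ the normalized fluorescence immediately after the bleach,
$f_i$ the plateau, $m$ the half-recovery time ($F(m) = (f_d+f_i)/2$ for
*any* $\alpha$ — the property that makes $m$ directly interpretable as
$t_{1/2}$) and $\alpha$ an anomalous exponent. We bound
$0 < \alpha \le 2$; $\alpha = 1$ is simple diffusion-like recovery. The
mobile fraction uses the standard convention
$(f_i - f_d)/(1 - f_d)$, clipped to $[0, 1.05]$ for normalization noise.

Note an important interaction with normalization: the bleach-corrected
curve $(I_b - B_g)/(I_c - B_g)$ is divided by its plateau value, which
by construction pushes $f_i \to 1$ and hence the apparent mobile
fraction toward 100%. Plateau normalization is the right convention for
comparing recovery *kinetics* (t₁/₂) across cells; to quantify the
mobile fraction, fit a curve normalized to the *pre-bleach* level
instead.

## The correlator

`multitau_autocorrelate()` estimates
$g(\tau) = \langle\delta I\,\delta I_\tau\rangle/\langle I\rangle^2$ on
a quasi-logarithmic grid: 2m lags at the native bin width (m = 16
channels per octave by default), then mean-rebinning by 2 per octave
with m further lags each, spanning µs to tens of seconds at fixed cost.
Two numerical choices matter:

* **Symmetric normalization.** Each lag's product mean is divided by the
  means of the two segments actually entering the sum. This removes the
  baseline bias a drifting intensity (acquisition bleaching) would
  otherwise introduce, and makes the estimator exactly zero for a
  constant trace and exactly invariant under intensity rescaling.
* **Lag assignment.** Mean-rebinning makes each deep-octave channel an
  average of products over a triangular window of elementary lags. We
  report the lag at the centre of that window, $k \cdot 2^\ell \Delta t$,
  because the analytic models are evaluated at the reported lag and an
  off-centre (e.g. geometric-mean) assignment would bias fits at small
  channel index.

The fluctuation normalization gives $g(0^+) \approx 1/N$ for
Poisson-emitting diffusers, so correlator output feeds the models with
no amplitude convention shim. A brute-force $O(n^2)$ estimator written
independently in the test suite agrees with the implementation to
1e-10 on random traces.

`average_curves()` implements the acquisition convention of averaging
repeated short measurements (e.g. ten 10-s runs per cell) into the curve
used for fitting, attaching per-lag SDs usable as weights.

## Fitting and model selection

Fits are Levenberg–Marquardt nonlinear least squares (`minpack.lm`),
with:

* **Lag window** τ ≥ 0.01 ms (`fit_config(min_lag = 1e-5)`): shorter
  lags are dominated by detector artefacts and photophysics outside the
  models. The upper bound defaults to the largest lag.
* **Unit weights** by default; per-lag SD weights optional when
  replicate curves provide them.
* **Positivity and ordering by parameterization.** $N$ and $\tau_{d1}$
  are fitted on the log scale; the two-component model fits
  $\log\tau_{d1}$ and $\log(\tau_{d2}/\tau_{d1})$ so that
  $\tau_{d1} < \tau_{d2}$ holds identically and the fast/slow labels
  cannot swap. $F_1$ is box-bounded in $(0, 1]$.
* **Multistart.** 8 starts (seeded jitter) over log-spaced $\tau_d$
  initializations spanning 1 µs–1 s, $F_1$ starting at 0.5. The
  two-time-scale model has genuine local minima; multistart is cheaper
  than global optimization and sufficient in all recovery sweeps.
* **Non-convergence is a flag, not an exception**, so batch analyses
  keep going; a curve with no positive amplitude (unidentifiable $N$) is
  flagged without fitting.

Model choice operationalizes the qualitative judgement that a curve
"cannot be fitted" by free 3D diffusion alone: both models are fitted
and the two-component model is selected only if its AIC
($n\log(\mathrm{SSE}/n) + 2(k+1)$) is lower; under
`model_selection_criterion = "aic_plus_runs_test"` the one-component
residuals must additionally fail a Wald–Wolfowitz runs test (level
0.05), i.e. show the systematic wave of a misspecified fit. On
noiseless curves both SSEs are machine zeros, so before AIC the SSE is
floored at $n(10^{-8}\max|g|)^2$ — just above the optimizer's
convergence level (~1e-11 relative) and far below any measurement noise
— which lets the parameter penalty decide the nested comparison and
makes model selection honour parsimony on perfect fits.

FRAP fits parameterize the plateau as $f_d + \Delta$, $\Delta > 0$, so
the fitted plateau can never fall below the post-bleach level, with $m$
on the log scale. Frame times start at the end of the bleach: the first
frame observes $F(0) = f_d$ directly. This anchor matters — without a
frame near $t = 0$, $f_d$, $m$ and $\alpha$ trade off against each
other and the half-time estimate degrades several-fold at realistic
noise, an identifiability property of the model rather than an
optimizer limitation.

## Synthetic data: what it emulates, what it does not

The study system this package targets deposits no raw data, so the
generators double as the test bed, with defaults chosen to match the
measured conditions:

* `generate_analytic_acf()`: model curves with i.i.d. multiplicative
  Gaussian noise — the error structure of a well-averaged FCS curve,
  whose relative noise is roughly lag-independent.
* `simulate_fcs_trace()`: Brownian dynamics (Rcpp) of a fast 3D pool
  (default 20 particles at 38.7 µm²/s) and a slow in-plane pool (10
  particles at 1.3 µm²/s in a plane through the focus) in a 3 µm
  periodic box ≥ 10 beam waists wide, Gaussian detection profile
  (145 nm waist, s = 5), Poisson photon emission at 10 µs bins for 60 s
  — about the cumulative duration of ten 10-s measurements. The time
  step equals the bin width, valid while
  $\sqrt{2D\Delta t} \ll w_{xy}$ (checked at config time). The mean
  count rate matches its closed-form expectation
  (`expected_mean_counts()`) and the simulate → correlate → fit round
  trip recovers $D$ within 20% and classifies mixed pools as
  two-component — the package's core end-to-end check, running in a
  few minutes on one CPU.
* `generate_frap_timeseries()`: raw $I_b, I_c, B_g$ vectors from a known
  recovery with exponential acquisition bleaching (default 0.005/s) and
  additive Gaussian noise; the bleach correction cancels the imposed
  decay exactly in the noiseless case, which the tests assert to 1e-10.
* `generate_colocalization_images()`: a disc cell with membrane ring,
  punctate structures, a controllable co-placement fraction between
  channels, and ROI masks (membrane ring, whole cell, background) at
  40 nm pixels.

Deliberately *not* modelled: triplet/blinking photophysics and
photobleaching of diffusers in FCS, diffraction-realistic point-spread
functions, vesicular or cytoskeletal transport, realistic cell geometry,
and detector afterpulsing. Passing recovery tests therefore demonstrate
correctness of the estimators under the stated physics, not robustness
to every artefact of real instruments; on real data the min-lag cutoff
and the optional fit offset are the first knobs to reach for.

Every generator is bit-reproducible given `rng_seed` (the Rcpp kernel
draws from R's RNG), and problem sizes in the shipped tests are chosen
so the whole suite runs in about a minute plus a few minutes for the
Brownian-dynamics round trip.

## Image quantification choices

The membrane/total ratio subtracts the mean background from the mean
membrane-ROI and whole-cell intensities before taking the ratio; since
means are linear this equals per-pixel subtraction, and the result is
invariant under a shared constant offset. The ratio errors (rather than
returning a negative number) if the cell mean does not exceed
background.

Pearson colocalization is provided plain and with a Costes-style
auto-threshold: channel thresholds are tied through the orthogonal
regression of channel 2 on channel 1, lowered from the top until the
sub-threshold pixels are uncorrelated (r ≤ 0), and the coefficient is
computed over pixels above threshold in either channel. When the search
never decorrelates (perfectly coupled channels) the thresholds reach the
minimum and the result equals plain Pearson. Both modes are exposed
because published Pearson values do not always state whether
thresholding was applied.

## Known limitations

* The 2D component assumes the membrane plane passes through the
  detection volume; strongly tilted or apical/basal geometries change
  the effective model (an elliptical-volume 2D variant is not
  implemented).
* AIC-based selection with unit weights can prefer the two-component
  model on data whose noise is strongly lag-dependent; supplying
  replicate SD weights mitigates this.
* The FRAP model is a phenomenological recovery law: it does not
  separate lateral diffusion within the membrane from cytosol–membrane
  exchange, and reaction–diffusion fitting is out of scope.
* Plateau-normalized FRAP curves carry no immobile-fraction
  information (see above).
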