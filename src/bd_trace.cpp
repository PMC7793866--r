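#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap(double v, double half) {
  // periodic wrap into [-half, half)
  const double L = 2.0 * half;
  double u = (v + half) / L;
  u -= std::floor(u);
  return u * L - half;
}

// Brownian-dynamics photon-count trace for a Gaussian confocal detection
// volume. Cytosolic particles take free 3D Gaussian steps of SD
// sqrt(2 D dt) per axis in a periodic cubic box; membrane particles are
// confined to the plane z = mem_z and step in-plane only. Expected photons
// per bin are brightness * dt * exp(-2 rho^2/wxy^2 - 2 z^2/wz^2) summed
// over particles, plus background * dt; counts are Poisson draws. Uses R's
// RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector bd_photon_trace(int n_bins, double dt, double box_size,
                              int n_cyt, double d_cyt,
                              int n_mem, double d_mem, double mem_z,
                              double wxy, double s,
                              double brightness, double background_rate) {
  const int np = n_cyt + n_mem;
  const double half = box_size / 2.0;
  const double wz = s * wxy;
  const double iw2 = 2.0 / (wxy * wxy);
  const double iwz2 = 2.0 / (wz * wz);
  const double sd_c = std::sqrt(2.0 * d_cyt * dt);
  const double sd_m = std::sqrt(2.0 * d_mem * dt);

  std::vector<double> x(np), y(np), z(np);
  RNGScope scope;
  for (int i = 0; i < np; ++i) {
    x[i] = R::runif(-half, half);
    y[i] = R::runif(-half, half);
    z[i] = (i < n_cyt) ? R::runif(-half, half) : mem_z;
  }

  IntegerVector out(n_bins);
  const double bdt = brightness * dt;
  const double bg = background_rate * dt;
  for (int t = 0; t < n_bins; ++t) {
    double lambda = bg;
    for (int i = 0; i < np; ++i) {
      const bool cyt = i < n_cyt;
      const double sd = cyt ? sd_c : sd_m;
      x[i] = wrap(x[i] + R::norm_rand() * sd, half);
      y[i] = wrap(y[i] + R::norm_rand() * sd, half);
      if (cyt) z[i] = wrap(z[i] + R::norm_rand() * sd, half);
      const double e = iw2 * (x[i] * x[i] + y[i] * y[i]) + iwz2 * z[i] * z[i];
      if (e < 30.0) lambda += bdt * std::exp(-e);
    }
    out[t] = (int) R::rpois(lambda);
    if (t % 1048576 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
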