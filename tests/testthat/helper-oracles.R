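# Independent oracles used across tests. Written deliberately naively
# (explicit loops, textbook formulas) so they share no code path with the
# package implementation.

# Direct multi-tau estimate: same lag plan and symmetric normalization as
# the package correlator, but computed with explicit per-pair loops on an
# explicitly rebinned copy of the trace.
direct_multitau <- function(counts, bin_width, m = 16L, max_lag = Inf) {
  x <- as.numeric(counts)
  lags <- numeric(0)
  g <- numeric(0)
  level <- 0L
  repeat {
    idx <- if (level == 0L) 1:(2L * m) else (m + 1L):(2L * m)
    w <- bin_width * 2^level
    if (length(x) < 2L * max(idx) || min(idx) * w > max_lag) break
    for (k in idx) {
      if (k * w > max_lag) break
      n <- length(x)
      s_prod <- 0; s_l <- 0; s_r <- 0
      for (t in 1:(n - k)) {
        s_prod <- s_prod + x[t] * x[t + k]
        s_l <- s_l + x[t]
        s_r <- s_r + x[t + k]
      }
      np <- n - k
      lags <- c(lags, k * w)
      g <- c(g, (s_prod / np) / ((s_l / np) * (s_r / np)) - 1)
    }
    n2 <- length(x) %/% 2L
    xr <- numeric(n2)
    for (i in 1:n2) xr[i] <- (x[2 * i - 1] + x[2 * i]) / 2
    x <- xr
    level <- level + 1L
  }
  list(lags = lags, g = g)
}

# Textbook Pearson correlation from the covariance definition.
direct_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  cov <- sum((x - mx) * (y - my)) / (n - 1)
  cov / sqrt(sum((x - mx)^2) / (n - 1)) / sqrt(sum((y - my)^2) / (n - 1))
}

geom_std <- function() beam_geometry(0.145, 5)

lag_grid_std <- function(n = 200, lo = -5, hi = 0) 10^seq(lo, hi, length.out = n)

# random valid parameter draws for round-trip sweeps
draw_acf1_params <- function() {
  list(n_particles = 10^runif(1, -1, 1.5), tau_d = 10^runif(1, -5, -3))
}
draw_acf2_params <- function() {
  td1 <- 10^runif(1, -4.5, -3.5)
  list(n_particles = 10^runif(1, -1, 1.5), f1 = runif(1, 0.25, 0.9),
       tau_d1 = td1, tau_d2 = td1 * 10^runif(1, 1, 2))
}
draw_frap_params <- function() {
  fd <- runif(1, 0, 0.4)
  list(fd = fd, fi = runif(1, fd + 0.3, 1), m = 10^runif(1, -0.2, 1),
       alpha = runif(1, 0.6, 1.4))
}
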