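test_that("the two-component fit recovers noiseless generating parameters", {
  g <- geom_std()
  truth <- list(n_particles = 1, f1 = 0.73, tau_d1 = 135.8e-6,
                tau_d2 = 4.043e-3)
  cv <- generate_analytic_acf(truth, g, lag_grid_std(200))
  fit <- fit_acf(cv, "two_component_3d2d", g)
  expect_true(fit$converged)
  expect_equal(fit$params$n_particles, 1, tolerance = 1e-3)
  expect_equal(fit$params$f1, 0.73, tolerance = 1e-3)
  expect_equal(fit$params$tau_d1, 135.8e-6, tolerance = 1e-3)
  expect_equal(fit$params$tau_d2, 4.043e-3, tolerance = 1e-3)
  # derived values are consistent with the conversion relation
  expect_equal(fit$d_fast, diffusion_from_tau(fit$params$tau_d1, g),
               tolerance = 1e-12)
  expect_equal(fit$slow_fraction_pct, 100 * (1 - fit$params$f1),
               tolerance = 1e-12)
})

test_that("noiseless round trips recover parameters to 0.1% across random draws", {
  g <- geom_std()
  set.seed(42)
  for (i in 1:25) {
    p <- draw_acf1_params()
    cv <- generate_analytic_acf(p, g, lag_grid_std(150))
    fit <- fit_acf(cv, "one_component_3d", g)
    expect_equal(fit$params$n_particles, p$n_particles, tolerance = 1e-3)
    expect_equal(fit$params$tau_d1, p$tau_d, tolerance = 1e-3)
  }
  for (i in 1:25) {
    p <- draw_acf2_params()
    cv <- generate_analytic_acf(p, g, lag_grid_std(150))
    fit <- fit_acf(cv, "two_component_3d2d", g)
    expect_equal(fit$params$n_particles, p$n_particles, tolerance = 1e-3)
    expect_equal(fit$params$f1, p$f1, tolerance = 1e-3)
    expect_equal(fit$params$tau_d1, p$tau_d1, tolerance = 1e-3)
    expect_equal(fit$params$tau_d2, p$tau_d2, tolerance = 1e-3)
  }
})

test_that("fitting is invariant to the unit of the lag axis after conversion", {
  g <- geom_std()
  truth <- list(n_particles = 2, f1 = 0.6, tau_d1 = 1e-4, tau_d2 = 3e-3)
  cv <- generate_analytic_acf(truth, g, lag_grid_std(120))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_acf_csv(cv, tmp)  # written in ms
  cv2 <- read_acf_csv(tmp) # converted back to s
  f1 <- fit_acf(cv, "two_component_3d2d", g)
  f2 <- fit_acf(cv2, "two_component_3d2d", g)
  expect_equal(f1$params$tau_d1, f2$params$tau_d1, tolerance = 1e-6)
})

test_that("the nested one-component limit is handled without label ambiguity", {
  g <- geom_std()
  cv <- generate_analytic_acf(list(n_particles = 1.5, tau_d = 2.5e-4), g,
                              lag_grid_std(150))
  f1c <- fit_acf(cv, "one_component_3d", g)
  f2c <- fit_acf(cv, "two_component_3d2d", g)
  expect_true(f2c$params$f1 >= 0.999 ||
                f2c$params$tau_d2 / f2c$params$tau_d1 < 1.05)
  # both SSEs are machine zeros; compare with an additive floor
  expect_lte(f2c$sse, f1c$sse + 1e-20)
  expect_true(f2c$params$tau_d1 < f2c$params$tau_d2)
})

test_that("an all-zero curve is flagged rather than fitted", {
  flat <- correlation_curve(lag_grid_std(60), rep(0, 60))
  fit <- fit_acf(flat, "one_component_3d", geom_std())
  expect_false(fit$converged)
  expect_true(is.na(fit$d_fast))
})

test_that("too few lags in the fit window is an error", {
  g <- geom_std()
  cv <- generate_analytic_acf(list(n_particles = 1, tau_d = 2e-4), g,
                              lag_grid_std(6))
  expect_error(fit_acf(cv, "one_component_3d", g), "8 lags")
})

test_that("model selection distinguishes one- from two-component data", {
  g <- geom_std()
  cfg <- fit_config()
  # two components, taud ratio 30, 1% multiplicative noise
  cv2 <- generate_analytic_acf(
    list(n_particles = 1, f1 = 0.7, tau_d1 = 1.5e-4, tau_d2 = 4.5e-3), g,
    lag_grid_std(200), "multiplicative_gaussian", 0.01, rng_seed = 21)
  expect_equal(select_model(cv2, g, cfg)$model_id, "two_component_3d2d")
  # one component, same noise
  cv1 <- generate_analytic_acf(list(n_particles = 1, tau_d = 2e-4), g,
                               lag_grid_std(200), "multiplicative_gaussian",
                               0.01, rng_seed = 22)
  expect_equal(select_model(cv1, g, cfg)$model_id, "one_component_3d")
  # noiseless one component: parsimony wins on a perfect fit
  cv0 <- generate_analytic_acf(list(n_particles = 1, tau_d = 2e-4), g,
                               lag_grid_std(200))
  expect_equal(select_model(cv0, g, cfg)$model_id, "one_component_3d")
  # runs-test variant agrees on clear-cut data
  cfg_rt <- fit_config(model_selection_criterion = "aic_plus_runs_test")
  expect_equal(select_model(cv2, g, cfg_rt)$model_id, "two_component_3d2d")
  expect_equal(select_model(cv1, g, cfg_rt)$model_id, "one_component_3d")
})

test_that("FRAP normalization inverts the generating construction", {
  t <- seq(1, 60)
  f_true <- frap_model(t, 0.1, 1.0, 2, 1)
  bg <- rep(10, 60)
  ic <- bg + 1000 * exp(-t / 200)
  ib <- bg + (ic - bg) * f_true
  out <- normalize_frap(t, ib, ic, bg)
  # reference: plateau = max 3-frame moving average over the last 20%
  win <- 49:60
  mov3 <- vapply(win, function(i) mean(f_true[max(1, i - 1):min(60, i + 1)]),
                 numeric(1))
  expect_equal(out$f, f_true / max(mov3), tolerance = 1e-10)
  # flat ratio normalizes to one
  ones <- normalize_frap(t, ic, ic, bg)
  expect_equal(ones$f, rep(1, 60), tolerance = 1e-12)
  # background above cell intensity names the offending frame
  ic_bad <- ic
  ic_bad[5] <- 5
  expect_error(normalize_frap(t, ib, ic_bad, bg), "frame 5")
})

test_that("FRAP fit recovers noiseless parameters and degrades gracefully", {
  t <- seq(1, 60)
  f <- frap_model(t, 0.1, 1.0, 2, 1)
  fit <- fit_frap(t, f)
  expect_true(fit$converged)
  expect_equal(fit$t_half, 2, tolerance = 5e-3)
  expect_equal(fit$params$fd, 0.1, tolerance = 1e-3)
  expect_equal(fit$params$fi, 1.0, tolerance = 1e-3)
  # sweep of random parameter sets
  set.seed(77)
  for (i in 1:25) {
    p <- draw_frap_params()
    tt <- seq(0.5, 12 * p$m, length.out = 80)
    fit <- fit_frap(tt, frap_model(tt, p$fd, p$fi, p$m, p$alpha))
    expect_equal(fit$params$m, p$m, tolerance = 1e-3)
    expect_equal(fit$params$fd, p$fd, tolerance = 2e-3)
    expect_equal(fit$params$fi, p$fi, tolerance = 2e-3)
  }
  # no recovery: plateau equals post-bleach level, mobile fraction ~ 0
  flat <- fit_frap(t, rep(0.42, 60))
  expect_lt(flat$mobile_fraction_pct, 1)
})

test_that("noisy FRAP fits recover the half-time within 5% in the median", {
  t <- seq(0, 59)
  f_true <- frap_model(t, 0.1, 0.95, 2, 1)
  set.seed(13)
  err <- vapply(1:100, function(i) {
    fit <- fit_frap(t, f_true + rnorm(60, 0, 0.02))
    abs(fit$params$m - 2) / 2
  }, numeric(1))
  expect_lt(median(err), 0.05)
})
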