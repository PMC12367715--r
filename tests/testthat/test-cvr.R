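test_that("exponential kernel has the documented closed form", {
  expect_equal(exp_kernel(0, 2, 5), c(1, 0, 0, 0, 0))
  for (tau in c(0.5, 3, 20, 100))
    expect_equal(sum(exp_kernel(tau, 2, 50)), 1)
  h <- exp_kernel(2, 2, 3)
  expect_equal(h, c(1, exp(-1), exp(-2)) / sum(c(1, exp(-1), exp(-2))))
})

test_that("magnitude fit matches constructed signals and the OLS oracle", {
  set.seed(3)
  n <- 80
  reg <- rnorm(n, 0, 4)
  reg <- reg - mean(reg)
  s0 <- 500
  ts <- s0 * (1 + 0.001 * reg)
  est <- fit_magnitude(ts, reg)
  expect_true(est$valid)
  expect_equal(est$magnitude, 0.1, tolerance = 1e-9)

  # orthogonal-by-construction noise leaves the magnitude at zero
  noise <- rnorm(n)
  noise <- drop(noise - cbind(1, seq_len(n), reg) %*%
                  solve(crossprod(cbind(1, seq_len(n), reg)),
                        crossprod(cbind(1, seq_len(n), reg), noise)))
  est0 <- fit_magnitude(s0 + noise, reg)
  expect_equal(est0$magnitude, 0, tolerance = 1e-9)

  # mean-zero linear drift: same magnitude as without, and equal to the
  # normal-equations oracle
  drift <- 0.8 * (seq_len(n) - mean(seq_len(n)))
  tsd <- ts + drift
  estd <- fit_magnitude(tsd, reg, drift_order = 1)
  X <- cbind(1, seq_len(n), reg)
  b <- solve(crossprod(X), crossprod(X, tsd))
  expect_equal(estd$magnitude, 100 * b[3] / mean(tsd), tolerance = 1e-9)
  expect_equal(estd$magnitude, est$magnitude, tolerance = 1e-9)
})

test_that("magnitude estimator is scale-equivariant and flags bad voxels", {
  set.seed(4)
  n <- 60
  reg <- sin(seq_len(n) / 5)
  ts <- 300 * (1 + 0.002 * reg) + rnorm(n, 0, 0.5)
  est <- fit_magnitude(ts, reg)
  for (c_ts in c(0.1, 7)) {
    expect_equal(fit_magnitude(c_ts * ts, reg)$magnitude, est$magnitude)
  }
  for (c_reg in c(0.5, 4)) {
    expect_equal(fit_magnitude(ts, c_reg * reg)$magnitude,
                 est$magnitude / c_reg)
  }
  flat <- fit_magnitude(rep(300, n), reg)
  expect_false(flat$valid)
  expect_true(is.na(flat$magnitude))
  expect_error(fit_magnitude(ts, rep(1, n)), "constant")
})

test_that("dispersion fit recovers generative constants and boundary cases", {
  cfg <- tiny_config(bold_noise_sd = 0, etco2_jitter_sd_mmHg = 0)
  trace <- generate_etco2(cfg)
  reg <- to_regressor(trace, cfg$tr_s, cfg$n_volumes)
  ts <- make_voxel_series(0.1, 20, cfg, trace)
  est <- fit_tau(ts, reg, cfg$tr_s)
  expect_true(est$converged)
  expect_equal(est$tau_s, 20, tolerance = 1e-4)

  # generative constant below the lower bound -> pinned near the bound
  ts0 <- make_voxel_series(0.1, 0, cfg, trace)
  est0 <- fit_tau(ts0, reg, cfg$tr_s, bounds_s = c(5, 120))
  expect_true(est0$converged)
  expect_lt(est0$tau_s, 5 * exp(log(120 / 5) / 39) * 1.01)

  # flat series: no information, flagged
  flat <- fit_tau(rep(100, cfg$n_volumes), reg, cfg$tr_s)
  expect_false(flat$converged)
  expect_true(is.na(flat$tau_s))
})

test_that("dispersion fit agrees with an exhaustive fine-grid minimiser", {
  cfg <- tiny_config(bold_noise_sd = 0, etco2_jitter_sd_mmHg = 0.4)
  trace <- generate_etco2(cfg, seed = 9)
  reg <- to_regressor(trace, cfg$tr_s, cfg$n_volumes)
  x <- reg$values
  n <- cfg$n_volumes
  Q <- qr.Q(qr(cbind(1, poly(seq_len(n), 1))))
  fine <- seq(1, 120, by = 0.1)
  set.seed(5)
  taus <- runif(20, 2, 110)
  for (tau in taus) {
    ts <- make_voxel_series(0.15, tau, cfg, trace)
    est <- fit_tau(ts, reg, cfg$tr_s)
    yr <- drop(ts - Q %*% crossprod(Q, ts))
    rss0 <- sum(yr^2)
    rss <- vapply(fine, function(tt) {
      cx <- convolve(x, rev(exp_kernel(tt, cfg$tr_s, n)), type = "open")[1:n]
      cr <- drop(cx - Q %*% crossprod(Q, cx))
      rss0 - sum(cr * yr)^2 / sum(cr^2)
    }, numeric(1))
    expect_equal(est$tau_s, fine[which.min(rss)], tolerance = 0.1)
    expect_equal(est$tau_s, tau, tolerance = 1e-3)
  }
})

test_that("volume fit recovers known voxels and flags degenerate ones", {
  cfg <- tiny_config(bold_noise_sd = 0, etco2_jitter_sd_mmHg = 0)
  trace <- generate_etco2(cfg)
  reg <- to_regressor(trace, cfg$tr_s, cfg$n_volumes)
  sp <- c(3, 1, 1)
  cvr <- array(c(0.05, 0.22, 0.1), sp)
  tau <- array(c(10, 60, 35), sp)
  cfg2 <- tiny_config(grid_shape = sp, bold_noise_sd = 0,
                      etco2_jitter_sd_mmHg = 0)
  bold <- generate_bold(cvr, tau, trace, cfg2)
  # make the third voxel constant: must be QC-flagged, not fatal
  bold$data[3, 1, 1, ] <- 1000
  maps <- fit_volume(bold, array(TRUE, sp), reg)
  expect_equal(maps$magnitude_map[1:2], as.vector(cvr)[1:2], tolerance = 1e-7)
  expect_equal(maps$tau_map[1:2], as.vector(tau)[1:2], tolerance = 1e-3)
  expect_equal(maps$qc_map[1:2], c(0L, 0L))
  expect_gt(maps$qc_map[3], 0)
  expect_true(is.na(maps$magnitude_map[3]))
  expect_error(fit_volume(bold, array(FALSE, sp), reg), "empty mask")
})

test_that("magnitude map tracks the truth under mild noise", {
  nv <- 150
  sp <- c(nv, 1, 1)
  # full-length acquisition: the correlation bound needs the default 120
  # volumes' worth of information
  cfg <- sim_config(grid_shape = sp, bold_noise_sd = 0.001, seed = 42)
  set.seed(6)
  cvr <- array(runif(nv, 0.01, 0.3), sp)
  tau <- array(runif(nv, 5, 100), sp)
  trace <- generate_etco2(cfg, seed = 10)
  bold <- generate_bold(cvr, tau, trace, cfg, seed = 11)
  reg <- to_regressor(trace, cfg$tr_s, cfg$n_volumes)
  maps <- fit_volume(bold, array(TRUE, sp), reg)
  expect_gt(cor(as.vector(maps$magnitude_map), as.vector(cvr)), 0.95)
})
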