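test_that("decoupled noiseless rate model relaxes to phi(I) with its time constant", {
  p <- rate_params(J_EE = 0, J_EI = 0, J_IE = 0, J_II = 0, noise_sigma = 0,
                   tau_E = 1, tau_I = 2, I_ext_E = 2, I_ext_I = 1,
                   dt = 0.01, T_s = 12)
  s <- simulate_rate(p, seed = 1)
  # fixed point phi(I) held exactly once reached
  expect_equal(unname(s$rates[nrow(s$rates), ]), c(2, 1), tolerance = 1e-6)
  # pulse perturbation: closed-form exponential relaxation back to baseline
  s2 <- simulate_rate(p, pulse_times = 2, seed = 1)
  idx <- s2$time > 2.5 & s2$time < 8   # after the pulse ends
  theory <- 2 + (s2$rates[max(which(s2$time <= 2.5)), "E"] - 2) *
    exp(-(s2$time[idx] - 2.5) / p$tau_E)
  expect_equal(s2$rates[idx, "E"], theory, tolerance = 0.02)
})

test_that("rate simulation is reproducible and flags divergence", {
  p <- rate_params(T_s = 20)
  expect_identical(simulate_rate(p, seed = 4)$rates,
                   simulate_rate(p, seed = 4)$rates)
  bad <- rate_params(J_EE = 40, J_EI = 0.1, I_ext_E = 10, T_s = 50,
                     noise_sigma = 0)
  expect_error(simulate_rate(bad, pulse_times = 5, seed = 1), "unstable|diverg")
})

test_that("analytic correlations reduce to the OU closed form when decoupled", {
  p <- rate_params(J_EE = 0, J_EI = 0, J_IE = 0, J_II = 0,
                   tau_E = 1, tau_I = 1, noise_sigma = 0.2)
  an <- analytic_rate_correlation(p, gcamp_tau_s = 0, max_lag_s = 5, dt = 0.05)
  expect_equal(an$ei$values, rep(0, length(an$ei$lags)), tolerance = 1e-10)
  expect_equal(an$ee$values, exp(-abs(an$ee$lags) / 1), tolerance = 1e-8)
})

test_that("analytic covariances match an independent spectral-integration oracle", {
  p <- rate_params(J_EI = 1.5)
  A <- pupdyn:::rate_jacobian(p)
  D <- diag(c(p$noise_sigma^2 / p$tau_E^2, p$noise_sigma^2 / p$tau_I^2))
  taus <- c(0, 0.5, 1, 2, 4)
  orac <- spectral_covariance(A, D, taus)
  an <- analytic_rate_correlation(p, gcamp_tau_s = 0, max_lag_s = 5, dt = 0.5)
  # normalize the oracle the same way
  see <- orac[1, 1, 1]; sii <- orac[2, 2, 1]
  for (k in seq_along(taus)) {
    expect_equal(an$ee$values[an$ee$lags == taus[k]],
                 orac[1, 1, k] / see, tolerance = 1e-3)
    # oracle C(tau)[i,j] = cov(x_i(t + tau), x_j(t)) = our ie at +tau
    expect_equal(an$ie$values[an$ie$lags == taus[k]],
                 orac[1, 2, k] / sqrt(see * sii), tolerance = 1e-3)
  }
})

test_that("unstable or non-interior parameter sets are rejected analytically", {
  expect_error(analytic_rate_correlation(rate_params(J_EE = 40, J_EI = 0.01)),
               "unstable|interior")
})

test_that("GCaMP convolution has the exact exponential impulse response and is linear", {
  dt <- 0.1
  x <- c(1, rep(0, 49))
  y <- gcamp_convolve(x, dt, tau_s = 2)
  expect_equal(y, exp(-(0:49) * dt / 2), tolerance = 1e-12)
  # steady state under constant input: geometric sum
  yc <- gcamp_convolve(rep(1, 400), dt, 2)
  expect_equal(yc[400], 1 / (1 - exp(-dt / 2)), tolerance = 1e-6)
  # superposition on random signals
  set.seed(9)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(gcamp_convolve(a + 2 * b, dt, 2),
               gcamp_convolve(a, dt, 2) + 2 * gcamp_convolve(b, dt, 2),
               tolerance = 1e-10)
})

test_that("weak inhibition relaxes monotonically while strong inhibition undershoots", {
  pulses <- seq(30, 370, by = 40)
  resp <- lapply(c(weak = 0.2, strong = 2), function(j) {
    p <- rate_params(J_EI = j, T_s = 400, noise_sigma = 0.02)
    model_pmth(simulate_rate(p, pulses, seed = 6))
  })
  dev <- lapply(resp, function(m) m$response - m$baseline)
  post <- resp$weak$bin_centers > 0
  noise_scale <- sd(dev$weak[resp$weak$bin_centers < -2])
  expect_lt(-min(dev$weak[post]), 5 * noise_scale + 1e-9)   # no real undershoot
  expect_gt(-min(dev$strong[post]), 0.2 * max(dev$strong))  # marked undershoot
  expect_gt(max(dev$weak), 0)
})

test_that("single noiseless LIF neuron matches the closed-form rate within 2%", {
  p <- lif_params(N_E = 1, N_I = 0, C_EE = 0, C_EI = 0, C_IE = 0, C_II = 0,
                  I_ext_E = 1.4, noise_sd = 0, dt = 1e-4, T_s = 60)
  s <- simulate_lif(p, seed = 1)
  emp <- length(s$spike_times) / p$T_s
  theory <- lif_rate_closed_form(1.4, p$tau_m, p$V_th, p$V_reset, p$tau_ref)
  expect_lt(abs(emp - theory) / theory, 0.02)
  # subthreshold constant drive, no connections -> silent
  p0 <- lif_params(N_E = 5, N_I = 0, C_EE = 0, C_EI = 0, C_IE = 0, C_II = 0,
                   I_ext_E = 0.9, noise_sd = 0, T_s = 10)
  expect_length(simulate_lif(p0, seed = 1)$spike_times, 0)
  expect_equal(lif_rate_closed_form(0.5, 0.05, 1, 0, 0.005), 0)
})

test_that("LIF simulation is reproducible and validates in-degrees", {
  p <- lif_params(N_E = 50, N_I = 20, C_EE = 10, C_EI = 5, C_IE = 10,
                  C_II = 5, T_s = 5)
  expect_identical(simulate_lif(p, seed = 3)$spike_times,
                   simulate_lif(p, seed = 3)$spike_times)
  expect_error(lif_params(N_I = 10, C_EI = 50), "C_EI")
})

test_that("raising the I-to-E in-degree lowers excitatory activity and pulse response", {
  fr <- vapply(c(10, 20, 40), function(cei) {
    s <- simulate_lif(lif_params(C_EI = cei, T_s = 40), seed = 4)
    mean(s$active_frac_E)
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
  pulses <- seq(20, 180, by = 20)
  peaks <- vapply(c(10, 20), function(cei) {
    s <- simulate_lif(lif_params(C_EI = cei, T_s = 200), pulses, seed = 5)
    m <- model_pmth(s)
    max(m$response) - m$baseline
  }, numeric(1))
  expect_lt(peaks[2], peaks[1])
})

test_that("model PMTH averages pulse-triggered responses on the shared contract", {
  # periodic identical responses: average equals any single response
  p <- rate_params(J_EI = 2, noise_sigma = 0, T_s = 120)
  pulses <- c(30, 60, 90)
  s <- simulate_rate(p, pulses, seed = 1)
  m <- model_pmth(s, window_s = 20)
  one <- gcamp_convolve(s$rates[, "E"], p$dt)
  half <- round(10 / p$dt)
  i0 <- round(30 / p$dt)
  expect_equal(m$response, one[(i0 - half):(i0 + half)], tolerance = 0.02)
  expect_error(model_pmth(simulate_rate(p, numeric(), seed = 1)), "no pulses")
})

test_that("J_EI sweep deepens the undershoot and the correlogram minimum monotonically", {
  pulses <- seq(30, 270, by = 40)
  base <- rate_params(T_s = 300, noise_sigma = 0.02)
  tab <- sweep_jei(base, c(0.2, 0.7, 1.4, 2), pulses, seed = 7)
  expect_true(all(diff(tab$undershoot) > 0))
  expect_true(all(diff(tab$corr_min_pos) < 0))
  expect_identical(tab, sweep_jei(base, c(0.2, 0.7, 1.4, 2), pulses, seed = 7))
})
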