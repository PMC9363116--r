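test_that("movement generation is seeded, labelled by duration and rate-controlled", {
  des <- session_design()
  m1 <- generate_movements(des, seed = 3)
  m2 <- generate_movements(des, seed = 3)
  expect_identical(m1, m2)
  expect_false(identical(m1, generate_movements(des, seed = 4)))
  # labels follow realised durations
  durs <- (m1$offset - m1$onset) / des$frame_rate
  expect_true(all(m1$category[durs < 1] == "twitch"))
  expect_true(all(m1$category[durs >= 2] == "complex"))
  # zero rate -> empty list
  m0 <- generate_movements(session_design(movement_rate = 0), seed = 1)
  expect_equal(nrow(m0), 0)
  # non-overlap
  if (nrow(m1) > 1)
    expect_true(all(m1$onset[-1] > m1$offset[-nrow(m1)]))
})

test_that("log-duration sample mean matches the designed log-normal (law of large numbers)", {
  # pure twitch component over a long session, thousands of draws
  des <- session_design(duration_s = 7200, movement_rate = 25,
                        twitch_fraction = 1)
  m <- generate_movements(des, seed = 8)
  logd <- log((m$offset - m$onset) / des$frame_rate)
  n <- length(logd)
  expect_gt(n, 2000)
  # brute-force oracle for the frame-quantised log-normal mean
  set.seed(99)
  oracle <- log(pmax(1, round(rlnorm(2e5, des$move_mu, des$move_sigma) *
                                des$frame_rate)) / des$frame_rate)
  se <- sd(logd) / sqrt(n)
  expect_lt(abs(mean(logd) - mean(oracle)), 3 * se)
})

test_that("infeasible movement density errors", {
  des <- session_design(movement_rate = 200, twitch_fraction = 0,
                        complex_mu = log(5))
  expect_error(generate_movements(des, seed = 1), "occupancy")
})

test_that("uncoupled sessions have Poisson-consistent transient counts", {
  des <- session_design(n_pyr = 200, n_int = 0, duration_s = 600,
                        baseline_rate_pyr = 2,
                        coupling = list(pyramidal = c(pre = 1, post = 1),
                                        interneuron = c(pre = 1, post = 1)),
                        sce_rate = 0)
  b <- generate_session(des, age_days = 7, seed = 21, traces = FALSE)
  counts <- vapply(b$raster$transients, nrow, integer(1))
  lambda <- 2 * 10  # transients/min x minutes
  # chi-square goodness of fit against Poisson(lambda), pooled tails
  br <- c(-Inf, qpois(seq(0.1, 0.9, by = 0.2), lambda), Inf)
  obs <- table(cut(counts, br))
  pr <- diff(ppois(br, lambda))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr / sum(pr)))$p.value, 0.01)
})

test_that("movement coupling raises post-onset activation before the switch age", {
  des <- session_design(n_pyr = 150, n_int = 0, sce_rate = 0)
  b <- generate_session(des, age_days = 5, seed = 31, traces = FALSE)
  act <- b$raster$activity
  half <- 2 * 10
  onsets <- b$movements$onset
  onsets <- onsets[onsets > half & onsets + half - 1 <= ncol(act)]
  frac <- vapply(onsets, function(on) {
    post <- mean(rowSums(act[, on:(on + half - 1)]) > 0)
    pre <- mean(rowSums(act[, (on - half):(on - 1)]) > 0)
    post - pre
  }, numeric(1))
  expect_gt(mean(frac), 0)          # paired over movements
  expect_gt(mean(frac > 0), 0.6)
})

test_that("post-switch sessions show movement-related inhibition downstream", {
  des <- session_design()
  b <- generate_session(des, age_days = 12, seed = 41, traces = FALSE)
  expect_lt(median(movement_activity_ratios(b), na.rm = TRUE), 0.5)
})

test_that("session generation is deterministic and respects the DF/F kernel", {
  des <- session_design(n_pyr = 10, n_int = 2, duration_s = 60,
                        dff_noise_sd = 0)
  b1 <- generate_session(des, 7, seed = 5)
  b2 <- generate_session(des, 7, seed = 5)
  expect_identical(b1$raster$activity, b2$raster$activity)
  expect_equal(b1$traces, b2$traces)
  # noiseless DF/F decays as exp(-t / tau) after a transient peak
  ci <- which.max(vapply(b1$raster$transients, nrow, integer(1)))
  pk <- b1$raster$transients[[ci]][1, "peak"]
  gap_ok <- pk + 6 <= ncol(b1$traces) &&
    all(b1$raster$activity[ci, (pk + 1):(pk + 6)] == 0)
  expect_true(gap_ok)
  expect_equal(b1$traces[ci, pk + 6] / b1$traces[ci, pk + 1],
               exp(-5 / (des$gcamp_tau_s * des$frame_rate)),
               tolerance = 1e-6)
})

test_that("EMG generator produces the designed states and recoverable twitches", {
  g <- generate_emg(emg_design(), seed = 2)
  expect_identical(g$trace, generate_emg(emg_design(), seed = 2)$trace)
  expect_length(g$high_windows, 5)
  expect_length(g$low_windows, 5)
  # two-level amplitude: rectified RMS within wake bins far above sleep bins
  rms <- function(t0) sqrt(mean(g$trace[(t0 * 1000 + 1):(t0 * 1000 + 1000)]^2))
  wake_rms <- mean(vapply(g$high_windows, rms, numeric(1)))
  sleep_rms <- mean(vapply(g$low_windows, rms, numeric(1)))
  expect_gt(wake_rms / sleep_rms, 5)
  expect_true(all(g$twitch_times >= 0))
})

test_that("LFP generator inserts reversing templates at the designed times and lag", {
  d <- lfp_design(duration_s = 60, sw_rate_per_min = 4, noise_sd = 0)
  g <- generate_lfp(d, seed = 3)
  expect_identical(g$ipsi$sr, generate_lfp(d, seed = 3)$ipsi$sr)
  i <- round(g$sw_times$ipsi[1] * g$fs) + 1
  expect_gt(g$ipsi$sr[i], 0)
  expect_lt(g$ipsi$so[i], 0)
  expect_lt(abs(g$ipsi$sp[i]), 0.2 * abs(g$ipsi$sr[i]))
  expect_equal(g$sw_times$contra[1] - g$sw_times$ipsi[1], d$lag_s)
})

test_that("syt2 phantom ground truth follows drawn in-range areas", {
  g <- generate_syt2_image(particle_areas_um2 = numeric(), seed = 1,
                           noise_sd = 0)
  expect_equal(g$truth_coverage_percent, 0)
  g1 <- generate_syt2_image(height = 50, width = 50, pixel_size_um = 0.2,
                            particle_areas_um2 = 1, seed = 1, noise_sd = 0)
  # one ~1 um^2 particle in a 100 um^2 field -> ~1% coverage
  expect_equal(g1$truth_coverage_percent,
               100 * g1$drawn_areas_um2 / (50 * 50 * 0.04))
  expect_equal(g1$truth_coverage_percent, 1, tolerance = 0.1)
})

test_that("axon movie generator returns masks matching the drawn branches", {
  des <- axon_movie_design(branches = list(cbind(c(8, 40), c(10, 42))))
  mv <- generate_axon_movie(des, seed = 4)
  expect_identical(mv$movie, generate_axon_movie(des, seed = 4)$movie)
  expect_length(mv$masks, 1)
  expect_gt(sum(mv$masks[[1]]), 30)
  # empty design -> background-only movie
  mv0 <- generate_axon_movie(axon_movie_design(noise_sd = 0), seed = 1)
  expect_equal(max(abs(mv0$movie)), 0)
})
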