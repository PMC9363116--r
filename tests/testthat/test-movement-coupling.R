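toy_bundle <- function() {
  # 2 cells, 30-frame session at 1 Hz so the 10-s PMTH window is 10 frames,
  # 3 movements with hand-placed activity
  transients <- list(cbind(c(12, 20), c(13, 21)), cbind(15, 16))
  r <- activity_raster(transients, 30, frame_rate = 1)
  m <- movement_epochs(c(12, 15, 19), c(13, 16, 20), n_frames = 30)
  session_bundle(r, m, meta = list(age_days = 7))
}

test_that("session PMTH matches hand enumeration on a toy session", {
  b <- toy_bundle()
  p <- pmth_session(b, n_surrogates = 20, window_s = 10, seed = 1)
  expect_equal(p$n_movements, 3)
  expect_length(p$bin_centers, 21)
  # per-bin active-cell counts around each onset, enumerated by hand
  counts <- colSums(b$raster$activity)
  win <- vapply(c(12, 15, 19), function(on) counts[(on - 10):(on + 10)],
                numeric(21))
  expect_equal(p$median, apply(win, 1, median) / 2 * 100)
  expect_equal(p$q25, apply(win, 1, quantile, 0.25, names = FALSE) / 2 * 100)
  expect_equal(p$q75, apply(win, 1, quantile, 0.75, names = FALSE) / 2 * 100)
})

test_that("PMTH median is 100% when every cell starts a transient at every onset", {
  onsets <- c(150, 300, 450)
  transients <- lapply(1:5, function(c) cbind(onsets, onsets + 3))
  r <- activity_raster(transients, 600)
  m <- movement_epochs(onsets, onsets + 5, n_frames = 600)
  b <- session_bundle(r, m, meta = list(age_days = 7))
  p <- pmth_session(b, n_surrogates = 20, seed = 1)
  expect_equal(p$median[p$bin_centers == 0], 100)
  expect_true(p$sig_up[p$bin_centers == 0])
})

test_that("null rasters stay inside the surrogate envelope almost everywhere", {
  r <- null_raster(60, 3000, rate_per_min = 4, seed = 11)
  m <- movement_epochs(seq(150, 2850, by = 150), seq(150, 2850, by = 150) + 10,
                       n_frames = 3000)
  b <- session_bundle(r, m, meta = list(age_days = 7))
  p <- pmth_session(b, n_surrogates = 200, seed = 2)
  inside <- p$median >= p$surrogate_p5 & p$median <= p$surrogate_p95
  expect_gte(mean(inside), 0.9)
})

test_that("PMTH is invariant to cell permutation and errors without usable movements", {
  r <- null_raster(20, 400, rate_per_min = 6, seed = 12)
  m <- movement_epochs(200, 210, n_frames = 400)
  b <- session_bundle(r, m, meta = list(age_days = 7))
  perm <- sample(20)
  rp <- r; rp$activity <- r$activity[perm, ]; rp$transients <- r$transients[perm]
  bp <- session_bundle(rp, m, meta = list(age_days = 7))
  expect_equal(pmth_session(bp, n_surrogates = 10, seed = 3)$median,
               pmth_session(b, n_surrogates = 10, seed = 3)$median)
  m_edge <- movement_epochs(30, 40, n_frames = 400)  # window exceeds session
  b_edge <- session_bundle(r, m_edge, meta = list(age_days = 7))
  expect_error(pmth_session(b_edge, n_surrogates = 10, seed = 1), "window")
})

test_that("group PMTH stacks session medians with percentile semantics", {
  b <- toy_bundle()
  p1 <- pmth_session(b, n_surrogates = 10, seed = 1)
  # single session: group median equals the session median
  g1 <- pmth_group(list(p1))
  expect_equal(g1$median, p1$median)
  # two identical sessions leave the median unchanged
  g2 <- pmth_group(list(p1, p1))
  expect_equal(g2$median, p1$median)
  # three sessions: direct percentile oracle on the stacked medians
  p2 <- p1; p2$median <- p1$median + 1
  p3 <- p1; p3$median <- p1$median - 2
  g3 <- pmth_group(list(p1, p2, p3))
  stacked <- rbind(p1$median, p2$median, p3$median)
  expect_equal(g3$median, apply(stacked, 2, median))
  expect_equal(g3$q25, apply(stacked, 2, quantile, 0.25, names = FALSE))
  # mixed binning is rejected
  p4 <- p1; p4$bin_centers <- p1$bin_centers * 2
  expect_error(pmth_group(list(p1, p4)), "binning")
})

test_that("post-movement activity ratio follows its definition exactly", {
  # 10 cells active in the window, 3 only in the post half -> 0.30
  post_only <- lapply(1:3, function(c) cbind(105, 110))
  pre_only <- lapply(1:7, function(c) cbind(85, 90))
  r <- activity_raster(c(post_only, pre_only), 200)
  expect_equal(post_movement_activity(r, 100), 0.3)
  # all active only post -> 1; all only pre -> 0
  r1 <- activity_raster(post_only, 200)
  expect_equal(post_movement_activity(r1, 100), 1)
  r0 <- activity_raster(pre_only, 200)
  expect_equal(post_movement_activity(r0, 100), 0)
  # no active cell in the window -> undefined
  expect_true(is.na(post_movement_activity(activity_raster(list(NULL), 200), 100)))
  # window outside the session errors
  expect_error(post_movement_activity(r, 10), "window")
})

test_that("a symmetric raster gives a balanced activity ratio", {
  # same number of pre-only and post-only cells plus one spanning cell
  trans <- c(lapply(1:4, function(c) cbind(85, 90)),
             lapply(1:4, function(c) cbind(105, 110)),
             list(cbind(95, 105)))
  r <- suppressWarnings(activity_raster(trans, 200))
  expect_equal(post_movement_activity(r, 100), 5 / 9)
})

test_that("inhibiting-movement proportion uses the strict 40% rule", {
  mk <- function(ratios) {
    # build a session whose per-movement ratios are exactly `ratios` by
    # classifying directly: use synthetic ratios through the public rule
    mean(ratios < 0.40)
  }
  expect_equal(mk(c(1, 1, 1)), 0)
  expect_equal(mk(c(0, 0)), 1)
  expect_equal(mk(c(0.3, 0.5, 0.39, 0.41)), 0.5)
  # end-to-end: pre-switch synthetic session has a low proportion
  des <- session_design(n_pyr = 150, n_int = 10, duration_s = 300)
  b <- generate_session(des, age_days = 5, seed = 51, traces = FALSE)
  expect_lt(inhibiting_movement_proportion(b), 0.2)
})

test_that("epoch-associated cells are flagged by the circular-shift percentile rule", {
  # a cell with all onsets inside a 20% epoch block is flagged
  nf <- 3000
  epochs <- 1:600
  dense <- cbind(seq(10, 590, by = 20), seq(10, 590, by = 20) + 2)
  others <- lapply(1:5, function(c) {
    on <- seq(50 + c, 2950, by = 97)
    cbind(on, on + 2)
  })
  r <- activity_raster(c(list(dense), others), nf)
  res <- epoch_associated_cells(r, epochs, seed = 3)
  expect_true(res$flag[1])
  # epochs covering all frames can never flag (shifted counts equal observed)
  res_all <- epoch_associated_cells(r, 1:nf, seed = 3)
  expect_false(any(res_all$flag))
  # transient-free cells are never flagged
  r0 <- activity_raster(list(NULL, cbind(10, 12)), 100)
  expect_false(epoch_associated_cells(r0, 1:20, seed = 1)$flag[1])
})

test_that("epoch-association calibration on independent null cells is ~1%", {
  r <- null_raster(400, 4000, rate_per_min = 3, seed = 13)
  res <- epoch_associated_cells(r, 1:800, seed = 14)
  band <- 2.58 * sqrt(0.01 * 0.99 / 400)
  expect_lt(res$fraction, 0.01 + band)
})

test_that("trend fits recover known curves", {
  x <- seq(3, 12, by = 0.5)
  # noiseless line
  f <- fit_trend(x, 2 * x + 1, "linear")
  expect_equal(unname(f$coefficients["slope"]), 2, tolerance = 1e-8)
  expect_equal(unname(f$coefficients["intercept"]), 1, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-8)
  # noiseless sigmoid with V50 = 9
  y <- 0.1 + 0.5 / (1 + exp(-2 * (x - 9)))
  fs <- fit_trend(x, y, "sigmoid")
  expect_lt(abs(fs$coefficients[["v50"]] - 9), 1e-3)
  expect_gt(fs$r2, 0.999)
  # quartic recovered by the polynomial fit
  yq <- 1 - 0.3 * x + 0.02 * x^4
  fq <- fit_trend(x, yq, "poly4")
  expect_equal(f4 <- unname(fq$coefficients["b4"]), 0.02, tolerance = 1e-6)
  # constant response: r2 = 0 by convention, flat prediction
  fc <- fit_trend(x, rep(0.7, length(x)), "sigmoid")
  expect_equal(fc$r2, 0)
  expect_equal(fc$predict(c(4, 10)), c(0.7, 0.7))
  # insufficient points
  expect_error(fit_trend(1:3, 1:3, "sigmoid"), "at least")
})
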