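test_that("Kapur threshold separates a bimodal image and is scale-free", {
  set.seed(31)
  img <- matrix(runif(10000, 0, 0.2), 100)
  img[40:60, 40:60] <- runif(441, 0.7, 1)
  thr <- kapur_threshold(img)
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.7)
})

test_that("coverage pipeline measures phantom ground truth with exact size filtering", {
  g <- generate_syt2_image(particle_areas_um2 = c(0.2, 1, 1, 2, 6), seed = 3)
  cv <- syt2_coverage(g$stack, pixel_size_um = 0.2,
                      background_roi = g$background_roi)
  # the 0.2 and 6 um^2 particles are outside [0.4, 4] and must be excluded
  expect_equal(cv$n_particles, 3)
  expect_true(all(cv$particle_areas_um2 >= 0.4 & cv$particle_areas_um2 <= 4))
  expect_lt(abs(cv$coverage_percent - g$truth_coverage_percent) /
              g$truth_coverage_percent, 0.1)
})

test_that("one 1-um^2 particle in a 100-um^2 field reads ~1% coverage", {
  g <- generate_syt2_image(height = 50, width = 50, pixel_size_um = 0.2,
                           particle_areas_um2 = 1, seed = 5, noise_sd = 0.01)
  cv <- syt2_coverage(g$stack, 0.2, g$background_roi)
  expect_equal(cv$n_particles, 1)
  expect_equal(cv$coverage_percent, g$truth_coverage_percent,
               tolerance = 0.1)
})

test_that("coverage is zero on blank input and invariant to intensity scaling", {
  blank <- array(0, c(4, 60, 60))
  roi <- matrix(FALSE, 60, 60); roi[1:5, 1:5] <- TRUE
  cb <- syt2_coverage(blank, 0.2, roi)
  expect_equal(cb$coverage_percent, 0)
  expect_equal(cb$n_particles, 0)
  g <- generate_syt2_image(particle_areas_um2 = c(1, 2), seed = 6)
  c1 <- syt2_coverage(g$stack, 0.2, g$background_roi)
  c2 <- syt2_coverage(g$stack * 0.37, 0.2, g$background_roi)
  expect_equal(c2$coverage_percent, c1$coverage_percent)
  expect_error(syt2_coverage(g$stack, 0.2, g$background_roi & FALSE), "ROI")
})

test_that("skeletonization recovers a straight branch within one pixel", {
  des <- axon_movie_design(branches = list(cbind(c(8, 40), c(10, 42))))
  mv <- generate_axon_movie(des, seed = 4)
  bs <- skeletonize_axons(mv$movie)
  expect_length(bs$branches, 1)
  expect_gt(dilated_dice(bs$skeleton, mv$masks[[1]]), 0.7)
})

test_that("a Y-shaped phantom splits into three branches at the junction", {
  des <- axon_movie_design(branches = list(
    cbind(c(24, 24), c(4, 24)), cbind(c(24, 8), c(24, 44)),
    cbind(c(24, 40), c(24, 44))))
  mv <- generate_axon_movie(des, seed = 6,
                            traces = matrix(0.8, 3, des$n_frames))
  bs <- skeletonize_axons(mv$movie)
  expect_length(bs$branches, 3)
})

test_that("structure-free movies produce no branches", {
  n <- vapply(11:20, function(s) length(skeletonize_axons(
    generate_axon_movie(axon_movie_design(), seed = s)$movie)$branches),
    numeric(1))
  expect_equal(sum(n), 0)
  # too-short movies are rejected
  expect_error(skeletonize_axons(array(0, c(5, 20, 20))), "10 frames")
})

test_that("branch validation keeps uniform branches and rejects partially lit ones", {
  h <- 40; w <- 40; nf <- 60
  px_full <- cbind(10, 5:35)          # uniformly lit branch
  px_part <- cbind(30, 5:35)          # lit on a quarter of its length only
  movie <- array(0.01, c(nf, h, w))
  lit <- 20:35
  movie[lit, 10, 5:35] <- 1
  movie[lit, 30, 5:11] <- 1           # the remaining pixels stay dark
  branches <- list(cbind(y = px_full[, 1], x = px_full[, 2]),
                   cbind(y = px_part[, 1], x = px_part[, 2]))
  keep <- validate_branches(movie, branches, skew_max = 1)
  expect_true(keep[1])
  expect_false(keep[2])
  # direct skewness oracle for the quarter-lit two-point distribution
  vals <- c(rep(1, 7), rep(0.01, 24))
  m <- mean(vals)
  skew <- mean((vals - m)^3) / mean((vals - m)^2)^1.5
  expect_gt(abs(skew), 1)
  # constant-intensity branch: zero variance -> skewness 0 -> kept
  movie2 <- array(0.5, c(nf, h, w))
  expect_true(validate_branches(movie2, branches[1], skew_max = 1)[1])
  # branches shorter than 5 px are auto-rejected
  short <- list(cbind(y = c(5, 5, 5), x = 5:7))
  expect_false(validate_branches(movie, short)[1])
})

test_that("branch clustering groups correlated traces and isolates the rest", {
  set.seed(41)
  tA <- cumsum(rnorm(80)); tB <- cumsum(rnorm(80))
  traces <- rbind(tA, tA + rnorm(80, 0, 1e-3), tB, tB + rnorm(80, 0, 1e-3))
  cl <- cluster_branches(traces)
  expect_equal(adjusted_rand(cl, c(1, 1, 2, 2)), 1)
  # identical traces collapse to one cluster
  cl_same <- cluster_branches(matrix(rep(sin(1:50), 4), 4, byrow = TRUE))
  expect_equal(length(unique(cl_same)), 1)
  expect_true(all(cl_same > 0))
  # all-constant traces have no usable correlation: all singletons
  cl_const <- cluster_branches(matrix(1, 5, 50))
  expect_true(all(cl_const == 0))
  expect_error(cluster_branches(matrix(1, 1, 50)), "at least 2")
  # label determinism
  expect_identical(cl, cluster_branches(traces))
})

test_that("end-to-end phantom clustering recovers the designed groups", {
  mv <- two_group_phantom(1)
  bs <- skeletonize_axons(mv$movie)
  expect_gte(length(bs$branches), 3)
  gt <- vapply(bs$branches, mv$group_of, integer(1))
  keep <- validate_branches(mv$movie, bs$branches)
  cl <- cluster_branches(branch_traces(mv$movie, bs$branches)[keep, ,
                                                              drop = FALSE])
  expect_equal(adjusted_rand(cl, gt[keep]), 1)
})
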