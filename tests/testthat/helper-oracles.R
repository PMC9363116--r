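# shared fixtures and small independent oracles, all built in code

# independent-cell null raster: per-cell Bernoulli transient onsets with a
# dead time, no cross-cell structure
null_raster <- function(n_cells, n_frames, rate_per_min = 2, seed = 1,
                        frame_rate = 10, dur_frames = 4L) {
  set.seed(seed)
  p <- rate_per_min / (60 * frame_rate)
  transients <- lapply(seq_len(n_cells), function(c) {
    ons <- which(stats::runif(n_frames) < p)
    if (!length(ons)) return(cbind(onset = integer(), peak = integer()))
    ons <- ons[c(TRUE, diff(ons) > dur_frames + 2L)]
    cbind(onset = ons, peak = pmin(n_frames, ons + dur_frames))
  })
  activity_raster(transients, n_frames, frame_rate)
}

# adjusted Rand index (closed form on the contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) sum(choose(x, 2))
  n <- length(a)
  e <- ch2(rowSums(tab)) * ch2(colSums(tab)) / choose(n, 2)
  (ch2(as.vector(tab)) - e) /
    ((ch2(rowSums(tab)) + ch2(colSums(tab))) / 2 - e)
}

# symmetric overlap score after 1-px dilation of both masks
dilated_dice <- function(skel, gt) {
  d1 <- EBImage::dilate(matrix(as.numeric(gt), nrow(gt), ncol(gt)),
                        EBImage::makeBrush(3, "box")) > 0
  d2 <- EBImage::dilate(matrix(as.numeric(skel), nrow(skel), ncol(skel)),
                        EBImage::makeBrush(3, "box")) > 0
  (sum(skel & d1) + sum(gt & d2)) / (sum(skel) + sum(gt))
}

# spectral-integration oracle for the stationary (cross-)covariance of the
# linear SDE dx = A x dt + sqrt(D) dW: C(tau) from the power spectrum
# S(w) = (iwI - A)^-1 D (-iwI - A^T)^-1, integrated numerically.
spectral_covariance <- function(A, D, taus, w_max = 200, n_w = 2^14) {
  ws <- seq(-w_max, w_max, length.out = n_w)
  dw <- ws[2] - ws[1]
  out <- array(0, c(2, 2, length(taus)))
  I2 <- diag(2)
  for (w in ws) {
    Sw <- solve(1i * w * I2 - A, D) %*% t(solve(-1i * w * I2 - A))
    ph <- exp(1i * w * taus)
    for (k in seq_along(taus))
      out[, , k] <- out[, , k] + Re(Sw * ph[k]) * dw / (2 * pi)
  }
  out
}

# two-group parallel-branch phantom used by the clustering recovery tests
two_group_phantom <- function(seed) {
  des <- axon_movie_design(height = 60, width = 60, branches = list(
    cbind(c(6, 6), c(5, 55)), cbind(c(16, 16), c(5, 55)),
    cbind(c(36, 36), c(5, 55)), cbind(c(48, 48), c(5, 55))))
  set.seed(seed + 999)
  mk_trace <- function() {
    tr <- numeric(des$n_frames)
    for (on in sample(10:(des$n_frames - 10), 4))
      tr[on:des$n_frames] <- pmax(tr[on:des$n_frames],
                                  exp(-(seq(on, des$n_frames) - on) / 8))
    tr + 0.05
  }
  tA <- mk_trace(); tB <- mk_trace()
  mv <- generate_axon_movie(des, seed = seed, traces = rbind(tA, tA, tB, tB))
  mv$group_of <- function(px) if (mean(px[, 1]) < 26) 1L else 2L
  mv
}
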