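#' Score vigilance states from a nuchal EMG trace
#'
#' The raw EMG is brought to 1000 Hz, high-pass filtered at 300 Hz
#' (zero-phase Butterworth) and rectified. Five 1-s representative windows
#' of high EMG tone and five of low tone provide the thresholds: bins at or
#' above the midpoint of the two mean rectified values are wake, bins below
#' the quarter point (low mean plus a quarter of the separation) are active
#' sleep, bins in between are a transition state. The trace is then cut
#' into non-overlapping 1-s bins and scored. Active-sleep samples exceeding
#' the low-tone mean + 5 SD are twitches; contiguous super-threshold
#' samples are grouped into one event. Bins whose average lies within 5% of
#' a threshold are flagged for review (a machine check standing in for
#' visual inspection of the hypnogram).
#'
#' @param emg numeric trace.
#' @param fs sampling rate, Hz; must be >= 1000 and an integer multiple of
#'   1000 (the trace is decimated to 1000 Hz).
#' @param high_windows,low_windows start times (s) of five 1-s
#'   representative windows of high and low EMG tone.
#' @return object of class \code{hypnogram}: \code{states} per 1-s bin
#'   (\code{wake}, \code{active_sleep}, \code{transition}),
#'   \code{twitch_times} (s), \code{thresholds} (midpoint, quarterpoint,
#'   twitch), \code{review_bins}, \code{bin_s = 1}.
#' @export
score_vigilance <- function(emg, fs, high_windows, low_windows) {
  stopifnot(fs >= 1000, length(high_windows) >= 1, length(low_windows) >= 1)
  if (fs != 1000) {
    if (fs %% 1000 != 0)
      stop("fs must be 1000 Hz or an integer multiple of it")
    emg <- emg[seq(1L, length(emg), by = fs / 1000)]
  }
  fs <- 1000
  bf <- signal::butter(4, 300 / (fs / 2), type = "high")
  rect <- abs(signal::filtfilt(bf, emg))
  n_bins <- floor(length(rect) / fs)
  if (n_bins < 1) stop("trace shorter than one 1-s bin")

  window_samples <- function(starts) {
    unlist(lapply(starts, function(t0) {
      i0 <- round(t0 * fs) + 1L
      i1 <- i0 + fs - 1L
      if (i0 < 1 || i1 > length(rect))
        stop("representative window at ", t0, " s is outside the record")
      rect[i0:i1]
    }))
  }
  hi <- window_samples(high_windows)
  lo <- window_samples(low_windows)
  mean_hi <- mean(hi); mean_lo <- mean(lo)
  if (mean_hi <= mean_lo)
    stop("high/low sample means are not separated: thresholds degenerate")
  midpoint <- (mean_hi + mean_lo) / 2
  quarterpoint <- mean_lo + (mean_hi - mean_lo) / 4
  twitch_level <- mean_lo + 5 * stats::sd(lo)

  bin_means <- colMeans(matrix(rect[seq_len(n_bins * fs)], nrow = fs))
  states <- ifelse(bin_means >= midpoint, "wake",
                   ifelse(bin_means < quarterpoint, "active_sleep",
                          "transition"))
  review <- which(abs(bin_means - midpoint) < 0.05 * midpoint |
                    abs(bin_means - quarterpoint) < 0.05 * quarterpoint)

  sleep_mask <- rep(states == "active_sleep", each = fs)
  super <- which(rect[seq_len(n_bins * fs)] > twitch_level & sleep_mask)
  # super-threshold samples separated by < 50 ms belong to one twitch
  twitch_times <- if (length(super)) {
    starts <- super[c(TRUE, diff(super) > 0.05 * fs)]
    (starts - 1L) / fs
  } else numeric(0)

  structure(list(states = states, bin_s = 1,
                 twitch_times = twitch_times,
                 thresholds = c(midpoint = midpoint,
                                quarterpoint = quarterpoint,
                                twitch = twitch_level),
                 review_bins = review),
            class = "hypnogram")
}

lowpass_decimate <- function(x, fs, target = 1000) {
  if (fs == target) return(x)
  if (fs < target || fs %% target != 0)
    stop("fs must be ", target, " Hz or an integer multiple of it")
  bf <- signal::butter(4, (target / 2.5) / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, x)
  y[seq(1L, length(y), by = fs / target)]
}

#' Band-pass and re-reference multi-channel LFP
#'
#' Downsamples to 1 kHz, band-passes 2-100 Hz with a zero-phase Butterworth
#' filter (the equivalent of a forward-inverse wavelet reconstruction over
#' the band; validated by frequency response) and subtracts the common
#' average reference at every time point.
#'
#' @param lfp numeric matrix, channels x samples.
#' @param fs sampling rate (Hz).
#' @return list with \code{lfp} (filtered channels x samples) and
#'   \code{fs} (1000).
#' @export
preprocess_lfp <- function(lfp, fs) {
  stopifnot(is.matrix(lfp), fs >= 250)
  target <- min(1000, fs)
  out <- t(apply(lfp, 1L, function(ch) {
    ch <- if (fs > 1000) lowpass_decimate(ch, fs, 1000) else ch
    bf <- signal::butter(2, c(2, 100) / (target / 2), type = "pass")
    signal::filtfilt(bf, ch)
  }))
  out <- sweep(out, 2L, colMeans(out))
  list(lfp = out, fs = target)
}

#' Detect early sharp waves (eSWs) in layered LFP
#'
#' The three layer traces (strata oriens, pyramidale, radiatum) are
#' band-passed 2-45 Hz and the radiatum-minus-oriens difference trace is
#' formed. Candidate events are local extrema of its absolute value
#' exceeding \code{threshold_sd} SDs computed over the entire trace;
#' a candidate is kept as an eSW only when the oriens and radiatum
#' deflections at the peak have opposite signs while the pyramidale trace
#' is close to the reversal (its amplitude below half the smaller flanking
#' deflection). Events closer than 100 ms are merged keeping the larger
#' peak.
#'
#' @param so,sp,sr layer traces (equal length).
#' @param fs sampling rate (Hz).
#' @param threshold_sd detection threshold in SDs of the difference trace
#'   (default 4).
#' @param min_separation_s minimal separation between events (s).
#' @return object of class \code{sw_event_set}: \code{event_times} (s),
#'   \code{rate_per_min}, \code{threshold}.
#' @export
detect_esw <- function(so, sp, sr, fs, threshold_sd = 4,
                       min_separation_s = 0.1) {
  stopifnot(length(so) == length(sp), length(so) == length(sr))
  bf <- signal::butter(2, c(2, 45) / (fs / 2), type = "pass")
  fso <- signal::filtfilt(bf, so)
  fsp <- signal::filtfilt(bf, sp)
  fsr <- signal::filtfilt(bf, sr)
  d <- fsr - fso
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    return(structure(list(event_times = numeric(), rate_per_min = 0,
                          threshold = 0), class = "sw_event_set"))
  thr <- threshold_sd * sd_d
  ad <- abs(d)
  cand <- local_maxima(ad)
  cand <- cand[ad[cand] > thr]
  keep <- vapply(cand, function(i) {
    rev_ok <- fso[i] * fsr[i] < 0
    sp_ok <- abs(fsp[i]) < 0.5 * min(abs(fso[i]), abs(fsr[i]))
    rev_ok && sp_ok
  }, logical(1))
  cand <- cand[keep]
  min_sep <- round(min_separation_s * fs)
  events <- merge_peaks(cand, ad, min_sep)
  minutes <- length(so) / fs / 60
  structure(list(event_times = (events - 1L) / fs,
                 rate_per_min = length(events) / minutes,
                 threshold = thr),
            class = "sw_event_set")
}

#' Inter-hemispheric sharp-wave co-occurrence
#'
#' Cross-correlates two sharp-wave timestamp trains: counts all
#' contralateral-minus-ipsilateral time differences within
#' \code{max_lag_s} in \code{bin_s}-wide bins and reports the lag of the
#' maximal bin (ties: the lag closest to zero).
#'
#' @param ipsi,contra event times (s).
#' @param bin_s bin width (default 0.010 s).
#' @param max_lag_s maximal lag considered (default 0.5 s).
#' @return list with \code{lags} (bin centres, s), \code{counts},
#'   \code{peak_lag_s}.
#' @export
esw_cooccurrence <- function(ipsi, contra, bin_s = 0.010, max_lag_s = 0.5) {
  stopifnot(length(ipsi) >= 1, length(contra) >= 1)
  diffs <- as.vector(outer(contra, ipsi, "-"))
  k <- round(max_lag_s / bin_s)
  centers <- seq(-k, k) * bin_s
  idx <- round(diffs / bin_s)
  idx <- idx[abs(idx) <= k]
  counts <- tabulate(idx + k + 1L, nbins = 2L * k + 1L)
  best <- which(counts == max(counts))
  peak <- centers[best[which.min(abs(centers[best]))]]
  list(lags = centers, counts = counts, peak_lag_s = peak)
}
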