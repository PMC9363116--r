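#' Design of a synthetic EMG recording
#'
#' The trace is a 400 Hz carrier whose amplitude follows a wake /
#' active-sleep schedule (two tone levels), with brief high-amplitude
#' bursts injected during sleep as muscle twitches. The carrier sits above
#' the 300 Hz high-pass corner of the scoring pipeline, so the rectified
#' level tracks the designed amplitude and the designed hypnogram is the
#' recoverable ground truth.
#'
#' @param duration_s record length (s).
#' @param fs sampling rate (Hz, >= 1000).
#' @param wake_s,sleep_s bout lengths of the alternating schedule (s),
#'   starting with sleep.
#' @param low_amp,high_amp carrier amplitudes in sleep and wake.
#' @param carrier_hz carrier frequency (must exceed 300 Hz).
#' @param twitch_rate twitches per minute of sleep.
#' @param twitch_amp_factor twitch amplitude as a multiple of
#'   \code{low_amp}; must clear the mean + 5 SD rule with margin.
#' @param twitch_dur_s twitch duration (s).
#' @param noise_sd additive Gaussian noise SD.
#' @return an \code{emg_design} list.
#' @export
emg_design <- function(duration_s = 120, fs = 1000,
                       wake_s = 20, sleep_s = 40,
                       low_amp = 0.02, high_amp = 0.2,
                       carrier_hz = 400,
                       twitch_rate = 6, twitch_amp_factor = 8,
                       twitch_dur_s = 0.1, noise_sd = 0) {
  d <- as.list(environment())
  stopifnot(d$fs >= 1000, d$carrier_hz > 300, d$low_amp < d$high_amp,
            d$duration_s >= d$wake_s + d$sleep_s)
  structure(d, class = "emg_design")
}

#' Generate a synthetic EMG trace with ground truth
#'
#' @param design an [emg_design()].
#' @param seed integer seed (twitch placement).
#' @return list with \code{trace}, \code{fs}, \code{states} (ground-truth
#'   state per 1-s bin), \code{twitch_times} (s), and suggested
#'   \code{high_windows} / \code{low_windows} (start times of five clean
#'   1-s representative windows per tone).
#' @export
generate_emg <- function(design, seed = 1) {
  stopifnot(inherits(design, "emg_design"))
  d <- design
  n <- round(d$duration_s * d$fs)
  tt <- (seq_len(n) - 1L) / d$fs
  cycle <- d$sleep_s + d$wake_s
  in_wake <- (tt %% cycle) >= d$sleep_s
  amp <- ifelse(in_wake, d$high_amp, d$low_amp)
  n_bins <- floor(d$duration_s)
  bin_start <- seq_len(n_bins) - 1
  states <- ifelse((bin_start %% cycle) >= d$sleep_s, "wake", "active_sleep")

  with_seed(seed, {
    sleep_time <- sum(!in_wake) / d$fs
    n_twitch <- stats::rpois(1, d$twitch_rate * sleep_time / 60)
    twitch_times <- numeric(0)
    guard <- 0.5  # keep twitches clear of bin and state boundaries
    tries <- 0
    while (length(twitch_times) < n_twitch && tries < 2000) {
      tries <- tries + 1
      t0 <- stats::runif(1, 0, d$duration_s - d$twitch_dur_s)
      phase <- t0 %% cycle
      ok_state <- phase > guard &&
        phase + d$twitch_dur_s < d$sleep_s - guard
      ok_apart <- !length(twitch_times) ||
        all(abs(twitch_times - t0) > 3 * d$twitch_dur_s)
      within_bin <- floor(t0) == floor(t0 + d$twitch_dur_s)
      if (ok_state && ok_apart && within_bin)
        twitch_times <- c(twitch_times, t0)
    }
    twitch_times <- sort(twitch_times)
    for (t0 in twitch_times) {
      idx <- which(tt >= t0 & tt < t0 + d$twitch_dur_s)
      amp[idx] <- d$twitch_amp_factor * d$low_amp
    }
    trace <- amp * sin(2 * pi * d$carrier_hz * tt)
    if (d$noise_sd > 0) trace <- trace + stats::rnorm(n, 0, d$noise_sd)

    clean_windows <- function(state) {
      starts <- bin_start[states == state]
      starts <- starts[!vapply(starts, function(s)
        any(twitch_times >= s - 1 & twitch_times < s + 2), logical(1))]
      # avoid the first/last bin of each bout (filter edge effects)
      keep <- vapply(starts, function(s) {
        phase <- s %% cycle
        if (state == "wake") phase > d$sleep_s & phase < cycle - 1
        else phase >= 1 & phase < d$sleep_s - 1
      }, logical(1))
      starts <- starts[keep]
      starts[round(seq(1, length(starts), length.out = min(5, length(starts))))]
    }
    list(trace = trace, fs = d$fs, states = states,
         twitch_times = twitch_times,
         high_windows = clean_windows("wake"),
         low_windows = clean_windows("active_sleep"))
  })
}

#' Design of a synthetic layered LFP recording
#'
#' Sharp-wave templates (Gaussian envelopes) are inserted with opposite
#' polarity in the strata oriens and radiatum and near-zero amplitude in
#' the stratum pyramidale, emulating the polarity reversal across the CA1
#' pyramidal layer; the contralateral hemisphere receives the same events
#' shifted by a configurable lag.
#'
#' @param duration_s record length (s).
#' @param fs sampling rate (Hz).
#' @param sw_rate_per_min ipsilateral sharp-wave rate (events/min).
#' @param lag_s contralateral lag (s).
#' @param amp template amplitude.
#' @param width_s Gaussian width of the template (s).
#' @param sp_frac residual amplitude at the pyramidale (fraction of
#'   \code{amp}).
#' @param noise_sd additive Gaussian noise SD.
#' @return an \code{lfp_design} list.
#' @export
lfp_design <- function(duration_s = 240, fs = 1000, sw_rate_per_min = 3,
                       lag_s = 0.08, amp = 1, width_s = 0.02,
                       sp_frac = 0.05, noise_sd = 0) {
  d <- as.list(environment())
  stopifnot(d$fs > 0, d$sw_rate_per_min >= 0, d$width_s > 0)
  structure(d, class = "lfp_design")
}

#' Generate synthetic layered LFP with ground truth
#'
#' @param design an [lfp_design()].
#' @param seed integer seed.
#' @param sw_times optional explicit ipsilateral event times (s); by
#'   default evenly spread with seeded jitter.
#' @return list with \code{ipsi} and \code{contra} (each a list of
#'   \code{so}, \code{sp}, \code{sr} traces), \code{fs}, and the
#'   ground-truth \code{sw_times} per hemisphere.
#' @export
generate_lfp <- function(design, seed = 1, sw_times = NULL) {
  stopifnot(inherits(design, "lfp_design"))
  d <- design
  n <- round(d$duration_s * d$fs)
  with_seed(seed, {
    if (is.null(sw_times)) {
      n_sw <- round(d$sw_rate_per_min * d$duration_s / 60)
      if (n_sw > 0) {
        grid <- seq(2, d$duration_s - 2, length.out = n_sw)
        spacing <- if (n_sw > 1) diff(grid[1:2]) else d$duration_s / 2
        jit <- stats::runif(n_sw, -0.3, 0.3) * spacing
        sw_times <- sort(pmin(d$duration_s - 2, pmax(2, grid + jit)))
      } else sw_times <- numeric(0)
    }
    half <- round(4 * d$width_s * d$fs)
    kernel <- exp(-((-half:half) / d$fs)^2 / (2 * d$width_s^2))
    insert <- function(times, scale) {
      x <- numeric(n)
      for (t0 in times) {
        i <- round(t0 * d$fs) + 1L
        lo <- max(1L, i - half); hi <- min(n, i + half)
        x[lo:hi] <- x[lo:hi] + scale * kernel[(lo - i + half + 1L):(hi - i + half + 1L)]
      }
      x
    }
    hemi <- function(times) {
      noise <- function() if (d$noise_sd > 0) stats::rnorm(n, 0, d$noise_sd)
                          else numeric(n)
      list(so = insert(times, -d$amp) + noise(),
           sp = insert(times, d$sp_frac * d$amp) + noise(),
           sr = insert(times, d$amp) + noise())
    }
    contra_times <- sw_times + d$lag_s
    contra_times <- contra_times[contra_times < d$duration_s - 1]
    list(ipsi = hemi(sw_times), contra = hemi(contra_times), fs = d$fs,
         sw_times = list(ipsi = sw_times, contra = contra_times))
  })
}
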