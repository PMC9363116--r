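#' Design of a synthetic imaging session
#'
#' Collects every parameter of the session generator. The generated sessions
#' emulate the statistical structure the analyses assume: a sparse baseline
#' of calcium transients, recurring synchronous calcium events (SCEs),
#' movement epochs with log-normal durations split into twitches and complex
#' movements, and a cell-type-specific coupling between movement onsets and
#' activation probability whose sign, for pyramidal cells, flips at a
#' configurable switch age.
#'
#' Coupling is a multiplicative hazard on transient onsets inside a 2-s
#' window after each movement onset. The default gains are chosen so that
#' pre-switch peri-movement peaks sit a few-fold above baseline (echoing
#' observed peak/baseline ratios of roughly 4x for both cell types) and
#' post-switch pyramidal activity is strongly suppressed while interneurons
#' remain activated.
#'
#' @param n_pyr,n_int numbers of pyramidal cells and interneurons.
#' @param duration_s session length in seconds.
#' @param frame_rate imaging rate, frames/s.
#' @param baseline_rate_pyr,baseline_rate_int baseline transient rates,
#'   transients/min per cell.
#' @param movement_rate movements per minute.
#' @param move_mu,move_sigma log-normal parameters (log seconds) of twitch
#'   durations.
#' @param twitch_fraction probability that a movement is drawn from the
#'   twitch duration component; the remainder are complex movements with
#'   durations of at least 2 s.
#' @param complex_mu,complex_sigma log-normal parameters of the complex
#'   movement duration component (resampled to be >= 2 s).
#' @param coupling named list with elements \code{pyramidal} and
#'   \code{interneuron}, each \code{c(pre = , post = )}: multiplicative
#'   onset-hazard gain in the 2 s after each movement onset, before
#'   (\code{pre}) and from (\code{post}) the switch age.
#' @param coupling_window_s length of the post-onset coupling window.
#' @param sce_rate SCE bursts per minute.
#' @param sce_participation fraction of cells recruited per SCE.
#' @param switch_age_days age (postnatal days) at which pyramidal coupling
#'   flips from \code{pre} to \code{post}; the generator's recoverable
#'   ground truth.
#' @param transient_mu,transient_sigma log-normal parameters (log seconds)
#'   of onset-to-peak transient durations.
#' @param dff_noise_sd Gaussian noise SD added to the synthetic DF/F traces.
#' @param gcamp_tau_s decay constant of the fluorescence kernel (s).
#' @return a \code{session_design} list.
#' @export
session_design <- function(n_pyr = 400, n_int = 25,
                           duration_s = 600, frame_rate = 10,
                           baseline_rate_pyr = 0.7,
                           baseline_rate_int = 2,
                           movement_rate = 6,
                           move_mu = log(0.4), move_sigma = 0.8,
                           twitch_fraction = 0.85,
                           complex_mu = log(3), complex_sigma = 0.4,
                           coupling = list(
                             pyramidal = c(pre = 4, post = 0.05),
                             interneuron = c(pre = 3.8, post = 2.5)),
                           coupling_window_s = 2,
                           sce_rate = 1, sce_participation = 0.15,
                           switch_age_days = 9,
                           transient_mu = log(0.4), transient_sigma = 0.3,
                           dff_noise_sd = 0.1, gcamp_tau_s = 2) {
  d <- as.list(environment())
  stopifnot(d$n_pyr >= 0, d$n_int >= 0, d$duration_s > 0, d$frame_rate > 0,
            d$baseline_rate_pyr >= 0, d$baseline_rate_int >= 0,
            d$movement_rate >= 0, d$sce_rate >= 0,
            d$twitch_fraction >= 0, d$twitch_fraction <= 1,
            d$sce_participation >= 0, d$sce_participation <= 1)
  structure(d, class = "session_design")
}

#' Generate movement epochs
#'
#' Movement onsets arrive at a Poisson rate; durations are drawn from a
#' log-normal mixture (a twitch component and a complex-movement component
#' resampled to last at least 2 s). Realised durations label the epochs:
#' under 1 s is a twitch, 2 s or more is complex, anything between is
#' unclassified. Overlaps are avoided by rejection sampling.
#'
#' @param design a [session_design()].
#' @param seed integer seed; identical seeds give identical epochs.
#' @return a [movement_epochs()] table.
#' @export
generate_movements <- function(design, seed = 1) {
  stopifnot(inherits(design, "session_design"))
  nf <- round(design$duration_s * design$frame_rate)
  with_seed(seed, {
    n_target <- stats::rpois(1, design$movement_rate * design$duration_s / 60)
    if (n_target == 0)
      return(movement_epochs(integer(), integer(), character(), n_frames = nf))
    durs <- vapply(seq_len(n_target), function(i) {
      if (stats::runif(1) < design$twitch_fraction) {
        stats::rlnorm(1, design$move_mu, design$move_sigma)
      } else {
        repeat {
          d <- stats::rlnorm(1, design$complex_mu, design$complex_sigma)
          if (d >= 2) return(d)
        }
      }
    }, numeric(1))
    mean_dur <- design$twitch_fraction *
      exp(design$move_mu + design$move_sigma^2 / 2) +
      (1 - design$twitch_fraction) *
      max(2, exp(design$complex_mu + design$complex_sigma^2 / 2))
    if (design$movement_rate / 60 * mean_dur > 0.8)
      stop("movement density infeasible: expected occupancy above 80%")
    dur_frames <- pmax(1L, round(durs * design$frame_rate))
    onsets <- integer(0); offsets <- integer(0)
    for (i in seq_len(n_target)) {
      if (dur_frames[i] >= nf) next
      for (try in seq_len(100)) {
        on <- sample.int(nf - dur_frames[i], 1)
        off <- on + dur_frames[i]
        if (!any(on <= offsets + 1L & off >= onsets - 1L)) {
          onsets <- c(onsets, on); offsets <- c(offsets, off)
          break
        }
      }
    }
    durs_s <- (offsets - onsets) / design$frame_rate
    category <- ifelse(durs_s < 1, "twitch",
                       ifelse(durs_s >= 2, "complex", "unclassified"))
    movement_epochs(onsets, offsets, category, n_frames = nf)
  })
}

#' Generate a full synthetic session
#'
#' Builds a session bundle at a given age: baseline Poisson-like transient
#' onsets per cell, SCE bursts that synchronise onsets in a random subset of
#' cells, movement coupling applied as a multiplicative hazard in the 2 s
#' after each movement onset (the pyramidal modulation blends from
#' activation to suppression across \code{switch_age_days} on a half-day
#' logistic scale, so the designed switch age is the midpoint of the
#' recoverable developmental transition), and DF/F traces
#' obtained by convolving the binary raster with an exponential kernel of
#' characteristic time \code{gcamp_tau_s} (unit peak) plus Gaussian noise.
#'
#' @param design a [session_design()].
#' @param age_days age of the simulated pup in postnatal days.
#' @param seed integer seed.
#' @param animal_id,session_id identifiers stored in the bundle metadata.
#' @param traces if \code{FALSE}, skip DF/F generation.
#' @return a [session_bundle()]; the design and the movement table are the
#'   recoverable ground truth.
#' @export
generate_session <- function(design, age_days, seed = 1,
                             animal_id = "synthetic", session_id = "s1",
                             traces = TRUE) {
  stopifnot(inherits(design, "session_design"))
  nf <- round(design$duration_s * design$frame_rate)
  movements <- generate_movements(design, seed = seed)
  with_seed(seed + 1L, {
    n_cells <- design$n_pyr + design$n_int
    cell_types <- c(rep("pyramidal", design$n_pyr),
                    rep("interneuron", design$n_int))
    # graded developmental switch: logistic blend between the pre- and
    # post-switch gains, centred on switch_age_days (0.5-day scale), so the
    # designed switch age is the midpoint of the recoverable transition
    w <- stats::plogis((age_days - design$switch_age_days) / 0.5)
    gain <- vapply(cell_types, function(ct) {
      g <- design$coupling[[ct]]
      exp((1 - w) * log(g[["pre"]]) + w * log(g[["post"]]))
    }, numeric(1))
    win <- round(design$coupling_window_s * design$frame_rate)
    in_window <- logical(nf)
    for (on in movements$onset)
      in_window[on:min(nf, on + win - 1L)] <- TRUE

    base_per_frame <- ifelse(cell_types == "pyramidal",
                             design$baseline_rate_pyr,
                             design$baseline_rate_int) /
      (60 * design$frame_rate)

    transients <- vector("list", n_cells)
    for (c in seq_len(n_cells)) {
      p <- rep(base_per_frame[c], nf)
      p[in_window] <- pmin(0.9, p[in_window] * gain[c])
      u <- stats::runif(nf)
      cand <- which(u < p)
      ons <- integer(0); pks <- integer(0)
      last_pk <- 0L
      for (f in cand) {
        if (f <= last_pk) next
        dur <- max(1L, round(stats::rlnorm(1, design$transient_mu,
                                           design$transient_sigma) *
                               design$frame_rate))
        pk <- min(nf, f + dur - 1L)
        ons <- c(ons, f); pks <- c(pks, pk)
        last_pk <- pk
      }
      transients[[c]] <- cbind(onset = ons, peak = pks)
    }

    n_sce <- stats::rpois(1, design$sce_rate * design$duration_s / 60)
    if (n_sce > 0 && design$sce_participation > 0) {
      sce_frames <- sort(sample.int(nf, n_sce))
      k <- max(1L, round(design$sce_participation * n_cells))
      for (s in sce_frames) {
        cells <- sample.int(n_cells, k)
        for (c in cells) {
          dur <- max(1L, round(stats::rlnorm(1, design$transient_mu,
                                             design$transient_sigma) *
                                 design$frame_rate))
          pk <- min(nf, s + dur - 1L)
          tr <- transients[[c]]
          if (nrow(tr) == 0L || !any(tr[, 1L] <= pk & tr[, 2L] >= s)) {
            transients[[c]] <- tr <- rbind(tr, c(s, pk))
          }
        }
      }
    }

    raster <- activity_raster(transients, n_frames = nf,
                              frame_rate = design$frame_rate,
                              cell_types = cell_types)
    dff <- NULL
    if (traces) {
      a <- exp(-1 / (design$gcamp_tau_s * design$frame_rate))
      dff <- t(apply(raster$activity, 1L, function(row)
        as.numeric(stats::filter(row, a, method = "recursive"))))
      dff <- dff + matrix(stats::rnorm(length(dff), 0, design$dff_noise_sd),
                          nrow(dff), ncol(dff))
    }
    session_bundle(raster, movements, dff,
                   meta = list(animal_id = animal_id, age_days = age_days,
                               session_id = session_id))
  })
}
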