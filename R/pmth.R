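#' Peri-movement time histogram (PMTH) for one session
#'
#' A 20-s window (10 s on each side) centred on each movement onset is
#' binned at frame resolution. For every usable movement (one whose whole
#' window fits inside the session; others are dropped) the number of active
#' cells — or the summed DF/F — is taken per bin; the 25th, median and 75th
#' percentiles across movements are divided by the number of cells (and
#' multiplied by 100 for the active-cell fraction). The chance band comes
#' from \code{n_surrogates} rasters in which each cell is circularly
#' shifted by a random integer: the median PMTH of every surrogate is kept
#' and the band is its per-bin 5th/50th/95th percentile. Bins where the
#' observed median lies above the 95th (below the 5th) surrogate percentile
#' are flagged as significant activation (suppression).
#'
#' @param bundle a [session_bundle()].
#' @param signal_kind \code{"active_fraction"} (binary raster) or
#'   \code{"dff"} (fluorescence traces; requires \code{bundle$traces}).
#' @param cell_types optional subset of cell types to include.
#' @param categories optional subset of movement categories (all pooled by
#'   default).
#' @param n_surrogates surrogate rasters for the chance band (default 500).
#' @param window_s half window length in seconds (default 10).
#' @param seed integer seed for the surrogate shifts.
#' @return object of class \code{pmth} with \code{bin_centers} (s),
#'   \code{q25}/\code{median}/\code{q75}, \code{surrogate_p5/p50/p95},
#'   \code{surrogate_medians} matrix, significance flags and
#'   \code{n_movements}.
#' @export
pmth_session <- function(bundle, signal_kind = c("active_fraction", "dff"),
                         cell_types = NULL, categories = NULL,
                         n_surrogates = 500, window_s = 10, seed = 1) {
  stopifnot(inherits(bundle, "session_bundle"))
  signal_kind <- match.arg(signal_kind)
  raster <- bundle$raster
  fr <- raster$frame_rate
  half <- round(window_s * fr)
  nf <- n_frames(raster)
  rows <- if (is.null(cell_types)) seq_len(n_cells(raster))
          else which(raster$cell_types %in% cell_types)
  if (length(rows) == 0L) stop("no cells of the requested type")
  mat <- if (signal_kind == "dff") {
    if (is.null(bundle$traces)) stop("bundle has no DF/F traces")
    bundle$traces[rows, , drop = FALSE]
  } else raster$activity[rows, , drop = FALSE]

  mv <- bundle$movements
  if (!is.null(categories)) mv <- mv[mv$category %in% categories, ]
  onsets <- mv$onset[mv$onset - half >= 1 & mv$onset + half <= nf]
  if (length(onsets) == 0L)
    stop("no movement with a full peri-movement window inside the session")
  scale <- if (signal_kind == "active_fraction") 100 / length(rows)
           else 1 / length(rows)

  windows <- function(popsig) {
    # bins x movements matrix of the population signal
    vapply(onsets, function(on) popsig[(on - half):(on + half)],
           numeric(2L * half + 1L))
  }
  obs <- apply(windows(colSums(mat)), 1L, stats::quantile,
               probs = c(0.25, 0.5, 0.75), names = FALSE) * scale

  binary <- signal_kind == "active_fraction"
  if (binary) {
    # sparse representation: one shifted tabulate per surrogate
    idx <- which(mat > 0, arr.ind = TRUE)
    cell_of <- idx[, 1L]
    frame_of <- idx[, 2L]
  }
  surr_med <- with_seed(seed, {
    out <- matrix(NA_real_, n_surrogates, 2L * half + 1L)
    for (s in seq_len(n_surrogates)) {
      shifts <- draw_shifts(nrow(mat), nf)
      popsig <- if (binary) {
        tabulate((frame_of - 1L + shifts[cell_of]) %% nf + 1L, nbins = nf)
      } else {
        acc <- numeric(nf)
        for (c in seq_len(nrow(mat)))
          acc <- acc + rotate_vector(mat[c, ], shifts[c])
        acc
      }
      out[s, ] <- apply(windows(popsig), 1L, stats::median) * scale
    }
    out
  })
  env <- apply(surr_med, 2L, stats::quantile, probs = c(0.05, 0.5, 0.95),
               names = FALSE)
  structure(list(
    bin_centers = seq(-half, half) / fr,
    q25 = obs[1L, ], median = obs[2L, ], q75 = obs[3L, ],
    surrogate_p5 = env[1L, ], surrogate_p50 = env[2L, ],
    surrogate_p95 = env[3L, ],
    surrogate_medians = surr_med,
    sig_up = obs[2L, ] > env[3L, ], sig_down = obs[2L, ] < env[1L, ],
    n_movements = length(onsets), n_cells = length(rows),
    signal_kind = signal_kind), class = "pmth")
}

#' Group-level PMTH
#'
#' Stacks the median PMTHs of several sessions and reports their per-bin
#' 25th/median/75th percentiles; the surrogate median curves of all
#' sessions are pooled the same way into a 5th/50th/95th chance band.
#'
#' @param session_pmths list of \code{pmth} objects with identical binning
#'   and signal kind.
#' @return a \code{pmth} object for the group.
#' @export
pmth_group <- function(session_pmths) {
  stopifnot(length(session_pmths) >= 1,
            all(vapply(session_pmths, inherits, logical(1), "pmth")))
  b0 <- session_pmths[[1L]]$bin_centers
  for (p in session_pmths) {
    if (length(p$bin_centers) != length(b0) ||
        any(abs(p$bin_centers - b0) > 1e-9) ||
        p$signal_kind != session_pmths[[1L]]$signal_kind)
      stop("sessions have mixed binning or signal kinds")
  }
  med <- do.call(rbind, lapply(session_pmths, `[[`, "median"))
  obs <- apply(med, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75),
               names = FALSE)
  surr <- do.call(rbind, lapply(session_pmths, `[[`, "surrogate_medians"))
  env <- apply(surr, 2L, stats::quantile, probs = c(0.05, 0.5, 0.95),
               names = FALSE)
  structure(list(
    bin_centers = b0,
    q25 = obs[1L, ], median = obs[2L, ], q75 = obs[3L, ],
    surrogate_p5 = env[1L, ], surrogate_p50 = env[2L, ],
    surrogate_p95 = env[3L, ],
    surrogate_medians = surr,
    sig_up = obs[2L, ] > env[3L, ], sig_down = obs[2L, ] < env[1L, ],
    n_movements = sum(vapply(session_pmths, `[[`, numeric(1), "n_movements")),
    n_cells = NA_integer_,
    signal_kind = session_pmths[[1L]]$signal_kind), class = "pmth")
}

#' Post-movement activity ratio of one movement
#'
#' In a 4-s window centred on the movement onset, the ratio of the number
#' of cells active in the 2 s from onset (the onset frame belongs to the
#' post window) to the number of cells active anywhere in the window. Each
#' cell is counted once. Returns \code{NA} when no cell is active in the
#' window (the ratio is undefined and the movement should be skipped).
#'
#' @param raster an [activity_raster()].
#' @param movement_onset onset frame.
#' @param window_half_s half window in seconds (default 2).
#' @return ratio in \code{[0, 1]}, or \code{NA}.
#' @export
post_movement_activity <- function(raster, movement_onset,
                                   window_half_s = 2) {
  stopifnot(inherits(raster, "activity_raster"))
  half <- round(window_half_s * raster$frame_rate)
  lo <- movement_onset - half
  hi <- movement_onset + half - 1L
  if (lo < 1 || hi > n_frames(raster))
    stop("4-s window around the movement onset exceeds the session")
  act <- raster$activity
  in_win <- rowSums(act[, lo:hi, drop = FALSE]) > 0
  if (!any(in_win)) return(NA_real_)
  in_post <- rowSums(act[, movement_onset:hi, drop = FALSE]) > 0
  sum(in_post) / sum(in_win)
}

#' Per-movement activity ratios of a session
#'
#' Applies [post_movement_activity()] to every movement whose 4-s window
#' fits in the session; movements with undefined ratios are \code{NA}.
#'
#' @param bundle a [session_bundle()].
#' @param window_half_s half window in seconds.
#' @return numeric vector, one entry per usable movement.
#' @export
movement_activity_ratios <- function(bundle, window_half_s = 2) {
  stopifnot(inherits(bundle, "session_bundle"))
  raster <- bundle$raster
  half <- round(window_half_s * raster$frame_rate)
  onsets <- bundle$movements$onset
  onsets <- onsets[onsets - half >= 1 & onsets + half - 1L <= n_frames(raster)]
  vapply(onsets, function(on)
    post_movement_activity(raster, on, window_half_s), numeric(1))
}

#' Proportion of inhibiting movements
#'
#' A movement is classified as inhibiting when strictly fewer than 40% of
#' the cells active in its 4-s window are active in the 2 s following
#' onset. Movements with undefined ratios are skipped; the proportion is
#' taken over the classified movements.
#'
#' @param bundle a [session_bundle()].
#' @param threshold classification threshold on the activity ratio
#'   (default 0.40, strict inequality).
#' @return proportion in \code{[0, 1]}.
#' @export
inhibiting_movement_proportion <- function(bundle, threshold = 0.40) {
  ratios <- movement_activity_ratios(bundle)
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0L)
    stop("no movement with a defined activity ratio")
  mean(ratios < threshold)
}

#' Movement- or immobility-associated cells
#'
#' For each cell, the number of transient onsets falling inside the epoch
#' frame set is compared with the same count after circularly shifting the
#' onsets \code{n_shifts} times; a cell is associated with the epochs when
#' its observed count is strictly above the chosen percentile of its own
#' shifted counts. Cells without transients are never flagged.
#'
#' @param raster an [activity_raster()].
#' @param epochs integer vector of epoch frames (e.g. from
#'   [movement_frames()] or [immobility_frames()]).
#' @param n_shifts circular shifts per cell (default 100).
#' @param percentile threshold percentile (default 99).
#' @param seed integer seed.
#' @return list with logical \code{flag} per cell and the flagged
#'   \code{fraction}.
#' @export
epoch_associated_cells <- function(raster, epochs, n_shifts = 100,
                                   percentile = 99, seed = 1) {
  stopifnot(inherits(raster, "activity_raster"), length(epochs) >= 1)
  nf <- n_frames(raster)
  in_epoch <- logical(nf)
  in_epoch[epochs] <- TRUE
  flag <- with_seed(seed, {
    vapply(raster$transients, function(tr) {
      if (nrow(tr) == 0L) return(FALSE)
      ons <- tr[, 1L]
      obs <- sum(in_epoch[ons])
      shifts <- sample.int(nf - 1L, n_shifts, replace = TRUE)
      shifted <- vapply(shifts, function(s)
        sum(in_epoch[(ons - 1L + s) %% nf + 1L]), numeric(1))
      obs > stats::quantile(shifted, percentile / 100)
    }, logical(1))
  })
  list(flag = flag, fraction = mean(flag))
}
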