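#' Circular-shift surrogate of an activity raster
#'
#' Each cell's row is rotated forward in time by an independent uniform
#' integer in \code{[1, n_frames - 1]}, destroying across-cell synchrony
#' while conserving every cell's total activity and its transient
#' durations. The zero shift is excluded so a surrogate row never equals
#' the original.
#'
#' @param raster an [activity_raster()] or a binary matrix.
#' @param seed integer seed.
#' @return a binary matrix of the same dimensions.
#' @export
circular_shift_surrogate <- function(raster, seed = 1) {
  mat <- if (inherits(raster, "activity_raster")) raster$activity else raster
  if (ncol(mat) < 2) stop("circular shifts need at least 2 frames")
  with_seed(seed, {
    shifts <- draw_shifts(nrow(mat), ncol(mat))
    out <- mat
    for (c in seq_len(nrow(mat))) out[c, ] <- rotate_vector(mat[c, ], shifts[c])
    out
  })
}

# pooled per-frame co-active counts over n_surrogates circular-shift
# surrogates, computed from per-cell active-frame index lists (fast path
# used by detect_sces)
surrogate_coactive_counts <- function(mat, n_surrogates) {
  nf <- ncol(mat)
  active_idx <- lapply(seq_len(nrow(mat)), function(c) which(mat[c, ] > 0))
  counts <- matrix(0L, nf, n_surrogates)
  for (s in seq_len(n_surrogates)) {
    shifts <- draw_shifts(nrow(mat), nf)
    shifted <- unlist(lapply(seq_len(nrow(mat)), function(c)
      (active_idx[[c]] - 1L + shifts[c]) %% nf + 1L))
    counts[, s] <- tabulate(shifted, nbins = nf)
  }
  counts
}

#' Detect synchronous calcium events (SCEs)
#'
#' SCEs are imaging frames where the number of co-active cells exceeds a
#' chance level estimated by a reshuffling method: an independent circular
#' shift is applied to each cell to obtain \code{n_surrogates} surrogate
#' rasters, and the given percentile of the pooled distribution of
#' per-frame co-active counts across all surrogates is used as the
#' threshold. Peaks of synchrony strictly above this threshold, separated
#' by at least \code{min_separation_frames} (500 ms at 10 Hz with the
#' default 5), are the SCE frames; closer peaks are merged keeping the
#' larger count (earlier frame on ties).
#'
#' @param raster an [activity_raster()].
#' @param n_surrogates number of surrogate rasters (default 300).
#' @param percentile surrogate percentile for the threshold (default 99).
#' @param min_separation_frames minimal gap between SCE frames.
#' @param seed integer seed for the surrogate shifts.
#' @return object of class \code{sce_result}: \code{threshold},
#'   \code{sce_frames}, \code{coactive} (per-frame observed counts) plus
#'   the detection parameters.
#' @export
detect_sces <- function(raster, n_surrogates = 300, percentile = 99,
                        min_separation_frames = 5, seed = 1) {
  stopifnot(inherits(raster, "activity_raster"), n_surrogates >= 1)
  mat <- raster$activity
  counts <- colSums(mat)
  if (all(counts == 0)) {
    return(structure(list(threshold = 0, sce_frames = integer(),
                          coactive = counts, n_surrogates = n_surrogates,
                          percentile = percentile,
                          min_separation_frames = min_separation_frames),
                     class = "sce_result"))
  }
  surr <- with_seed(seed, surrogate_coactive_counts(mat, n_surrogates))
  threshold <- as.numeric(stats::quantile(surr, percentile / 100))
  peaks <- local_maxima(counts)
  cand <- peaks[counts[peaks] > threshold]
  sce_frames <- merge_peaks(cand, counts, min_separation_frames)
  structure(list(threshold = threshold, sce_frames = sce_frames,
                 coactive = counts, n_surrogates = n_surrogates,
                 percentile = percentile,
                 min_separation_frames = min_separation_frames),
            class = "sce_result")
}

# strict local maxima; plateaus resolved to their first frame
local_maxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1L], -Inf)
  starts[r$values > left & r$values > right]
}

# greedy left-to-right merge: peaks closer than min_sep keep the larger
# count, earlier frame on ties
merge_peaks <- function(frames, counts, min_sep) {
  if (length(frames) <= 1L) return(frames)
  kept <- frames[1L]
  for (f in frames[-1L]) {
    last <- kept[length(kept)]
    if (f - last < min_sep) {
      if (counts[f] > counts[last]) kept[length(kept)] <- f
    } else kept <- c(kept, f)
  }
  kept
}

#' Fraction of each cell's transients that cross SCE frames
#'
#' For each cell with at least one transient, counts its calcium transients
#' (onset to peak) whose interval contains an SCE frame and divides by its
#' total number of transients. The per-animal value is the mean over cells
#' with transients.
#'
#' @param raster the [activity_raster()] the SCEs were detected on.
#' @param sce an \code{sce_result} from [detect_sces()].
#' @return list with \code{per_cell} (NA for transient-free cells) and
#'   \code{mean}.
#' @export
transients_in_sce_ratio <- function(raster, sce) {
  stopifnot(inherits(raster, "activity_raster"), inherits(sce, "sce_result"))
  sce_set <- logical(n_frames(raster))
  sce_set[sce$sce_frames] <- TRUE
  per_cell <- vapply(raster$transients, function(tr) {
    if (nrow(tr) == 0L) return(NA_real_)
    hits <- vapply(seq_len(nrow(tr)), function(i)
      any(sce_set[tr[i, 1L]:tr[i, 2L]]), logical(1))
    mean(hits)
  }, numeric(1))
  if (all(is.na(per_cell)))
    stop("no cell has any transient: ratio undefined")
  list(per_cell = per_cell, mean = mean(per_cell, na.rm = TRUE))
}

#' Calcium transient frequency
#'
#' Per-cell count of transient onsets divided by the recording duration,
#' in transients per minute; the per-animal value is the mean over cells.
#'
#' @param raster an [activity_raster()].
#' @return list with \code{per_cell} (1/min) and \code{mean}.
#' @export
transient_frequency <- function(raster) {
  stopifnot(inherits(raster, "activity_raster"))
  minutes <- n_frames(raster) / raster$frame_rate / 60
  if (minutes <= 0) stop("recording duration must be positive")
  per_cell <- vapply(raster$transients, nrow, integer(1)) / minutes
  list(per_cell = per_cell, mean = mean(per_cell))
}
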