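#' Build a binary activity matrix from calcium-transient intervals
#'
#' A neuron is considered active from the onset to the peak of each of its
#' calcium transients, so the raster entry for cell \code{c} at frame
#' \code{f} is 1 exactly when \code{f} lies inside the closed interval
#' \code{[onset, peak]} of some transient of that cell. Frames are 1-based.
#'
#' Overlapping or touching transients within a cell are merged into a single
#' interval, with a warning, since the binary raster cannot distinguish them.
#'
#' @param transients list with one element per cell; each element a
#'   two-column matrix (or data.frame) of \code{onset}, \code{peak} frame
#'   indices. An empty matrix (or \code{NULL}) means a silent cell.
#' @param n_frames total number of frames in the session.
#' @return integer matrix (cells x frames) of 0/1.
#' @export
raster_from_transients <- function(transients, n_frames) {
  stopifnot(is.list(transients), n_frames >= 1)
  n_cells <- length(transients)
  act <- matrix(0L, n_cells, n_frames)
  merged_any <- FALSE
  for (c in seq_len(n_cells)) {
    tr <- as_transient_matrix(transients[[c]])
    if (nrow(tr) == 0L) next
    if (any(tr < 1) || any(tr > n_frames))
      stop("transient frame indices out of [1, n_frames] for cell ", c)
    if (any(tr[, 2L] < tr[, 1L]))
      stop("transient peak before onset for cell ", c)
    tr <- tr[order(tr[, 1L]), , drop = FALSE]
    m <- merge_intervals(tr)
    if (nrow(m) < nrow(tr)) merged_any <- TRUE
    for (i in seq_len(nrow(m))) act[c, m[i, 1L]:m[i, 2L]] <- 1L
  }
  if (merged_any)
    warning("overlapping transients within a cell were merged")
  act
}

as_transient_matrix <- function(x) {
  if (is.null(x)) return(matrix(integer(), 0L, 2L))
  x <- as.matrix(x)
  if (length(x) == 0L) return(matrix(integer(), 0L, 2L))
  if (ncol(x) != 2L) stop("transients must have two columns (onset, peak)")
  storage.mode(x) <- "integer"
  x
}

# merge sorted closed intervals that overlap or touch
merge_intervals <- function(tr) {
  if (nrow(tr) <= 1L) return(tr)
  out <- tr[1L, , drop = FALSE]
  for (i in 2L:nrow(tr)) {
    j <- nrow(out)
    if (tr[i, 1L] <= out[j, 2L] + 0L) {
      out[j, 2L] <- max(out[j, 2L], tr[i, 2L])
    } else {
      out <- rbind(out, tr[i, , drop = FALSE])
    }
  }
  out
}

#' Recover transient intervals from a binary raster
#'
#' Extracts, per cell, the maximal runs of consecutive active frames. For a
#' raster built with [raster_from_transients()] this returns the merged
#' transient intervals exactly.
#'
#' @param activity binary cells x frames matrix.
#' @return list with one two-column (onset, peak) matrix per cell.
#' @export
transients_from_raster <- function(activity) {
  lapply(seq_len(nrow(activity)), function(c) {
    r <- rle(as.integer(activity[c, ]) > 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(onset = starts[keep], peak = ends[keep])
  })
}

#' Construct an activity raster object
#'
#' The central analysis substrate: a binary cells x frames matrix built from
#' per-cell transient (onset, peak) intervals, together with the imaging
#' frame rate and per-cell type labels. Cells labelled \code{"noise"} are
#' dropped at construction time and excluded from every analysis.
#'
#' @param transients per-cell list of (onset, peak) matrices.
#' @param n_frames number of imaging frames.
#' @param frame_rate imaging rate in frames per second (default 10).
#' @param cell_types character vector, one of \code{"pyramidal"},
#'   \code{"interneuron"}, \code{"noise"} per cell; defaults to all
#'   pyramidal.
#' @return an object of class \code{activity_raster} with elements
#'   \code{activity}, \code{frame_rate}, \code{cell_types},
#'   \code{transients}.
#' @export
activity_raster <- function(transients, n_frames, frame_rate = 10,
                            cell_types = NULL) {
  if (is.null(cell_types))
    cell_types <- rep("pyramidal", length(transients))
  stopifnot(length(cell_types) == length(transients),
            frame_rate > 0, n_frames >= 1)
  bad <- setdiff(unique(cell_types), c("pyramidal", "interneuron", "noise"))
  if (length(bad))
    stop("unknown cell type(s): ", paste(bad, collapse = ", "))
  keep <- cell_types != "noise"
  transients <- lapply(transients[keep], as_transient_matrix)
  cell_types <- cell_types[keep]
  act <- raster_from_transients(transients, n_frames)
  structure(
    list(activity = act, frame_rate = frame_rate,
         cell_types = cell_types,
         transients = lapply(transients, function(tr) {
           tr <- tr[order(tr[, 1L]), , drop = FALSE]
           colnames(tr) <- c("onset", "peak")
           tr
         })),
    class = "activity_raster")
}

#' @export
print.activity_raster <- function(x, ...) {
  cat("<activity_raster> ", nrow(x$activity), " cells x ",
      ncol(x$activity), " frames @ ", x$frame_rate, " Hz (",
      sum(x$cell_types == "pyramidal"), " pyr, ",
      sum(x$cell_types == "interneuron"), " int)\n", sep = "")
  invisible(x)
}

n_frames <- function(raster) ncol(raster$activity)
n_cells <- function(raster) nrow(raster$activity)

#' Construct a movement-epoch table
#'
#' @param onset,offset frame indices (1-based, closed intervals); vectors of
#'   equal length.
#' @param category per-epoch label in \code{"twitch"}, \code{"complex"},
#'   \code{"unclassified"}.
#' @param n_frames total session frames.
#' @return object of class \code{movement_epochs}: a data.frame with
#'   columns onset, offset, category and attribute \code{n_frames}.
#' @export
movement_epochs <- function(onset, offset, category = NULL, n_frames) {
  onset <- as.integer(onset); offset <- as.integer(offset)
  if (is.null(category)) category <- rep("unclassified", length(onset))
  stopifnot(length(onset) == length(offset),
            length(onset) == length(category))
  bad <- setdiff(unique(category), c("twitch", "complex", "unclassified"))
  if (length(bad) && length(onset))
    stop("unknown movement category: ", paste(bad, collapse = ", "))
  if (length(onset)) {
    if (any(onset >= offset)) stop("movement onset must precede offset")
    if (any(onset < 1) || any(offset > n_frames))
      stop("movement epochs outside [1, n_frames]")
    o <- order(onset)
    onset <- onset[o]; offset <- offset[o]; category <- category[o]
    if (any(onset[-1L] <= offset[-length(offset)]))
      stop("movement epochs overlap")
  }
  structure(
    data.frame(onset = onset, offset = offset, category = category,
               stringsAsFactors = FALSE),
    n_frames = as.integer(n_frames), class = c("movement_epochs", "data.frame"))
}

#' Frames covered by movement epochs
#'
#' @param movements a [movement_epochs()] table.
#' @param buffer_frames dilation applied to each epoch on both sides.
#' @return sorted integer vector of frame indices.
#' @export
movement_frames <- function(movements, buffer_frames = 0L) {
  nf <- attr(movements, "n_frames")
  if (nrow(movements) == 0L) return(integer())
  idx <- unlist(lapply(seq_len(nrow(movements)), function(i) {
    seq(max(1L, movements$onset[i] - buffer_frames),
        min(nf, movements$offset[i] + buffer_frames))
  }))
  sort(unique(idx))
}

#' Immobility frames
#'
#' The complement of the union of movement epochs, each dilated by
#' \code{buffer_frames} on both sides; used to restrict correlogram and
#' epoch-association analyses to rest.
#'
#' @inheritParams movement_frames
#' @return sorted integer vector of immobile frame indices.
#' @export
immobility_frames <- function(movements, buffer_frames = 0L) {
  stopifnot(buffer_frames >= 0)
  nf <- attr(movements, "n_frames")
  setdiff(seq_len(nf), movement_frames(movements, buffer_frames))
}
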