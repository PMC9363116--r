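#' Population activity signal of one cell type
#'
#' Per-frame fraction of active cells of the requested type; frames outside
#' the restriction set (e.g. movement frames when analysing immobility) are
#' masked to \code{NA} so that downstream correlograms only use valid
#' frames.
#'
#' @param raster an [activity_raster()].
#' @param cell_type \code{"pyramidal"}, \code{"interneuron"} or
#'   \code{"all"}.
#' @param frames optional integer vector of frames to keep (others masked).
#' @return numeric vector of length \code{n_frames} with attribute
#'   \code{frame_rate}.
#' @export
population_signal <- function(raster, cell_type = "all", frames = NULL) {
  stopifnot(inherits(raster, "activity_raster"))
  rows <- if (cell_type == "all") seq_len(n_cells(raster))
          else which(raster$cell_types == cell_type)
  if (length(rows) == 0L) stop("no cells of type ", cell_type)
  sig <- colMeans(raster$activity[rows, , drop = FALSE])
  if (!is.null(frames)) {
    mask <- rep(NA_real_, length(sig))
    mask[frames] <- sig[frames]
    sig <- mask
  }
  attr(sig, "frame_rate") <- raster$frame_rate
  sig
}

#' Cross-correlogram of two (possibly masked) time series
#'
#' Pearson correlation of the two mean-removed series at every integer-bin
#' lag up to \code{max_lag_s}. A positive lag means \code{b} follows
#' \code{a}. Masked (\code{NA}) samples split the series into contiguous
#' segments and only lag pairs lying inside the same segment are used, so
#' no pair straddles an excluded stretch. Lags with fewer than
#' \code{min_pairs} valid pairs are reported as \code{NA}.
#'
#' @param a,b numeric vectors on the same frame grid (NAs mark excluded
#'   frames; the two masks must agree).
#' @param bin_s bin width in seconds (one frame for imaging signals).
#' @param max_lag_s maximal lag in seconds (default 10).
#' @param min_pairs minimal number of pairs per lag (default 10).
#' @return object of class \code{correlogram}: \code{lags} (s),
#'   \code{values}, \code{bin_s}, \code{max_lag_s}, \code{n_pairs}.
#' @export
crosscorrelogram <- function(a, b, bin_s, max_lag_s = 10, min_pairs = 10) {
  stopifnot(length(a) == length(b), bin_s > 0)
  if (any(is.na(a) != is.na(b)))
    stop("the two series must share the same restriction mask")
  n <- length(a)
  valid <- !is.na(a)
  # contiguous-segment labels of the valid frames
  seg <- cumsum(c(TRUE, diff(valid) != 0))
  seg[!valid] <- NA_integer_
  max_k <- round(max_lag_s / bin_s)
  lags <- seq(-max_k, max_k)
  values <- rep(NA_real_, length(lags))
  n_pairs <- integer(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    t0 <- max(1L, 1L - k):min(n, n - k)
    t1 <- t0 + k
    use <- valid[t0] & valid[t1] & seg[t0] == seg[t1]
    use[is.na(use)] <- FALSE
    x <- a[t0[use]]; y <- b[t1[use]]
    n_pairs[i] <- length(x)
    if (length(x) >= min_pairs && stats::sd(x) > 0 && stats::sd(y) > 0)
      values[i] <- stats::cor(x, y)
  }
  structure(list(lags = lags * bin_s, values = values, bin_s = bin_s,
                 max_lag_s = max_lag_s, n_pairs = n_pairs),
            class = "correlogram")
}

#' Immobility-restricted population cross-correlogram of a session
#'
#' Convenience wrapper: builds the population signals of two cell types,
#' restricts them to immobility frames and calls [crosscorrelogram()].
#' A positive lag means the second population follows the first.
#'
#' @param bundle a [session_bundle()].
#' @param a,b cell types of the leading and following population.
#' @param buffer_frames dilation of movement epochs before exclusion.
#' @param max_lag_s maximal lag in seconds.
#' @return a \code{correlogram}.
#' @export
session_crosscorrelogram <- function(bundle, a = "interneuron",
                                     b = "pyramidal", buffer_frames = 0L,
                                     max_lag_s = 10) {
  stopifnot(inherits(bundle, "session_bundle"))
  frames <- immobility_frames(bundle$movements, buffer_frames)
  sa <- population_signal(bundle$raster, a, frames)
  sb <- population_signal(bundle$raster, b, frames)
  crosscorrelogram(as.numeric(sa), as.numeric(sb),
                   bin_s = 1 / bundle$raster$frame_rate,
                   max_lag_s = max_lag_s)
}

#' Average a series over non-overlapping blocks
#'
#' Brings finely sampled model output onto a coarser bin grid (e.g.
#' integration steps onto 100-ms bins) before correlating it with the same
#' estimator as the imaging data.
#'
#' @param x numeric series.
#' @param factor samples per block.
#' @return numeric vector of block means.
#' @export
rebin_series <- function(x, factor) {
  n <- floor(length(x) / factor)
  colMeans(matrix(x[seq_len(n * factor)], nrow = factor))
}
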