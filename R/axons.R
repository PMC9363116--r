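# Zhang-Suen binary thinning; returns a 1-px-wide skeleton. Written here
# because no installed package provides morphological thinning.
thin_skeleton <- function(binary) {
  img <- matrix(as.integer(binary), nrow(binary), ncol(binary))
  pad <- matrix(0L, nrow(img) + 2L, ncol(img) + 2L)
  pad[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)] <- img
  nr <- nrow(pad); nc <- ncol(pad)
  shift <- function(m, dy, dx)
    m[(2:(nr - 1L)) + dy, (2:(nc - 1L)) + dx, drop = FALSE]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift(pad, -1L, 0L); p3 <- shift(pad, -1L, 1L)
      p4 <- shift(pad, 0L, 1L);  p5 <- shift(pad, 1L, 1L)
      p6 <- shift(pad, 1L, 0L);  p7 <- shift(pad, 1L, -1L)
      p8 <- shift(pad, 0L, -1L); p9 <- shift(pad, -1L, -1L)
      ctr <- shift(pad, 0L, 0L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- Reduce(`+`, lapply(1:8, function(k)
        (seqs[[k]] == 0L) * (seqs[[k + 1L]] == 1L)))
      if (pass == 1L) {
        cond <- ctr == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- ctr == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        changed <- TRUE
        inner <- pad[2:(nr - 1L), 2:(nc - 1L)]
        inner[cond] <- 0L
        pad[2:(nr - 1L), 2:(nc - 1L)] <- inner
      }
    }
    if (!changed) break
  }
  pad[2:(nr - 1L), 2:(nc - 1L)] > 0L
}

count_neighbors <- function(skel) {
  s <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  pad <- matrix(0L, nrow(s) + 2L, ncol(s) + 2L)
  pad[2:(nrow(s) + 1L), 2:(ncol(s) + 1L)] <- s
  nb <- matrix(0L, nrow(s), ncol(s))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- nb + pad[(2:(nrow(s) + 1L)) + dy, (2:(ncol(s) + 1L)) + dx]
  }
  nb
}

# iteratively strip endpoint pixels to remove short spur twigs, which
# would otherwise create spurious junctions along an axon backbone
prune_spurs <- function(skel, n = 4L) {
  for (i in seq_len(n)) {
    endpoints <- skel & count_neighbors(skel) == 1L
    if (!any(endpoints)) break
    skel <- skel & !endpoints
  }
  skel
}

# crossing number: 0->1 transitions around the 8-neighbourhood circle;
# >= 3 marks a true junction (robust to staircase pixels of thinned
# diagonals, which have contiguous neighbourhoods)
count_transitions <- function(skel) {
  s <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  pad <- matrix(0L, nrow(s) + 2L, ncol(s) + 2L)
  pad[2:(nrow(s) + 1L), 2:(ncol(s) + 1L)] <- s
  ring <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nbs <- lapply(ring, function(d)
    pad[(2:(nrow(s) + 1L)) + d[1L], (2:(ncol(s) + 1L)) + d[2L]])
  tr <- matrix(0L, nrow(s), ncol(s))
  for (k in 1:8) {
    nxt <- if (k == 8) 1L else k + 1L
    tr <- tr + (nbs[[k]] == 0L) * (nbs[[nxt]] == 1L)
  }
  tr
}

#' Skeleton-based axon segmentation of a calcium-imaging movie
#'
#' Summarises the movie (Gaussian spatial smoothing of every frame, then a
#' temporal average), applies histogram equalisation, another Gaussian
#' smoothing, an adaptive (local-mean) threshold, and morphological
#' thinning to obtain a 1-px skeleton. Branches are the connected skeleton
#' segments after removing junction pixels (pixels with more than two
#' skeleton neighbours); segments shorter than \code{min_branch_px} are
#' discarded.
#'
#' @param movie numeric array t x y x x with at least 10 frames.
#' @param gauss_sigma Gaussian smoothing sigma (px).
#' @param adaptive_w half-width of the adaptive-threshold window (px).
#' @param adaptive_offset threshold offset above the local window mean
#'   (equalised-intensity units).
#' @param min_branch_px minimal branch length (pixels).
#' @param prune_px spur twigs up to this length are pruned off the
#'   skeleton before branch decomposition.
#' @param min_contrast foreground gate: the summary image must contain
#'   pixels at least this many robust SDs (MAD) above its median,
#'   otherwise the movie is treated as structure-free and an empty branch
#'   set is returned. Histogram equalisation is rank-based, so without
#'   this gate a signal-free movie would be stretched into spurious
#'   texture.
#' @return object of class \code{branch_set}: \code{skeleton} (logical
#'   matrix), \code{branches} (list of two-column pixel coordinate
#'   matrices, rows = (y, x)), \code{summary_image}.
#' @export
skeletonize_axons <- function(movie, gauss_sigma = 1, adaptive_w = 12,
                              adaptive_offset = 0.2, min_branch_px = 10,
                              prune_px = 4, min_contrast = 10) {
  stopifnot(length(dim(movie)) == 3L)
  if (dim(movie)[1L] < 10L) stop("movie needs at least 10 frames")
  sm <- apply(movie, 1L, function(fr)
    EBImage::gblur(matrix(fr, dim(movie)[2L], dim(movie)[3L]),
                   sigma = gauss_sigma))
  summary_img <- matrix(rowMeans(sm), dim(movie)[2L], dim(movie)[3L])
  rng <- range(summary_img)
  empty <- structure(list(skeleton = summary_img > Inf, branches = list(),
                          summary_image = summary_img),
                     class = "branch_set")
  if (diff(rng) == 0) return(empty)
  scale <- stats::mad(summary_img)
  if (scale == 0 ||
      (max(summary_img) - stats::median(summary_img)) / scale < min_contrast)
    return(empty)
  norm <- (summary_img - rng[1L]) / diff(rng)
  eq <- EBImage::equalize(EBImage::Image(norm), levels = 256)
  eq <- EBImage::gblur(eq, sigma = gauss_sigma)
  w <- min(adaptive_w, floor((min(dim(norm)) - 1) / 2))
  binary <- EBImage::thresh(eq, w = w, h = w, offset = adaptive_offset)
  binary <- matrix(as.logical(binary > 0), nrow(norm), ncol(norm))
  if (!any(binary)) return(empty)
  skel <- prune_spurs(thin_skeleton(binary), prune_px)
  if (!any(skel)) return(empty)
  seg_mask <- skel & count_transitions(skel) <= 2L
  labels <- EBImage::bwlabel(seg_mask)
  n_obj <- max(labels)
  branches <- list()
  for (k in seq_len(n_obj)) {
    px <- which(labels == k, arr.ind = TRUE)
    if (nrow(px) >= min_branch_px)
      branches[[length(branches) + 1L]] <-
        cbind(y = px[, 1L], x = px[, 2L])
  }
  structure(list(skeleton = skel, branches = branches,
                 summary_image = summary_img),
            class = "branch_set")
}

#' Average intensity trace of each branch
#'
#' @param movie numeric array t x y x x.
#' @param branches list of pixel coordinate matrices (from
#'   [skeletonize_axons()]).
#' @return matrix branches x frames.
#' @export
branch_traces <- function(movie, branches) {
  stopifnot(length(dim(movie)) == 3L)
  t(vapply(branches, function(px) {
    idx <- (px[, 2L] - 1L) * dim(movie)[2L] + px[, 1L]
    vapply(seq_len(dim(movie)[1L]), function(f) {
      fr <- matrix(movie[f, , ], dim(movie)[2L], dim(movie)[3L])
      mean(fr[idx])
    }, numeric(1))
  }, numeric(dim(movie)[1L])))
}

#' Validate branches by illumination uniformity
#'
#' A functional axonal branch lights up uniformly along its length during
#' a calcium transient. For each branch, the frame of its largest
#' (smoothed) trace excursion is found and the sample skewness of the
#' pixel intensities along the branch at that frame is computed; branches
#' with \code{|skewness| <= skew_max} are kept. Zero-variance pixel
#' distributions have skewness 0 by convention. Branches shorter than
#' 5 px are rejected outright.
#'
#' @param movie numeric array t x y x x.
#' @param branches list of pixel coordinate matrices.
#' @param skew_max skewness cutoff (default 1).
#' @param smooth_w running-mean window for the trace (frames).
#' @return logical vector, one flag per branch.
#' @export
validate_branches <- function(movie, branches, skew_max = 1, smooth_w = 5) {
  stopifnot(length(branches) >= 1)
  traces <- branch_traces(movie, branches)
  vapply(seq_along(branches), function(b) {
    px <- branches[[b]]
    if (nrow(px) < 5L) return(FALSE)
    tr <- stats::filter(traces[b, ], rep(1 / smooth_w, smooth_w))
    peak <- which.max(ifelse(is.na(tr), -Inf, tr))
    fr <- matrix(movie[peak, , ], dim(movie)[2L], dim(movie)[3L])
    vals <- fr[(px[, 2L] - 1L) * nrow(fr) + px[, 1L]]
    abs(sample_skewness(vals)) <= skew_max
  }, logical(1))
}

# minimal DBSCAN on a point matrix (euclidean); labels 0 = unassigned
dbscan_points <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- which(D[i, ] <= eps)
    if (length(nb) < min_pts) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (!visited[j]) {
        visited[j] <- TRUE
        nb2 <- which(D[j, ] <= eps)
        if (length(nb2) >= min_pts) queue <- c(queue, setdiff(nb2, j))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

#' Cluster branches by the similarity of their activity traces
#'
#' Branch pairwise distance is one minus the Spearman correlation of their
#' traces (constant traces correlate with nothing: distance 1). The
#' distances are embedded in two dimensions by classical multidimensional
#' scaling and clustered by density (DBSCAN with a data-driven radius);
#' branches in groups smaller than \code{min_cluster_size} are labelled 0
#' (singletons).
#'
#' @param traces matrix branches x frames.
#' @param min_cluster_size minimal cluster size (default 2).
#' @param eps optional DBSCAN radius; by default a quarter of the median
#'   non-zero pairwise embedded distance.
#' @param seed unused for the deterministic MDS embedding; kept so callers
#'   can pin a seed uniformly.
#' @return integer cluster labels (0 = singleton), one per branch.
#' @export
cluster_branches <- function(traces, min_cluster_size = 2, eps = NULL,
                             seed = 1) {
  traces <- as.matrix(traces)
  n <- nrow(traces)
  if (n < 2L) stop("need at least 2 branches to cluster")
  labels <- rep(0L, n)
  # constant traces correlate with nothing: permanent singletons
  ok <- apply(traces, 1L, stats::sd) > 0
  if (sum(ok) < 2L) return(labels)
  rho <- suppressWarnings(stats::cor(t(traces[ok, , drop = FALSE]),
                                     method = "spearman"))
  rho[!is.finite(rho)] <- 0
  D <- pmax(1 - rho, 0)
  diag(D) <- 0
  emb <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = min(2L, sum(ok) - 1L)))
  if (is.null(dim(emb)) || ncol(emb) == 0L)
    emb <- matrix(0, sum(ok), 1L)
  pd <- stats::dist(emb)
  pos <- pd[pd > 1e-8]
  if (is.null(eps))
    eps <- if (length(pos)) 0.25 * stats::median(pos) else 1e-8
  sub <- dbscan_points(emb, eps, min_pts = min_cluster_size)
  sizes <- table(sub[sub > 0])
  small <- as.integer(names(sizes)[sizes < min_cluster_size])
  sub[sub %in% small] <- 0L
  labels[ok] <- sub
  labels
}
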