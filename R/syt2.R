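#' Kapur maximum-entropy threshold
#'
#' Classical max-entropy thresholding: choose the grey level that
#' maximises the sum of the Shannon entropies of the background and
#' foreground histogram partitions.
#'
#' @param img numeric matrix with values in \code{[0, 1]}.
#' @param n_bins histogram resolution (default 256).
#' @return threshold in \code{[0, 1]}; pixels strictly above are
#'   foreground.
#' @export
kapur_threshold <- function(img, n_bins = 256) {
  v <- as.vector(img)
  stopifnot(all(v >= 0), all(v <= 1))
  h <- tabulate(pmin(n_bins, floor(v * n_bins) + 1L), nbins = n_bins)
  p <- h / sum(h)
  P <- cumsum(p)
  ent <- function(q) ifelse(q > 0, -q * log(q), 0)
  Hc <- cumsum(ent(p))
  Htot <- Hc[n_bins]
  best <- -Inf; best_t <- 1L
  for (t in seq_len(n_bins - 1L)) {
    if (P[t] <= 0 || P[t] >= 1) next
    hb <- Hc[t] / P[t] + log(P[t])
    hf <- (Htot - Hc[t]) / (1 - P[t]) + log(1 - P[t])
    if (hb + hf > best) { best <- hb + hf; best_t <- t }
  }
  best_t / n_bins
}

#' Synaptotagmin-2 bouton coverage of the pyramidal layer
#'
#' Quantifies the fraction of the analysed area covered by
#' synaptotagmin-2-positive puncta, a proxy for parvalbumin basket-cell
#' bouton density: max-intensity projection of the top 6 um of the z-stack,
#' morphological (top-hat) background removal, subtraction of the mean
#' intensity of a background ROI (clipped at zero), Kapur max-entropy
#' binarisation, connected-component particle analysis, and retention of
#' particles with area between 0.4 and 4 um^2. Coverage is the retained
#' particle area divided by the image area, in percent. Every step is
#' histogram- or morphology-based, so the result is invariant to global
#' intensity scaling.
#'
#' @param stack numeric array: either y x x (single plane) or z x y x x.
#' @param pixel_size_um pixel size (um/px).
#' @param background_roi logical matrix (y x x) marking the background
#'   region whose mean is subtracted.
#' @param z_step_um spacing between z slices (um); used to select the top
#'   \code{z_top_um}.
#' @param z_top_um depth of the projected sub-stack (default 6 um).
#' @param size_range_um2 retained particle area range (default 0.4-4).
#' @param tophat_radius_px radius of the background-removal structuring
#'   element (px).
#' @return object of class \code{coverage_result}: \code{coverage_percent},
#'   \code{n_particles}, \code{particle_areas_um2}, \code{mask},
#'   \code{threshold}.
#' @export
syt2_coverage <- function(stack, pixel_size_um, background_roi,
                          z_step_um = 1, z_top_um = 6,
                          size_range_um2 = c(0.4, 4),
                          tophat_radius_px = 15) {
  if (length(dim(stack)) == 3L) {
    n_top <- max(1L, min(dim(stack)[1L], ceiling(z_top_um / z_step_um)))
    img <- apply(stack[seq_len(n_top), , , drop = FALSE], c(2L, 3L), max)
  } else img <- as.matrix(stack)
  stopifnot(is.logical(background_roi),
            all(dim(background_roi) == dim(img)))
  if (!any(background_roi)) stop("background ROI is empty")

  empty <- function(thr) structure(
    list(coverage_percent = 0, n_particles = 0L,
         particle_areas_um2 = numeric(), mask = img * 0 > 1,
         threshold = thr), class = "coverage_result")
  if (max(img) <= 0) return(empty(0))
  img <- img / max(img)

  brush <- EBImage::makeBrush(2L * tophat_radius_px + 1L, shape = "disc")
  bg <- EBImage::opening(img, brush)
  img <- pmax(img - bg, 0)
  img <- pmax(img - mean(img[background_roi]), 0)
  if (max(img) <= 0) return(empty(0))
  img <- img / max(img)

  thr <- kapur_threshold(img)
  binary <- img > thr
  labels <- EBImage::bwlabel(binary)
  n_obj <- max(labels)
  if (n_obj == 0) return(empty(thr))
  areas_px <- tabulate(labels[labels > 0], nbins = n_obj)
  areas_um2 <- areas_px * pixel_size_um^2
  keep <- areas_um2 >= size_range_um2[1L] & areas_um2 <= size_range_um2[2L]
  mask <- matrix(labels %in% which(keep), nrow(img), ncol(img))
  structure(list(
    coverage_percent = 100 * sum(areas_px[keep]) / length(img),
    n_particles = sum(keep),
    particle_areas_um2 = areas_um2[keep],
    mask = mask, threshold = thr), class = "coverage_result")
}
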