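#' Design of a synthetic axon-imaging movie
#'
#' Branches are polylines rasterised at 1-2 px width, blurred by a
#' Gaussian point-spread function; each branch's intensity follows its
#' assigned time course (calcium-transient-like events on a baseline) and
#' Gaussian noise is added per pixel and frame.
#'
#' @param height,width image size (px).
#' @param n_frames movie length (frames).
#' @param branches list of polylines, each a two-column (y, x) matrix of
#'   vertices.
#' @param psf_sigma PSF sigma (px).
#' @param noise_sd per-pixel Gaussian noise SD.
#' @param amplitude peak branch intensity.
#' @param event_rate transient events per 100 frames per branch.
#' @param event_tau_frames exponential decay of the events (frames).
#' @return an \code{axon_movie_design} list.
#' @export
axon_movie_design <- function(height = 48, width = 48, n_frames = 120,
                              branches = list(), psf_sigma = 1,
                              noise_sd = 0.01, amplitude = 1,
                              event_rate = 3, event_tau_frames = 8) {
  d <- as.list(environment())
  stopifnot(d$height > 4, d$width > 4, d$n_frames >= 10)
  structure(d, class = "axon_movie_design")
}

rasterize_polyline <- function(poly, height, width, thick = 1L) {
  mask <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(poly) - 1L)) {
    p0 <- poly[i, ]; p1 <- poly[i + 1L, ]
    n <- max(2L, ceiling(2 * max(abs(p1 - p0))))
    ys <- round(seq(p0[1L], p1[1L], length.out = n))
    xs <- round(seq(p0[2L], p1[2L], length.out = n))
    for (dy in 0:(thick - 1L)) {
      yy <- pmin(height, pmax(1L, ys + dy))
      xx <- pmin(width, pmax(1L, xs))
      mask[cbind(yy, xx)] <- TRUE
    }
  }
  mask
}

#' Generate a synthetic axon movie with ground truth
#'
#' @param design an [axon_movie_design()].
#' @param seed integer seed.
#' @param traces optional matrix branches x frames of intensity time
#'   courses; drawn as random transient trains by default.
#' @return list with \code{movie} (t x y x x), ground-truth \code{masks}
#'   (one logical matrix per branch) and \code{traces}.
#' @export
generate_axon_movie <- function(design, seed = 1, traces = NULL) {
  stopifnot(inherits(design, "axon_movie_design"))
  d <- design
  nb <- length(d$branches)
  with_seed(seed, {
    masks <- lapply(d$branches, rasterize_polyline,
                    height = d$height, width = d$width)
    if (is.null(traces)) {
      traces <- matrix(0.05, max(1L, nb), d$n_frames)
      for (b in seq_len(nb)) {
        n_ev <- stats::rpois(1, d$event_rate * d$n_frames / 100)
        onsets <- sort(sample.int(d$n_frames, min(n_ev, d$n_frames)))
        for (on in onsets) {
          decay <- exp(-(seq(on, d$n_frames) - on) / d$event_tau_frames)
          traces[b, on:d$n_frames] <- pmax(traces[b, on:d$n_frames], decay)
        }
      }
    }
    blurred <- lapply(masks, function(m)
      as.matrix(EBImage::gblur(matrix(as.numeric(m), d$height, d$width),
                               sigma = d$psf_sigma)))
    movie <- array(stats::rnorm(d$n_frames * d$height * d$width,
                                0, d$noise_sd),
                   dim = c(d$n_frames, d$height, d$width))
    for (b in seq_len(nb)) {
      for (f in seq_len(d$n_frames)) {
        movie[f, , ] <- movie[f, , ] +
          d$amplitude * traces[b, f] * blurred[[b]]
      }
    }
    list(movie = movie, masks = masks,
         traces = if (nb) traces[seq_len(nb), , drop = FALSE]
                  else traces[0, , drop = FALSE])
  })
}

#' Generate a synthetic synaptotagmin-2 stack with ground truth
#'
#' Bright square particles of specified areas are placed on a noisy
#' background in the top slices of a small z-stack. Ground-truth coverage
#' is the drawn area of particles within the retained size range divided
#' by the image area.
#'
#' @param height,width image size (px).
#' @param pixel_size_um pixel size (um/px).
#' @param particle_areas_um2 areas of the particles to draw (um^2).
#' @param n_z,z_step_um stack geometry; particles live in the top slices.
#' @param intensity particle intensity (background is 0 plus noise).
#' @param noise_sd background Gaussian noise SD.
#' @param size_range_um2 range used for the ground-truth coverage.
#' @param seed integer seed (particle placement).
#' @return list with \code{stack} (z x y x x), \code{truth_coverage_percent},
#'   \code{background_roi} (logical, a clean corner region),
#'   \code{drawn_areas_um2} (realised, discretised areas).
#' @export
generate_syt2_image <- function(height = 100, width = 100,
                                pixel_size_um = 0.2,
                                particle_areas_um2 = c(1, 1, 2),
                                n_z = 8, z_step_um = 1,
                                intensity = 1, noise_sd = 0.02,
                                size_range_um2 = c(0.4, 4), seed = 1) {
  with_seed(seed, {
    img <- matrix(0, height, width)
    drawn <- numeric(0)
    margin <- 6L
    occupied <- matrix(FALSE, height, width)
    for (a in particle_areas_um2) {
      side <- max(1L, round(sqrt(a) / pixel_size_um))
      for (try in seq_len(200)) {
        y0 <- sample.int(height - side - 2L * margin, 1L) + margin
        x0 <- sample.int(width - side - 2L * margin, 1L) + margin
        ys <- y0:(y0 + side - 1L); xs <- x0:(x0 + side - 1L)
        pad_y <- max(1L, y0 - 3L):min(height, y0 + side + 2L)
        pad_x <- max(1L, x0 - 3L):min(width, x0 + side + 2L)
        if (!any(occupied[pad_y, pad_x])) {
          img[ys, xs] <- intensity
          occupied[pad_y, pad_x] <- TRUE
          drawn <- c(drawn, side^2 * pixel_size_um^2)
          break
        }
      }
    }
    in_range <- drawn >= size_range_um2[1L] & drawn <= size_range_um2[2L]
    truth <- 100 * sum(drawn[in_range] / pixel_size_um^2) / (height * width)
    stack <- array(stats::rnorm(n_z * height * width, 0, noise_sd),
                   dim = c(n_z, height, width))
    top <- seq_len(max(1L, min(n_z, floor(6 / z_step_um))))
    for (z in top) stack[z, , ] <- stack[z, , ] + img
    stack <- pmin(pmax(stack, 0), 1)
    roi <- matrix(FALSE, height, width)
    roi[1:4, 1:4] <- TRUE
    list(stack = stack, truth_coverage_percent = truth,
         background_roi = roi, drawn_areas_um2 = drawn)
  })
}
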