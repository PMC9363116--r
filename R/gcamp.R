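#' Convolve a signal with the fluorescence indicator kernel
#'
#' Causal convolution with \code{k(t) = exp(-t / tau_s)} (unit peak),
#' emulating the slow GCaMP6s decay (characteristic time 2 s). Implemented
#' as the exact recursive filter of the sampled kernel, so a unit impulse
#' maps to \code{exp(-t / tau_s)} sampled on the grid.
#'
#' @param x numeric signal, uniformly sampled.
#' @param dt sample interval in seconds.
#' @param tau_s kernel decay time (default 2 s).
#' @return numeric vector of the same length.
#' @export
gcamp_convolve <- function(x, dt, tau_s = 2) {
  stopifnot(dt > 0, tau_s > 0)
  a <- exp(-dt / tau_s)
  as.numeric(stats::filter(x, a, method = "recursive"))
}
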