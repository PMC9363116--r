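# Run expr with a temporary RNG seed, restoring global RNG state after.
# All generators and surrogate routines funnel through this so that they
# behave as pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# uniform integer shifts in [1, n - 1]; excludes 0 so a surrogate row never
# equals the original
draw_shifts <- function(n_cells, n_frames) {
  if (n_frames < 2) stop("circular shifts need at least 2 frames")
  sample.int(n_frames - 1L, n_cells, replace = TRUE)
}

rotate_vector <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  c(x[(n - k + 1L):n], x[seq_len(n - k)])
}

sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}
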