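#' Parameters of the two-population rate model
#'
#' One excitatory (E) and one inhibitory (I) population with recurrent
#' interactions. \code{J_ab} is the effect of population b on a;
#' \code{J_EI} and \code{J_II} enter the input with a negative sign. Each
#' population obeys
#' \deqn{\tau_a \dot r_a = -r_a + \phi(\sum_b \pm J_{ab} r_b + I_{ext,a}
#'  + pulse(t)) + \xi_a(t)}
#' with threshold-linear \eqn{\phi} and white noise \eqn{\xi}. The time
#' constants are slow (1 s) to stand in for the slow kinetics of early
#' synaptic transmission; developmental strengthening of somatic
#' inhibition is modelled by increasing \code{J_EI}.
#'
#' The presets [rate_params_weak()] and [rate_params_strong()] give the
#' weak-inhibition (first postnatal week) and strong-inhibition (second
#' week) regimes; both have stable, strictly positive fixed points.
#'
#' @param J_EE,J_EI,J_IE,J_II interaction strengths (all given as positive
#'   magnitudes).
#' @param tau_E,tau_I time constants (s).
#' @param I_ext_E,I_ext_I constant external drive.
#' @param noise_sigma white-noise amplitude.
#' @param pulse_amp_E,pulse_amp_I feedforward pulse amplitude per
#'   population.
#' @param pulse_dur_s default pulse duration (s); [simulate_rate()] can
#'   instead draw log-normal durations per pulse.
#' @param dt integration step (s); must be below \code{min(tau)/10}.
#' @param T_s simulated time (s).
#' @return a \code{rate_params} list.
#' @export
rate_params <- function(J_EE = 0.8, J_EI = 2, J_IE = 2, J_II = 0.5,
                        tau_E = 3, tau_I = 3,
                        I_ext_E = 2, I_ext_I = 1,
                        noise_sigma = 0.1,
                        pulse_amp_E = 1, pulse_amp_I = 2,
                        pulse_dur_s = 0.4,
                        dt = 0.01, T_s = 200) {
  p <- as.list(environment())
  stopifnot(p$tau_E > 0, p$tau_I > 0, p$dt > 0, p$T_s > 0,
            p$pulse_dur_s > 0)
  if (p$dt >= min(p$tau_E, p$tau_I) / 10)
    stop("dt must be smaller than min(tau)/10")
  structure(p, class = "rate_params")
}

#' @rdname rate_params
#' @export
rate_params_weak <- function(...) rate_params(J_EI = 0.2, ...)

#' @rdname rate_params
#' @export
rate_params_strong <- function(...) rate_params(J_EI = 2, ...)

# interior fixed point r* solving r = J r + I_ext (threshold-linear branch)
rate_fixed_point <- function(p) {
  J <- matrix(c(p$J_EE, p$J_IE, -p$J_EI, -p$J_II), 2L, 2L)
  r <- solve(diag(2) - J, c(p$I_ext_E, p$I_ext_I))
  if (any(r <= 0))
    stop("fixed point is not interior (some rate <= 0); ",
         "the linearized analysis does not apply")
  r
}

# Jacobian of the rate dynamics at an interior fixed point
rate_jacobian <- function(p) {
  matrix(c((p$J_EE - 1) / p$tau_E, p$J_IE / p$tau_I,
           -p$J_EI / p$tau_E, -(1 + p$J_II) / p$tau_I), 2L, 2L)
}

#' Simulate the two-population rate model
#'
#' Euler-Maruyama integration of the noisy rate equations with
#' threshold-linear transfer; rates are clipped at zero. Short feedforward
#' pulses are added to both populations at \code{pulse_times}; their
#' durations are either \code{params$pulse_dur_s} or drawn log-normal per
#' pulse (\code{pulse_dur_lognormal}), matching the movement-duration
#' model.
#'
#' @param params a [rate_params()] object.
#' @param pulse_times pulse onset times (s); may be empty.
#' @param seed integer seed.
#' @param pulse_dur_lognormal optional \code{c(mu, sigma)} of log-normal
#'   pulse durations (log seconds).
#' @return object of class \code{rate_sim}: \code{time}, \code{rates}
#'   (columns E, I), \code{pulse_times}, \code{pulse_durs}, \code{dt}.
#' @export
simulate_rate <- function(params, pulse_times = numeric(),
                          seed = 1, pulse_dur_lognormal = NULL) {
  stopifnot(inherits(params, "rate_params"))
  p <- params
  n <- round(p$T_s / p$dt)
  with_seed(seed, {
    durs <- if (is.null(pulse_dur_lognormal))
      rep(p$pulse_dur_s, length(pulse_times))
    else stats::rlnorm(length(pulse_times), pulse_dur_lognormal[1L],
                       pulse_dur_lognormal[2L])
    pulse <- numeric(n)
    for (i in seq_along(pulse_times)) {
      i0 <- max(1L, round(pulse_times[i] / p$dt))
      i1 <- min(n, round((pulse_times[i] + durs[i]) / p$dt))
      pulse[i0:i1] <- 1
    }
    rates <- matrix(0, n, 2L, dimnames = list(NULL, c("E", "I")))
    r <- tryCatch(rate_fixed_point(p), error = function(e) c(1, 1))
    sqdt <- sqrt(p$dt)
    noise <- matrix(stats::rnorm(2L * n), n, 2L)
    for (t in seq_len(n)) {
      uE <- p$J_EE * r[1L] - p$J_EI * r[2L] + p$I_ext_E +
        p$pulse_amp_E * pulse[t]
      uI <- p$J_IE * r[1L] - p$J_II * r[2L] + p$I_ext_I +
        p$pulse_amp_I * pulse[t]
      r[1L] <- r[1L] + p$dt / p$tau_E * (-r[1L] + max(0, uE)) +
        p$noise_sigma / p$tau_E * sqdt * noise[t, 1L]
      r[2L] <- r[2L] + p$dt / p$tau_I * (-r[2L] + max(0, uI)) +
        p$noise_sigma / p$tau_I * sqdt * noise[t, 2L]
      r[r < 0] <- 0
      if (any(abs(r) > 1e6))
        stop("rate divergence: unstable parameter regime (|r| > 1e6); ",
             "check J_EE against the inhibitory feedback loop")
      rates[t, ] <- r
    }
    structure(list(time = seq_len(n) * p$dt, rates = rates,
                   pulse_times = pulse_times, pulse_durs = durs,
                   dt = p$dt, kind = "rate"),
              class = "rate_sim")
  })
}

#' Analytic correlation functions of the linearized rate model
#'
#' For the noise-driven linearization around the interior fixed point, the
#' stationary covariance \eqn{C_0} solves the continuous Lyapunov equation
#' \eqn{A C_0 + C_0 A^T + D = 0} and the lagged covariance is
#' \eqn{C(\tau) = e^{A\tau} C_0} for \eqn{\tau \ge 0} (transposed relation
#' for negative lags). The covariances are then convolved with the
#' symmetric autocorrelation of the exponential indicator kernel and
#' normalized to correlation, so they predict exactly what the empirical
#' correlogram estimator measures on kernel-convolved simulated rates.
#'
#' @param params a [rate_params()] object.
#' @param gcamp_tau_s indicator decay time (default 2 s); \code{0} skips
#'   kernel smoothing.
#' @param max_lag_s maximal lag (s).
#' @param dt lag grid step (s).
#' @return list of \code{correlogram}-like objects \code{ee}, \code{ii},
#'   \code{ei} (positive lag: I follows E) and \code{ie}, each with
#'   \code{lags} and \code{values}.
#' @export
analytic_rate_correlation <- function(params, gcamp_tau_s = 2,
                                      max_lag_s = 10, dt = 0.01) {
  stopifnot(inherits(params, "rate_params"))
  p <- params
  rate_fixed_point(p)
  A <- rate_jacobian(p)
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("linearized system is unstable (eigenvalue with Re >= 0)")
  D <- diag(c(p$noise_sigma^2 / p$tau_E^2, p$noise_sigma^2 / p$tau_I^2))
  # vec(C0) solves (I (x) A + A (x) I) vec(C0) = -vec(D)
  K <- kronecker(diag(2), A) + kronecker(A, diag(2))
  C0 <- matrix(solve(K, -as.vector(D)), 2L, 2L)
  C0 <- (C0 + t(C0)) / 2

  pad <- if (gcamp_tau_s > 0) 8 * gcamp_tau_s else 0
  max_k <- round((max_lag_s + pad) / dt)
  taus <- seq(0, max_k) * dt
  E <- eigen(A)
  Vi <- solve(E$vectors)
  expA <- function(tt) {
    M <- E$vectors %*% diag(exp(E$values * tt), 2L) %*% Vi
    Re(M)
  }
  # gamma[[i]][[j]](tau) on the padded grid, tau >= 0: E[r(t+tau) r(t)^T]c
  gpos <- lapply(taus, function(tt) expA(tt) %*% C0)
  cov_fun <- function(i, j) {
    # cov(a_i(t), a_j(t + tau)) over signed lags
    pos <- vapply(gpos, function(M) M[j, i], numeric(1))   # tau >= 0
    neg <- vapply(gpos, function(M) M[i, j], numeric(1))   # tau < 0 mirror
    c(rev(neg[-1L]), pos)
  }
  lags_full <- c(rev(-taus[-1L]), taus)
  smooth <- function(v) {
    if (gcamp_tau_s <= 0) return(v)
    g <- exp(-abs(lags_full) / gcamp_tau_s)
    g <- g / sum(g)
    # open convolution, trimmed back to the original grid
    full <- stats::convolve(v, rev(g), type = "open")
    m <- (length(full) + 1L) %/% 2L
    half <- (length(v) - 1L) %/% 2L
    full[(m - half):(m + half)]
  }
  cee <- smooth(cov_fun(1L, 1L))
  cii <- smooth(cov_fun(2L, 2L))
  cei <- smooth(cov_fun(1L, 2L))
  cie <- smooth(cov_fun(2L, 1L))
  mid <- (length(lags_full) + 1L) %/% 2L
  norm_ee <- cee[mid]; norm_ii <- cii[mid]
  keep <- abs(lags_full) <= max_lag_s + 1e-9
  mk <- function(v, denom) {
    structure(list(lags = lags_full[keep], values = (v / denom)[keep],
                   bin_s = dt, max_lag_s = max_lag_s),
              class = "correlogram")
  }
  list(ee = mk(cee, norm_ee), ii = mk(cii, norm_ii),
       ei = mk(cei, sqrt(norm_ee * norm_ii)),
       ie = mk(cie, sqrt(norm_ee * norm_ii)))
}
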