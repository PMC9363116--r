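#' Parameters of the sparse leaky integrate-and-fire network
#'
#' Two populations of LIF neurons with fixed in-degree random connectivity:
#' each neuron of population a receives exactly \code{C_ab} inputs from
#' randomly selected neurons of population b, with weight \code{w_ab}.
#' Presynaptic spikes produce exponentially decaying postsynaptic currents
#' with slow decay constants that stand in for the slow kinetics of early
#' synaptic transmission. Perisomatic inhibition is manipulated through
#' \code{C_EI}, the number of I-to-E connections. Faster timescales are
#' represented by a normally distributed noisy input to every cell. The
#' drive and weights of [lif_params_weak()] / [lif_params_strong()] are
#' tuned so that the 100-ms-bin fraction of active E cells sits in the
#' few-percent range typical of the imaging data.
#'
#' @param N_E,N_I population sizes.
#' @param C_EE,C_EI,C_IE,C_II in-degrees (presynaptic counts).
#' @param w_EE,w_EI,w_IE,w_II synaptic weight magnitudes (inhibitory
#'   weights are applied with negative sign).
#' @param tau_m membrane time constant (s).
#' @param V_th,V_reset spike threshold and reset (dimensionless units).
#' @param tau_ref absolute refractory period (s).
#' @param tau_syn_E,tau_syn_I synaptic current decay constants (s).
#' @param I_ext_E,I_ext_I constant external drive.
#' @param noise_sd white-noise input amplitude.
#' @param pulse_amp_E,pulse_amp_I feedforward pulse amplitudes.
#' @param dt integration step (s).
#' @param T_s simulated time (s).
#' @return a \code{lif_params} list.
#' @export
lif_params <- function(N_E = 400, N_I = 100,
                       C_EE = 40, C_EI = 20, C_IE = 40, C_II = 10,
                       w_EE = 0.002, w_EI = 0.006, w_IE = 0.006,
                       w_II = 0.005,
                       tau_m = 0.05, V_th = 1, V_reset = 0,
                       tau_ref = 0.005,
                       tau_syn_E = 1, tau_syn_I = 1,
                       I_ext_E = 0.86, I_ext_I = 0.8, noise_sd = 0.025,
                       pulse_amp_E = 0.2, pulse_amp_I = 0.4,
                       dt = 1e-3, T_s = 100) {
  p <- as.list(environment())
  stopifnot(p$V_th > p$V_reset, p$tau_m > 0, p$tau_syn_E > 0,
            p$tau_syn_I > 0, p$tau_ref >= 0, p$dt > 0, p$T_s > 0,
            p$C_EE <= p$N_E, p$C_IE <= p$N_E,
            p$C_EI <= p$N_I, p$C_II <= p$N_I)
  structure(p, class = "lif_params")
}

#' @rdname lif_params
#' @export
lif_params_weak <- function(...) lif_params(C_EI = 10, ...)

#' @rdname lif_params
#' @export
lif_params_strong <- function(...) lif_params(C_EI = 40, ...)

#' Simulate the LIF network
#'
#' Euler integration of the membrane equation with exponential synaptic
#' currents, threshold/reset spiking and an absolute refractory period.
#' Short feedforward pulses are applied to every neuron at
#' \code{pulse_times}. Besides spike trains the result carries the
#' 100-ms-bin fraction of active cells per population (a cell is active in
#' a bin when it fires at least once), the quantity compared with the
#' imaging data.
#'
#' @param params a [lif_params()] object.
#' @param pulse_times pulse onset times (s).
#' @param seed integer seed (connectivity and noise).
#' @param pulse_dur_lognormal optional \code{c(mu, sigma)} for log-normal
#'   pulse durations; default uses a fixed 0.4 s pulse.
#' @param pulse_dur_s fixed pulse duration when durations are not drawn.
#' @param bin_s width of the activity bins (default 0.1 s).
#' @return object of class \code{lif_sim}: \code{spike_times},
#'   \code{spike_ids}, \code{bin_time}, \code{active_frac_E},
#'   \code{active_frac_I}, \code{pulse_times}, \code{params}.
#' @export
simulate_lif <- function(params, pulse_times = numeric(), seed = 1,
                         pulse_dur_lognormal = NULL, pulse_dur_s = 0.4,
                         bin_s = 0.1) {
  stopifnot(inherits(params, "lif_params"))
  p <- params
  with_seed(seed, {
    durs <- if (is.null(pulse_dur_lognormal))
      rep(pulse_dur_s, length(pulse_times))
    else stats::rlnorm(length(pulse_times), pulse_dur_lognormal[1L],
                       pulse_dur_lognormal[2L])
    res <- lif_simulate_cpp(p$N_E, p$N_I, p$C_EE, p$C_EI, p$C_IE, p$C_II,
                            p$w_EE, p$w_EI, p$w_IE, p$w_II,
                            p$tau_m, p$V_th, p$V_reset, p$tau_ref,
                            p$tau_syn_E, p$tau_syn_I,
                            p$I_ext_E, p$I_ext_I, p$noise_sd,
                            pulse_times, pulse_times + durs,
                            p$pulse_amp_E, p$pulse_amp_I, p$dt, p$T_s)
    n_bins <- floor(p$T_s / bin_s)
    bin_of <- pmin(n_bins, floor(res$spike_times / bin_s) + 1L)
    is_E <- res$spike_ids <= p$N_E
    frac <- function(sel, n_pop) {
      if (n_pop == 0L) return(rep(0, n_bins))
      key <- unique(cbind(bin_of[sel], res$spike_ids[sel]))
      tabulate(key[, 1L], nbins = n_bins) / n_pop
    }
    structure(list(spike_times = res$spike_times,
                   spike_ids = res$spike_ids,
                   bin_time = (seq_len(n_bins) - 0.5) * bin_s,
                   bin_s = bin_s,
                   active_frac_E = frac(is_E, p$N_E),
                   active_frac_I = frac(!is_E, p$N_I),
                   pulse_times = pulse_times, pulse_durs = durs,
                   dt = p$dt, kind = "lif", params = p),
              class = "lif_sim")
  })
}

#' Closed-form firing rate of a noiseless LIF neuron
#'
#' For constant suprathreshold drive I the deterministic LIF fires at
#' \deqn{1 / (\tau_{ref} + \tau_m \log((I - V_{reset}) / (I - V_{th})))}
#' used as the independent check of the simulator.
#'
#' @param I constant input current.
#' @param tau_m,V_th,V_reset,tau_ref neuron constants.
#' @return rate in Hz (0 if subthreshold).
#' @export
lif_rate_closed_form <- function(I, tau_m, V_th, V_reset, tau_ref) {
  if (I <= V_th) return(0)
  1 / (tau_ref + tau_m * log((I - V_reset) / (I - V_th)))
}

#' Pulse-triggered average response (model PMTH)
#'
#' Averages the indicator-convolved population signal in a window centred
#' on every pulse onset: the population rate for the rate model, the
#' 100-ms-bin active-cell fraction for the LIF network. The same binning
#' contract as the imaging PMTH.
#'
#' @param sim a \code{rate_sim} or \code{lif_sim}.
#' @param window_s total window length (s), centred on onsets.
#' @param gcamp_tau_s indicator decay time; 0 disables convolution.
#' @param population \code{"E"} or \code{"I"}.
#' @return list with \code{bin_centers} (s, relative to onset),
#'   \code{response}, \code{baseline} (mean of the pre-onset half) and
#'   \code{n_pulses}.
#' @export
model_pmth <- function(sim, window_s = 20, gcamp_tau_s = 2,
                       population = "E") {
  if (length(sim$pulse_times) < 1) stop("no pulses in the simulation")
  if (sim$kind == "rate") {
    step <- sim$dt
    sig <- sim$rates[, population]
  } else {
    step <- sim$bin_s
    sig <- if (population == "E") sim$active_frac_E else sim$active_frac_I
  }
  if (gcamp_tau_s > 0) sig <- gcamp_convolve(sig, step, gcamp_tau_s)
  half <- round(window_s / 2 / step)
  n <- length(sig)
  idx <- round(sim$pulse_times / step)
  idx <- idx[idx - half >= 1 & idx + half <= n]
  if (length(idx) == 0L) stop("no pulse with a full window inside the run")
  win <- vapply(idx, function(i) sig[(i - half):(i + half)],
                numeric(2L * half + 1L))
  response <- rowMeans(win)
  bc <- seq(-half, half) * step
  list(bin_centers = bc, response = response,
       baseline = mean(response[bc < 0]), n_pulses = length(idx))
}

#' Sweep the inhibitory-to-excitatory coupling
#'
#' Re-simulates the model over a list of J_EI values (interaction weight
#' for the rate model, I-to-E in-degree \code{C_EI} for the LIF network)
#' and summarises, for each, the pulse response of the E population (peak
#' above baseline and undershoot depth below baseline) and the minimum of
#' the E auto-correlogram at positive lags (rate model: from the analytic
#' expressions).
#'
#' @param base_params a [rate_params()] or [lif_params()] object.
#' @param jei_values numeric (rate: J_EI weights; LIF: C_EI in-degrees).
#' @param pulse_times pulse onsets (s).
#' @param seed integer seed.
#' @param gcamp_tau_s indicator decay time.
#' @return data.frame with columns \code{J_EI}, \code{peak},
#'   \code{undershoot}, \code{corr_min_pos}.
#' @export
sweep_jei <- function(base_params, jei_values, pulse_times, seed = 1,
                      gcamp_tau_s = 2) {
  stopifnot(length(jei_values) >= 2)
  is_rate <- inherits(base_params, "rate_params")
  rows <- lapply(jei_values, function(j) {
    p <- base_params
    if (is_rate) p$J_EI <- j else p$C_EI <- as.integer(j)
    sim <- if (is_rate) simulate_rate(p, pulse_times, seed = seed)
           else simulate_lif(p, pulse_times, seed = seed)
    pm <- model_pmth(sim, gcamp_tau_s = gcamp_tau_s)
    post <- pm$bin_centers > 0
    corr_min <- if (is_rate) {
      ac <- analytic_rate_correlation(p, gcamp_tau_s = gcamp_tau_s)$ee
      min(ac$values[ac$lags > 0.5], na.rm = TRUE)
    } else {
      sig <- gcamp_convolve(sim$active_frac_E, sim$bin_s, gcamp_tau_s)
      cg <- crosscorrelogram(sig, sig, bin_s = sim$bin_s, max_lag_s = 10)
      min(cg$values[cg$lags > 0.5], na.rm = TRUE)
    }
    data.frame(J_EI = j,
               peak = max(pm$response) - pm$baseline,
               undershoot = pm$baseline - min(pm$response[post]),
               corr_min_pos = corr_min)
  })
  do.call(rbind, rows)
}
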