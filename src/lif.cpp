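#include <Rcpp.h>
using namespace Rcpp;

// Sparse two-population LIF network, exponential synapses, fixed in-degree.
// Populations: E neurons are ids [0, N_E), I neurons [N_E, N_E + N_I).
// dV/dt = (-V + s_E - s_I + I_ext + pulse(t))/tau_m + noise
// Presynaptic spikes add w_ab to the matching synaptic current of their
// targets; currents decay with tau_syn of the presynaptic type.
// Spike at V >= V_th -> reset to V_reset, refractory tau_ref.
// [[Rcpp::export]]
List lif_simulate_cpp(int N_E, int N_I,
                      int C_EE, int C_EI, int C_IE, int C_II,
                      double w_EE, double w_EI, double w_IE, double w_II,
                      double tau_m, double V_th, double V_reset,
                      double tau_ref,
                      double tau_syn_E, double tau_syn_I,
                      double I_ext_E, double I_ext_I, double noise_sd,
                      NumericVector pulse_on, NumericVector pulse_off,
                      double pulse_amp_E, double pulse_amp_I,
                      double dt, double T_s) {
  const int N = N_E + N_I;
  const int n_steps = (int)std::round(T_s / dt);

  // fixed in-degree adjacency: for each neuron, its presynaptic E and I ids
  std::vector<std::vector<int>> pre_E(N), pre_I(N);
  for (int i = 0; i < N; ++i) {
    const bool is_E = i < N_E;
    const int cE = is_E ? C_EE : C_IE;
    const int cI = is_E ? C_EI : C_II;
    if (cE > N_E || cI > N_I) stop("in-degree exceeds population size");
    if (cE > 0 && N_E > 0) {
      IntegerVector s = Rcpp::sample(N_E, cE, false);  // 1-based
      for (int k = 0; k < cE; ++k) pre_E[i].push_back(s[k] - 1);
    }
    if (cI > 0 && N_I > 0) {
      IntegerVector s = Rcpp::sample(N_I, cI, false);
      for (int k = 0; k < cI; ++k) pre_I[i].push_back(s[k] - 1 + N_E);
    }
  }
  // invert to postsynaptic lists for fast propagation
  std::vector<std::vector<int>> post(N);
  for (int i = 0; i < N; ++i) {
    for (int j : pre_E[i]) post[j].push_back(i);
    for (int j : pre_I[i]) post[j].push_back(i);
  }

  std::vector<double> V(N, 0.0), sE(N, 0.0), sI(N, 0.0), ref_until(N, -1.0);
  const double decay_E = std::exp(-dt / tau_syn_E);
  const double decay_I = std::exp(-dt / tau_syn_I);
  const double sq = noise_sd * std::sqrt(dt) / tau_m;

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<int> spikers;
  int n_pulse = pulse_on.size();
  int rate_guard = 0;

  for (int t = 0; t < n_steps; ++t) {
    const double now = t * dt;
    double pulsing = 0.0;
    for (int p = 0; p < n_pulse; ++p)
      if (now >= pulse_on[p] && now < pulse_off[p]) { pulsing = 1.0; break; }

    spikers.clear();
    for (int i = 0; i < N; ++i) {
      const bool is_E = i < N_E;
      sE[i] *= decay_E;
      sI[i] *= decay_I;
      if (now < ref_until[i]) continue;
      const double I_ext = is_E ? I_ext_E : I_ext_I;
      const double p_amp = is_E ? pulse_amp_E : pulse_amp_I;
      const double I_tot = sE[i] - sI[i] + I_ext + p_amp * pulsing;
      V[i] += dt * (-V[i] + I_tot) / tau_m;
      if (noise_sd > 0) V[i] += sq * norm_rand();
      if (V[i] >= V_th) {
        V[i] = V_reset;
        ref_until[i] = now + tau_ref;
        spike_t.push_back(now);
        spike_id.push_back(i + 1);  // 1-based for R
        spikers.push_back(i);
      }
    }
    for (int j : spikers) {
      const bool j_is_E = j < N_E;
      for (int i : post[j]) {
        const bool i_is_E = i < N_E;
        if (j_is_E) sE[i] += i_is_E ? w_EE : w_IE;
        else        sI[i] += i_is_E ? w_EI : w_II;
      }
    }
    // sustained population rate guard (> 500 Hz per neuron over 100 ms)
    rate_guard += (int)spikers.size();
    if (t % (int)std::max(1.0, std::round(0.1 / dt)) == 0) {
      if (rate_guard > 50.0 * N) stop("rate explosion: population rate above 500 Hz");
      rate_guard = 0;
    }
  }
  return List::create(_["spike_times"] = wrap(spike_t),
                      _["spike_ids"] = wrap(spike_id));
}
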