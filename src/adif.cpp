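#include <Rcpp.h>
using namespace Rcpp;

// Compiled AdIF network loop. Mirrors the pure-R engine step for step and
// consumes R's RNG in the identical order (one Poisson draw per neuron per
// step, neurons in index order), so both engines are bit-reproducible from
// the same seed.
// [[Rcpp::export]]
List simulate_adif_cpp(NumericVector V0, List targets, int n_steps,
                       double dt, double lambda, double w_ext,
                       double C_m, double g_L, double E_L, double E_e,
                       double V_th, double V_r, double tau_w, double a,
                       double b, double tau_e, double w_e,
                       double max_spikes) {
  const int n = V0.size();
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> g_e(n, 0.0), w(n, 0.0);

  // adjacency as flat arrays for cache-friendly delivery
  std::vector<int> adj, adj_start(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    IntegerVector t = targets[i];
    adj_start[i + 1] = adj_start[i] + t.size();
    for (int k = 0; k < t.size(); ++k) adj.push_back(t[k] - 1);
  }

  const double decay = std::exp(-dt / tau_e);
  std::vector<int> spk_neuron;
  std::vector<double> spk_time;
  std::vector<int> cnt(n, 0), touched;

  for (int step = 1; step <= n_steps; ++step) {
    if (lambda > 0)
      for (int i = 0; i < n; ++i) {
        double k = R::rpois(lambda);
        if (k > 0) g_e[i] += w_ext * k;
      }
    // forward Euler on V and w from the pre-step state; exact decay on g_e
    for (int i = 0; i < n; ++i) {
      double Vi = V[i];
      double dV = (g_L * (E_L - Vi) + g_e[i] * (E_e - Vi) - w[i]) / C_m;
      double dw = (a * (Vi - E_L) - w[i]) / tau_w;
      V[i] = Vi + dt * dV;
      w[i] += dt * dw;
      g_e[i] *= decay;
      if (!std::isfinite(V[i]) || !std::isfinite(w[i]))
        stop("numeric-failure: non-finite state at neuron index %d", i + 1);
    }
    // threshold, reset, same-step recurrent delivery; increments from
    // several presynaptic spikers accumulate as w_e * count (bit-identical
    // to the reference engine's tabulate-and-scale)
    double t_ms = step * dt;
    touched.clear();
    for (int i = 0; i < n; ++i) {
      if (V[i] >= V_th) {
        spk_neuron.push_back(i + 1);
        spk_time.push_back(t_ms);
        V[i] = V_r;
        w[i] += b;
        for (int k = adj_start[i]; k < adj_start[i + 1]; ++k) {
          int j = adj[k];
          if (cnt[j]++ == 0) touched.push_back(j);
        }
      }
    }
    for (size_t k = 0; k < touched.size(); ++k) {
      int j = touched[k];
      g_e[j] += w_e * cnt[j];
      cnt[j] = 0;
    }
    if ((double)spk_neuron.size() > max_spikes)
      stop("runaway-network: spike budget exceeded at t = %.1f ms", t_ms);
    if (step % 50000 == 0) checkUserInterrupt();
  }
  return List::create(_["neuron"] = wrap(spk_neuron),
                      _["time_ms"] = wrap(spk_time));
}
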