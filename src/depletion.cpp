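#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fixed-step Monte Carlo of the multi-source synaptic depletion-
// replenishment spike generator. Per step of length dt and per source k a
// release occurs when a uniform draw r < p_depl[k] * n[k] * dt; a release
// decrements the pool by 1 (floored at 0) and resets the source's release
// clock. Otherwise the pool replenishes toward n_max[k]:
//   scheme 0 ("relaxation"): n += (n_max - n) * (1 - exp(-dt / tau_repl)),
//     the exact per-step solution of dn/dt = (n_max - n) / tau_repl;
//   scheme 1 ("printed"):    n += (n_max - n) * (1 - exp(-(t - t_rel) / tau_repl)),
//     a recursive update whose exponent uses the absolute time since the
//     last release (kept for sensitivity comparison; its replenishment
//     speed depends on dt).
// A release triggers a spike only outside the refractory period; each
// spike starts a new refractory interval t_D + Exp(mean t_R). Releases
// during refractoriness optionally still deplete the pool.

// [[Rcpp::export]]
List simulate_depletion_cpp(NumericVector n_max, NumericVector p_depl,
                            NumericVector tau_repl, double t_D, double t_R,
                            int n_isis, double dt,
                            bool deplete_during_refractory, int scheme,
                            bool record_releases, double max_steps) {
  const int K = n_max.size();
  if (p_depl.size() != K || tau_repl.size() != K)
    stop("per-source parameter vectors must have equal length");
  for (int k = 0; k < K; ++k) {
    if (p_depl[k] * n_max[k] * dt > 0.1)
      stop("step size too coarse: per-step release probability exceeds 0.1");
  }

  std::vector<double> pool(K), t_rel(K), relax(K);
  for (int k = 0; k < K; ++k) {
    pool[k] = n_max[k];
    t_rel[k] = 0.0;
    relax[k] = 1.0 - std::exp(-dt / tau_repl[k]);
  }

  std::vector<double> spikes;
  spikes.reserve(n_isis + 1);
  std::vector< std::vector<double> > releases(K);

  double t = 0.0;
  double refr_until = -1.0;  // no refractory before the first spike
  double steps = 0.0;
  int n_spikes = 0;

  while (n_spikes < n_isis + 1) {
    t += dt;
    if (++steps > max_steps)
      stop("simulation exceeded max_steps before producing n_isis ISIs");
    for (int k = 0; k < K; ++k) {
      // re-evaluated per source: an earlier source's spike in this same
      // step starts a refractory period that silences the later ones
      const bool in_refr = (t < refr_until);
      bool released = false;
      if (!in_refr || deplete_during_refractory) {
        double r = unif_rand();
        if (r < p_depl[k] * pool[k] * dt) {
          released = true;
          pool[k] = std::max(pool[k] - 1.0, 0.0);
          t_rel[k] = t;
          if (record_releases) releases[k].push_back(t);
          if (!in_refr && n_spikes < n_isis + 1) {
            spikes.push_back(t);
            ++n_spikes;
            refr_until = t + t_D + (t_R > 0 ? exp_rand() * t_R : 0.0);
          }
        }
      }
      if (!released) {
        if (scheme == 0) {
          pool[k] += (n_max[k] - pool[k]) * relax[k];
        } else {
          pool[k] += (n_max[k] - pool[k]) *
                     (1.0 - std::exp(-(t - t_rel[k]) / tau_repl[k]));
        }
      }
    }
  }

  List rel_out(K);
  if (record_releases)
    for (int k = 0; k < K; ++k) rel_out[k] = wrap(releases[k]);
  return List::create(_["spikes"] = wrap(spikes),
                      _["releases"] = rel_out,
                      _["final_pools"] = wrap(pool));
}
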