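// Passive branched-cable stepper: backward Euler in time with a Hines
// (tree-ordered tridiagonal) direct solve per step.  Compartments are
// ordered so that parent[i] < i, which makes one downward elimination
// sweep and one upward substitution sweep exact.
//
// Units: mV, ms, uS, nF (so uS * mV = nA and nF * mV / ms = nA).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cable_run_cpp(IntegerVector parent,      // 0-based, -1 for the root
                   NumericVector cm,          // nF per compartment
                   NumericVector gpas,        // uS leak per compartment
                   NumericVector gax,         // uS coupling to parent
                   double e_pas,
                   IntegerVector syn_comp,    // 0-based compartment index
                   IntegerVector syn_kind,    // 0 = AMPA, 1 = NMDA
                   NumericVector syn_weight,  // uS
                   NumericVector syn_esyn,    // mV
                   double ampa_tau,           // ms
                   double nmda_alpha, double nmda_beta, double nmda_cmax,
                   double nmda_pulse, double mg,
                   NumericVector spike_times, // concatenated, sorted per syn
                   IntegerVector spike_start, // 0-based offset per synapse
                   IntegerVector spike_count,
                   double dt, int nsteps,
                   double v_init,
                   NumericVector i_const,    // nA injected per compartment
                   IntegerVector record) {   // 0-based compartments
  const int n = parent.size();
  const int ns = syn_comp.size();

  std::vector<double> v(n, v_init), A(n), rhs(n), diag_base(n);
  for (int i = 0; i < n; ++i) diag_base[i] = cm[i] / dt + gpas[i] + gax[i];
  for (int i = 1; i < n; ++i) diag_base[parent[i]] += gax[i];

  const double ampa_decay = std::exp(-dt / ampa_tau);
  const double rtau = 1.0 / (nmda_alpha + nmda_beta);
  const double rinf = nmda_cmax * nmda_alpha * rtau;
  const double on_decay = std::exp(-dt / rtau);
  const double off_decay = std::exp(-nmda_beta * dt);

  std::vector<double> g_ampa(ns, 0.0), r_nmda(ns, 0.0), pulse_end(ns, -1.0);
  std::vector<int> next_spike(ns);
  for (int s = 0; s < ns; ++s) next_spike[s] = spike_start[s];

  const int nrec = record.size();
  NumericMatrix out(nsteps + 1, nrec);
  for (int j = 0; j < nrec; ++j) out(0, j) = v[record[j]];

  std::vector<double> gsyn_sum(n), isyn_sum(n);

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    std::fill(gsyn_sum.begin(), gsyn_sum.end(), 0.0);
    std::fill(isyn_sum.begin(), isyn_sum.end(), 0.0);

    for (int s = 0; s < ns; ++s) {
      // deliver spikes due in (t, t+dt]
      const int lim = spike_start[s] + spike_count[s];
      if (syn_kind[s] == 0) {
        g_ampa[s] *= ampa_decay;
        while (next_spike[s] < lim && spike_times[next_spike[s]] <= t + dt) {
          g_ampa[s] += syn_weight[s];
          ++next_spike[s];
        }
        gsyn_sum[syn_comp[s]] += g_ampa[s];
        isyn_sum[syn_comp[s]] += g_ampa[s] * syn_esyn[s];
      } else {
        while (next_spike[s] < lim && spike_times[next_spike[s]] <= t + dt) {
          pulse_end[s] = spike_times[next_spike[s]] + nmda_pulse;
          ++next_spike[s];
        }
        if (t + dt <= pulse_end[s])
          r_nmda[s] = rinf + (r_nmda[s] - rinf) * on_decay;
        else
          r_nmda[s] *= off_decay;
        // voltage-dependent Mg block evaluated at the previous voltage
        const double block =
          1.0 / (1.0 + std::exp(-0.062 * v[syn_comp[s]]) * mg / 3.57);
        const double g = syn_weight[s] * r_nmda[s] * block;
        gsyn_sum[syn_comp[s]] += g;
        isyn_sum[syn_comp[s]] += g * syn_esyn[s];
      }
    }

    for (int i = 0; i < n; ++i) {
      A[i] = diag_base[i] + gsyn_sum[i];
      rhs[i] = cm[i] / dt * v[i] + gpas[i] * e_pas + isyn_sum[i] + i_const[i];
    }
    // Hines elimination (children before parents)
    for (int i = n - 1; i >= 1; --i) {
      const double f = gax[i] / A[i];
      A[parent[i]] -= f * gax[i];
      rhs[parent[i]] += f * rhs[i];
    }
    v[0] = rhs[0] / A[0];
    for (int i = 1; i < n; ++i) v[i] = (rhs[i] + gax[i] * v[parent[i]]) / A[i];

    for (int i = 0; i < n; ++i)
      if (!std::isfinite(v[i]))
        stop("numerical instability: non-finite voltage at t = %f ms", t);

    for (int j = 0; j < nrec; ++j) out(step + 1, j) = v[record[j]];
  }
  return List::create(_["v"] = out);
}
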