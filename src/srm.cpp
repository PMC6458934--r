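#include <Rcpp.h>
using namespace Rcpp;

// Spike Response Model kernel: eps(s) = (s/tau) * exp(1 - s/tau) for s > 0, else 0.
static inline double psp(double s, double tau) {
  if (s <= 0.0) return 0.0;
  double x = s / tau;
  return x * std::exp(1.0 - x);
}

// Earliest grid time t in [search_from, t_end] (step dt) at which the
// membrane potential sum_i w_i * eps(t - onset_i) reaches theta.
// onset_i = presynaptic spike time + synaptic delay. Non-firing -> NA.
// [[Rcpp::export(name = ".first_spike_grid")]]
double first_spike_grid(NumericVector onset, NumericVector weight,
                        double tau, double theta,
                        double search_from, double t_end, double dt) {
  const int n = onset.size();
  const long K = (long)std::floor((t_end - search_from) / dt + 1e-9);
  for (long k = 0; k <= K; ++k) {
    double t = search_from + (double)k * dt;
    double v = 0.0;
    for (int i = 0; i < n; ++i)
      v += weight[i] * psp(t - onset[i], tau);
    if (v >= theta) return t;
  }
  return NA_REAL;
}

// Membrane potential at each time in t for one neuron.
// [[Rcpp::export(name = ".membrane_grid")]]
NumericVector membrane_grid(NumericVector t, NumericVector onset,
                            NumericVector weight, double tau) {
  const int nt = t.size(), n = onset.size();
  NumericVector out(nt);
  for (int k = 0; k < nt; ++k) {
    double v = 0.0;
    for (int i = 0; i < n; ++i)
      v += weight[i] * psp(t[k] - onset[i], tau);
    out[k] = v;
  }
  return out;
}
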