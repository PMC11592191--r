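#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Fixed-step integrator for the single-compartment conductance model under
// current clamp.  States: V, Na activation m, Na inactivation h, and the two
// potassium activations.  Gating variables use exponential Euler toward their
// Boltzmann steady states; V uses forward Euler.  dt must resolve the fastest
// gate (tau_m ~ 0.15 ms), so the default 0.01 ms is comfortable.
//
// p: named numeric vector with the channel_params fields (flattened).
// i_amp injected from t in [onset, onset+dur), zero elsewhere.
// Records V every `record_every` steps (sample 0 = t 0).
// [[Rcpp::export]]
NumericVector cclamp_integrate_cpp(NumericVector p,
                                   double v0,
                                   double i_amp, double onset, double dur,
                                   double total, double dt, int record_every) {
  const double g_leak = p["g_leak"], e_leak = p["e_leak"], e_k = p["e_k"],
               c_m = p["c_m"];
  const double gl = p["lva_g"], vl = p["lva_v50"], kl = p["lva_k"],
               bl = p["lva_b"], tl = p["lva_tau"];
  const double gh = p["hva_g"], vh = p["hva_v50"], kh = p["hva_k"],
               bh = p["hva_b"], th = p["hva_tau"];
  const double gna = p["g_na"], ena = p["e_na"],
               mv50 = p["act_v50"], mk = p["act_k"],
               hv50 = p["inact_v50"], hk = p["inact_k"],
               tau_m = p["tau_m"], tau_h = p["tau_h"];

  const long n_steps = (long)std::llround(total / dt);
  const long n_rec = n_steps / record_every + 1;
  NumericVector out(n_rec);

  double v = v0;
  double al = bl + (1.0 - bl) * logistic((v - vl) / kl);
  double ah = bh + (1.0 - bh) * logistic((v - vh) / kh);
  double m = logistic((v - mv50) / mk);
  double h = logistic(-(v - hv50) / hk);

  const double fl = 1.0 - std::exp(-dt / tl);
  const double fh = 1.0 - std::exp(-dt / th);
  const double fm = 1.0 - std::exp(-dt / tau_m);
  const double fhh = 1.0 - std::exp(-dt / tau_h);

  out[0] = v;
  long rec = 1;
  for (long s = 1; s <= n_steps; ++s) {
    const double t = (s - 1) * dt;  // stimulus evaluated at interval start
    const double inj = (t >= onset && t < onset + dur) ? i_amp : 0.0;

    const double i_ion = g_leak * (v - e_leak) +
      gl * al * (v - e_k) + gh * ah * (v - e_k) +
      gna * m * m * m * h * (v - ena);
    v += dt * (inj - i_ion) / c_m;

    if (!std::isfinite(v)) stop("simulation failure: non-finite state");

    al += (bl + (1.0 - bl) * logistic((v - vl) / kl) - al) * fl;
    ah += (bh + (1.0 - bh) * logistic((v - vh) / kh) - ah) * fh;
    m  += (logistic((v - mv50) / mk) - m) * fm;
    h  += (logistic(-(v - hv50) / hk) - h) * fhh;

    if (s % record_every == 0 && rec < n_rec) out[rec++] = v;
  }
  return out;
}
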