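#include <Rcpp.h>
using namespace Rcpp;

// Adaptive exponential integrate-and-fire membrane with an h-current,
// explicit Euler at fixed dt. Units: mV, ms, pA, nS, pF (so dV = dt/C * pA).
// Noise is additive Gaussian on V scaled by sqrt(dt) (diffusion convention),
// drawn from R's RNG so set.seed() in the caller governs reproducibility.
//
// Spike rule: when the Euler update carries V across 0 mV the overshooting
// value is stored as the sampled peak, the crossing time is logged, and the
// state resets (V -> Vr, w -> w + b).

static inline double minf_h(double V, double Vh, double kh) {
  double z = (V - Vh) / kh;
  if (z > 40.0) return 0.0;
  if (z < -40.0) return 1.0;
  return 1.0 / (1.0 + std::exp(z));
}

// [[Rcpp::export]]
List adex_integrate(List pars, double step_amp, double holding,
                    double onset, double duration, double total, double dt) {
  const double C      = as<double>(pars["C"]);
  const double gL     = as<double>(pars["g_L"]);
  const double EL     = as<double>(pars["E_L"]);
  const double DeltaT = as<double>(pars["Delta_T"]);
  const double VT     = as<double>(pars["V_T"]);
  const double Vr     = as<double>(pars["V_r"]);
  const double a      = as<double>(pars["a"]);
  const double b      = as<double>(pars["b"]);
  const double tau_w  = as<double>(pars["tau_w"]);
  const double gh     = as<double>(pars["g_h"]);
  const double Eh     = as<double>(pars["E_h"]);
  const double Vh     = as<double>(pars["V_h"]);
  const double kh     = as<double>(pars["k_h"]);
  const double tau_h  = as<double>(pars["tau_h"]);
  const double sigma  = as<double>(pars["noise_sd"]);

  const int n = (int) std::lround(total / dt) + 1;
  NumericVector V_out(n);
  std::vector<double> spikes;

  // start from the holding-current fixed point of the passive subsystem;
  // the pre-step baseline lets w and m settle the rest of the way
  double V = EL + holding / gL;
  double w = a * (V - EL);
  double m = minf_h(V, Vh, kh);
  const double Vclip = VT + 5.0 * DeltaT;
  const double sq = std::sqrt(dt);
  bool blew_up = false;

  V_out[0] = V;
  for (int k = 1; k < n; ++k) {
    double t_prev = (k - 1) * dt;
    double I = holding +
      ((t_prev >= onset && t_prev < onset + duration) ? step_amp : 0.0);

    double ex = 0.0;
    if (DeltaT > 0.0) {
      double Veff = (V > Vclip) ? Vclip : V;
      ex = gL * DeltaT * std::exp((Veff - VT) / DeltaT);
    }
    double dV = (dt / C) * (-gL * (V - EL) + ex - w - gh * m * (V - Eh) + I);
    double dw = dt * (a * (V - EL) - w) / tau_w;
    double dm = dt * (minf_h(V, Vh, kh) - m) / tau_h;

    double Vn = V + dV;
    if (sigma > 0.0) Vn += sigma * sq * norm_rand();
    w += dw;
    m += dm;

    if (V < 0.0 && Vn >= 0.0) {
      // crossing time by linear interpolation within the step
      double frac = (0.0 - V) / (Vn - V);
      spikes.push_back(t_prev + frac * dt);
      V_out[k] = Vn;          // sampled overshoot = the spike peak
      V = Vr;
      w += b;
      continue;
    }
    if (!std::isfinite(Vn) || Vn > 200.0 || Vn < -200.0) {
      blew_up = true;
      V_out[k] = Vn;
      break;
    }
    V = Vn;
    V_out[k] = V;
  }

  return List::create(_["voltage"] = V_out,
                      _["spike_times"] = wrap(spikes),
                      _["blew_up"] = blew_up);
}
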