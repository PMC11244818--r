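#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stationary firing rate of an EIF neuron driven by white noise with
// infinitesimal mean mu (mV/ms) and variance s (mV^2/ms), by backward
// "threshold integration" of the steady-state Fokker-Planck flux equations:
// integrate the scaled density p = P/nu from V_peak down to V_lb with unit
// flux above the reset (reinjection at V_r), then nu = 1 / integral(p dV).
// The per-interval update uses the exact solution of dp/dV = G p - F with
// frozen midpoint coefficients, which is stable in the backward direction.

static double fp_rate_one(double mu, double s, double V_L, double V_T,
                          double Delta_T, double V_peak, double V_r,
                          double tau_m, double V_lb, double dV) {
  const int n = (int)std::lround((V_peak - V_lb) / dV);
  const int k_r = (int)std::lround((V_r - V_lb) / dV);
  double p = 0.0;     // p at upper edge of current interval; p(V_peak) = 0
  double integral = 0.0;
  for (int k = n; k >= 1; --k) {
    const double Vm = V_lb + (k - 0.5) * dV;
    const double psi =
        (-(Vm - V_L) + Delta_T * std::exp((Vm - V_T) / Delta_T)) / tau_m + mu;
    const double G = 2.0 * psi / s;
    const double A = G * dV;
    const double j = (k - 1 >= k_r) ? 1.0 : 0.0;
    double pl;  // p at lower edge
    if (std::fabs(A) < 1e-10) {
      pl = p * (1.0 - A) + (2.0 * j / s) * dV * (1.0 - 0.5 * A);
    } else {
      const double E = std::exp(-A);
      pl = p * E + (2.0 * j / s) * (-std::expm1(-A) / G);
    }
    integral += 0.5 * (p + pl) * dV;
    p = pl;
    if (integral > 1e280) return 0.0;  // deep subthreshold: rate ~ 0
  }
  return 1000.0 / integral;  // ms^-1 -> spikes/s
}

// [[Rcpp::export]]
NumericVector eif_fp_rate_cpp(NumericVector mu, NumericVector s, double V_L,
                              double V_T, double Delta_T, double V_peak,
                              double V_r, double tau_m, double V_lb,
                              double dV) {
  const int m = mu.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    if (s[i] <= 0) stop("noise variance s must be > 0");
    out[i] = fp_rate_one(mu[i], s[i], V_L, V_T, Delta_T, V_peak, V_r, tau_m,
                         V_lb, dV);
    if ((i & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Euler-Maruyama Monte-Carlo estimate of the same stationary rate: n_rep
// independent neurons, burn_ms discarded, spikes counted over T_ms each.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
double eif_mc_rate_cpp(double mu, double s, double V_L, double V_T,
                       double Delta_T, double V_peak, double V_r,
                       double tau_m, double T_ms, double dt, int n_rep,
                       double burn_ms) {
  const long burn = (long)std::llround(burn_ms / dt);
  const long steps = (long)std::llround(T_ms / dt);
  const double sq = std::sqrt(s * dt);
  long count = 0;
  for (int r = 0; r < n_rep; ++r) {
    double V = V_L;
    for (long k = 0; k < burn + steps; ++k) {
      const double Vc = V < V_peak ? V : V_peak;
      V += dt * ((-(V - V_L) + Delta_T * std::exp((Vc - V_T) / Delta_T)) /
                     tau_m + mu) + sq * norm_rand();
      if (V >= V_peak) {
        V = V_r;
        if (k >= burn) count++;
      }
      if ((k & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }
  return 1000.0 * (double)count / ((double)n_rep * T_ms);
}
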