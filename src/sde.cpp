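#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Population transfer function (a*I - b) / (1 - exp(-d*(a*I - b))),
// numerically stable across the removable singularity and large |argument|.
static inline double phi(double I, double a, double b, double d) {
  double x = a * I - b;
  double u = d * x;
  if (std::fabs(u) < 1e-5) return (1.0 + u / 2.0 + u * u / 12.0) / d;
  if (u >= 0.0) return x / (1.0 - std::exp(-u));
  double eu = std::exp(u);
  return x * eu / (eu - 1.0);
}

// Euler-Maruyama integration of the coupled synaptic (2N) and hemodynamic
// (4N) equations with additive Gaussian noise (sd sigma*sqrt(dt)) on both
// gating variables. Excitatory gating clamped to [0,1], inhibitory at 0.
// BOLD is sampled every `tr` seconds after `burn_in` seconds are discarded.
// [[Rcpp::export]]
List sde_integrate_cpp(NumericMatrix C, NumericVector w_EI,
                       NumericVector a_E, NumericVector a_I,
                       double Ib, double J, double gamma_kin,
                       double W_E, double W_I, double w_EE, double w_IE,
                       double tau_E, double tau_I,
                       double b_E, double d_E, double b_I, double d_I,
                       double G, double sigma,
                       double rho, double tau_h, double kappa,
                       double gamma_h, double alpha, double V0,
                       double k1, double k2, double k3,
                       NumericVector S_E0, NumericVector S_I0,
                       NumericVector x0, NumericVector f0,
                       NumericVector v0, NumericVector q0,
                       double T_total, double dt, double tr,
                       double burn_in, bool keep_synaptic) {
  const int n = C.nrow();
  const double sqdt = std::sqrt(dt);
  const double inv_alpha = 1.0 / alpha;
  const long n_steps = (long)std::llround((T_total + burn_in) / dt);
  const int sample_every = (int)std::llround(tr / dt);
  const long burn_steps = (long)std::llround(burn_in / dt);
  const int n_samples = (int)((n_steps - burn_steps) / sample_every);

  std::vector<double> SE(S_E0.begin(), S_E0.end());
  std::vector<double> SI(S_I0.begin(), S_I0.end());
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> f(f0.begin(), f0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> q(q0.begin(), q0.end());
  std::vector<double> lr(n), dSE(n), dSI(n);

  NumericMatrix bold(n_samples, n);
  NumericMatrix SEout(keep_synaptic ? n_samples : 0, keep_synaptic ? n : 0);
  NumericMatrix SIout(keep_synaptic ? n_samples : 0, keep_synaptic ? n : 0);

  RNGScope scope;
  int isamp = 0;
  for (long step = 1; step <= n_steps; ++step) {
    // long-range excitatory input
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += C(i, j) * SE[j];
      lr[i] = acc;
    }
    for (int i = 0; i < n; ++i) {
      double I_E = W_E * Ib + w_EE * SE[i] + G * J * lr[i] - w_EI[i] * SI[i];
      double I_I = W_I * Ib + w_IE * SE[i] - SI[i];
      double r_E = phi(I_E, a_E[i], b_E, d_E);
      double r_I = phi(I_I, a_I[i], b_I, d_I);
      dSE[i] = (-SE[i] / tau_E + (1.0 - SE[i]) * gamma_kin * r_E) * dt;
      dSI[i] = (-SI[i] / tau_I + r_I) * dt;
      if (sigma > 0.0) {
        dSE[i] += sigma * sqdt * norm_rand();
        dSI[i] += sigma * sqdt * norm_rand();
      }
      // hemodynamics driven by the current excitatory gating
      double E = 1.0 - std::pow(1.0 - rho, 1.0 / f[i]);
      double dx = (SE[i] - kappa * x[i] - gamma_h * (f[i] - 1.0)) * dt;
      double df = x[i] * dt;
      double dv = (f[i] - std::pow(v[i], inv_alpha)) / tau_h * dt;
      double dq = (f[i] * E / rho - q[i] * std::pow(v[i], inv_alpha - 1.0)) /
                  tau_h * dt;
      x[i] += dx; f[i] += df; v[i] += dv; q[i] += dq;
      SE[i] += dSE[i];
      SI[i] += dSI[i];
      if (SE[i] < 0.0) SE[i] = 0.0; else if (SE[i] > 1.0) SE[i] = 1.0;
      if (SI[i] < 0.0) SI[i] = 0.0;
      if (!std::isfinite(SE[i]) || !std::isfinite(f[i]) || f[i] <= 0.0 ||
          v[i] <= 0.0) {
        stop("numerical blow-up at t = %.3f s (step %ld)", step * dt, step);
      }
    }
    if (step > burn_steps && (step - burn_steps) % sample_every == 0 &&
        isamp < n_samples) {
      for (int i = 0; i < n; ++i) {
        bold(isamp, i) = V0 * (k1 * (1.0 - q[i]) + k2 * (1.0 - q[i] / v[i]) +
                               k3 * (1.0 - v[i]));
        if (keep_synaptic) {
          SEout(isamp, i) = SE[i];
          SIout(isamp, i) = SI[i];
        }
      }
      ++isamp;
    }
  }
  List out = List::create(Named("bold") = bold);
  if (keep_synaptic) {
    out["S_E"] = SEout;
    out["S_I"] = SIout;
  } else {
    out["S_E"] = R_NilValue;
    out["S_I"] = R_NilValue;
  }
  return out;
}
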