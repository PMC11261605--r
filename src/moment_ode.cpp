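#include <Rcpp.h>
using namespace Rcpp;

// Moment equations of nucleation-elongation fibrillization, in the whitened
// form where P absorbs the elongation rate: with m = 1 - M,
//   dP/dt = lam^2 * m^n_c + kap^2 * m^n_2 * M,   dM/dt = m * P.
// Classical RK4 with a step bounded by hmax; dense output at the (sorted,
// non-negative) requested times.

static inline double ipow(double x, double e) {
  // fast path for the small integer orders used in practice
  if (e == 2.0) return x * x;
  if (e == 1.0) return x;
  if (e == 3.0) return x * x * x;
  if (e == 0.0) return 1.0;
  return std::pow(x, e);
}

static inline void deriv(double M, double P, double lam2, double kap2,
                         double nc, double n2, double *dM, double *dP) {
  double m = 1.0 - M;
  if (m < 0.0) m = 0.0;
  *dP = lam2 * ipow(m, nc) + kap2 * ipow(m, n2) * M;
  *dM = m * P;
}

// [[Rcpp::export]]
NumericVector moment_ode_mass_cpp(NumericVector times, double lam, double kap,
                                  double nc, double n2, double hmax) {
  const double lam2 = lam * lam, kap2 = kap * kap;
  const int n = times.size();
  NumericVector out(n);
  double M = 0.0, P = 0.0, t = 0.0;
  bool saturated = false;
  for (int i = 0; i < n; ++i) {
    const double target = times[i];
    if (saturated) { out[i] = M; continue; }
    while (t < target - 1e-13) {
      double h = target - t;
      if (h > hmax) h = hmax;
      double dM1, dP1, dM2, dP2, dM3, dP3, dM4, dP4;
      deriv(M, P, lam2, kap2, nc, n2, &dM1, &dP1);
      deriv(M + 0.5 * h * dM1, P + 0.5 * h * dP1, lam2, kap2, nc, n2, &dM2, &dP2);
      deriv(M + 0.5 * h * dM2, P + 0.5 * h * dP2, lam2, kap2, nc, n2, &dM3, &dP3);
      deriv(M + h * dM3, P + h * dP3, lam2, kap2, nc, n2, &dM4, &dP4);
      M += h / 6.0 * (dM1 + 2.0 * dM2 + 2.0 * dM3 + dM4);
      P += h / 6.0 * (dP1 + 2.0 * dP2 + 2.0 * dP3 + dP4);
      if (M > 1.0) M = 1.0;
      if (M < 0.0) M = 0.0;
      t += h;
      if (M > 1.0 - 1e-12) { saturated = true; break; }
    }
    out[i] = M;
  }
  return out;
}
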