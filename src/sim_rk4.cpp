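// Fixed-step RK4 core for the coupled FM/FFM energy-balance ODEs.
// Schedules enter as segments with constant EI and an activity coefficient
// lambda(t) = lam_a + lam_b * exp(-(t - lam_tref)/tau) on each segment.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  double rho_FM, rho_FFM, gamma_FM, gamma_FFM, eta_FM, eta_FFM,
         beta, K, alpha_c, alpha_d, alpha_k;
};

// dFM/dt from the closed-form solution of the implicit EE system; returns
// false if FM leaves the measured partition-function domain.
static inline bool deriv(double t, double FM, double FFM, double EI,
                         double dEI, double lam_a, double lam_b,
                         double lam_tref, double tau, const Pars& P,
                         double* dFM, double* dFFM) {
  if (FM < 0.1 || FM > 60.0 || FFM <= 0.0) return false;
  double A = P.alpha_c + P.alpha_d * std::exp(P.alpha_k * FM);
  double lam = lam_a + lam_b * std::exp(-(t - lam_tref) / tau);
  double M = P.K + P.gamma_FFM * FFM + P.gamma_FM * FM + lam * (FM + FFM)
             + P.beta * dEI;
  double den = P.rho_FM + A * P.rho_FFM + P.eta_FM + A * P.eta_FFM;
  *dFM = (EI - M) / den;
  *dFFM = A * (*dFM);
  return true;
}

// [[Rcpp::export(name = "sim_rk4")]]
NumericMatrix sim_rk4(double FM0, double FFM0,
                      NumericVector t0, NumericVector t1,
                      NumericVector EI, NumericVector dEI,
                      NumericVector lam_a, NumericVector lam_b,
                      NumericVector lam_tref, double tau,
                      List pars, double dt) {
  Pars P;
  P.rho_FM = pars["rho_FM"];   P.rho_FFM = pars["rho_FFM"];
  P.gamma_FM = pars["gamma_FM"]; P.gamma_FFM = pars["gamma_FFM"];
  P.eta_FM = pars["eta_FM"];   P.eta_FFM = pars["eta_FFM"];
  P.beta = pars["beta"];       P.K = pars["K"];
  P.alpha_c = pars["alpha_c"]; P.alpha_d = pars["alpha_d"];
  P.alpha_k = pars["alpha_k"];

  int nseg = t0.size();
  int total = 1;
  std::vector<int> nsteps(nseg);
  for (int s = 0; s < nseg; ++s) {
    nsteps[s] = (int)std::ceil((t1[s] - t0[s]) / dt - 1e-12);
    if (nsteps[s] < 1) nsteps[s] = 1;
    total += nsteps[s];
  }
  NumericMatrix out(total, 3);
  double FM = FM0, FFM = FFM0;
  int row = 0;
  out(row, 0) = t0[0]; out(row, 1) = FM; out(row, 2) = FFM; ++row;

  double k1FM, k1FF, k2FM, k2FF, k3FM, k3FF, k4FM, k4FF;
  for (int s = 0; s < nseg; ++s) {
    double h = (t1[s] - t0[s]) / nsteps[s];
    double t = t0[s];
    for (int i = 0; i < nsteps[s]; ++i) {
      bool ok =
        deriv(t, FM, FFM, EI[s], dEI[s], lam_a[s], lam_b[s], lam_tref[s],
              tau, P, &k1FM, &k1FF) &&
        deriv(t + h / 2, FM + h / 2 * k1FM, FFM + h / 2 * k1FF, EI[s],
              dEI[s], lam_a[s], lam_b[s], lam_tref[s], tau, P, &k2FM, &k2FF) &&
        deriv(t + h / 2, FM + h / 2 * k2FM, FFM + h / 2 * k2FF, EI[s],
              dEI[s], lam_a[s], lam_b[s], lam_tref[s], tau, P, &k3FM, &k3FF) &&
        deriv(t + h, FM + h * k3FM, FFM + h * k3FF, EI[s], dEI[s],
              lam_a[s], lam_b[s], lam_tref[s], tau, P, &k4FM, &k4FF);
      if (!ok) {
        for (int r = row; r < total; ++r)
          out(r, 0) = out(r, 1) = out(r, 2) = NA_REAL;
        return out;
      }
      FM += h / 6 * (k1FM + 2 * k2FM + 2 * k3FM + k4FM);
      FFM += h / 6 * (k1FF + 2 * k2FF + 2 * k3FF + k4FF);
      t = t0[s] + (i + 1) * h;
      out(row, 0) = t; out(row, 1) = FM; out(row, 2) = FFM; ++row;
    }
  }
  return out;
}
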