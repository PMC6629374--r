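#include <Rcpp.h>
#include <cmath>

// Hodgkin-Huxley rate expressions for the VIP-IN model.  Voltages in mV,
// rates in 1/ms.  alpha_m and alpha_n have removable singularities at
// V = -38 and V = -55; the series limit is used within 1e-6 mV.

static inline double alpha_m(double v) {
  double x = v + 38.0;
  if (std::fabs(x) < 1e-6) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_m(double v) {
  return 4.0 * std::exp(-(v + 65.0) / 17.0);
}
static inline double alpha_h(double v) {
  return 0.05 * std::exp(-(v + 55.0) / 20.0);
}
static inline double beta_h(double v) {
  return 1.0 / (std::exp(-(v + 35.0) / 10.0) + 1.0);
}
static inline double alpha_n(double v) {
  double x = v + 55.0;
  if (std::fabs(x) < 1e-6) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_n(double v) {
  return 0.125 * std::exp(-(v + 65.0) / 80.0);
}
static inline double s_inf(double v) {
  return 1.0 / (1.0 + std::exp(-(v + 35.0) / 5.0));
}

//' @noRd
// [[Rcpp::export(name = ".hh_rates_cpp")]]
Rcpp::List hh_rates_cpp(Rcpp::NumericVector v) {
  int n = v.size();
  Rcpp::NumericVector am(n), bm(n), ah(n), bh(n), an(n), bn(n), si(n);
  for (int i = 0; i < n; ++i) {
    am[i] = alpha_m(v[i]); bm[i] = beta_m(v[i]);
    ah[i] = alpha_h(v[i]); bh[i] = beta_h(v[i]);
    an[i] = alpha_n(v[i]); bn[i] = beta_n(v[i]);
    si[i] = s_inf(v[i]);
  }
  return Rcpp::List::create(
    Rcpp::Named("alpha_m") = am, Rcpp::Named("beta_m") = bm,
    Rcpp::Named("alpha_h") = ah, Rcpp::Named("beta_h") = bh,
    Rcpp::Named("alpha_n") = an, Rcpp::Named("beta_n") = bn,
    Rcpp::Named("s_inf") = si);
}

// Forward-Euler integration of
//   c_m dV/dt = g_leak (E_l - V) + m^3 h g_Na (E_Na - V)
//             + n^p g_KDR (E_K - V) + s g_KS (E_K - V) + (I_inj + I_noise)/A
// with conductance densities in mS/cm^2, c_m in uF/cm^2, V in mV, t in ms,
// injected current in pA over membrane area `area` (cm^2).  Noise (when on)
// is a per-step Gaussian draw from R's RNG, sd = noise_sd pA, clipped to
// +/- noise_clip pA, injected at every step including zero-current padding.
//
//' @noRd
// [[Rcpp::export(name = ".hh_euler_cpp")]]
Rcpp::List hh_euler_cpp(Rcpp::NumericVector i_inj, double dt,
                        double g_leak, double g_na, double g_kdr, double g_ks,
                        double e_leak, double e_na, double e_k,
                        double c_m, double area, double tau_s,
                        double kdr_exponent,
                        double v0, double m0, double h0, double n0, double s0,
                        bool noise, double noise_sd, double noise_clip,
                        bool record_gating) {
  const int nstep = i_inj.size();
  Rcpp::NumericVector v_out(nstep);
  Rcpp::NumericVector m_out(record_gating ? nstep : 0),
                      h_out(record_gating ? nstep : 0),
                      n_out(record_gating ? nstep : 0),
                      s_out(record_gating ? nstep : 0);
  // pA -> uA/cm^2 for a membrane of `area` cm^2
  const double i_scale = 1e-6 / area;

  double v = v0, m = m0, h = h0, n = n0, s = s0;
  for (int k = 0; k < nstep; ++k) {
    v_out[k] = v;
    if (record_gating) { m_out[k] = m; h_out[k] = h; n_out[k] = n; s_out[k] = s; }

    double i_pA = i_inj[k];
    if (noise) {
      double eta = R::rnorm(0.0, noise_sd);
      if (eta > noise_clip) eta = noise_clip;
      if (eta < -noise_clip) eta = -noise_clip;
      i_pA += eta;
    }

    double np = (kdr_exponent == 3.0) ? n * n * n : std::pow(n, kdr_exponent);
    double dv = (g_leak * (e_leak - v)
                 + m * m * m * h * g_na * (e_na - v)
                 + np * g_kdr * (e_k - v)
                 + s * g_ks * (e_k - v)
                 + i_pA * i_scale) / c_m;

    double am = alpha_m(v), bm = beta_m(v);
    double ah = alpha_h(v), bh = beta_h(v);
    double an = alpha_n(v), bn = beta_n(v);

    v += dt * dv;
    m += dt * (am * (1.0 - m) - bm * m);
    h += dt * (ah * (1.0 - h) - bh * h);
    n += dt * (an * (1.0 - n) - bn * n);
    s += dt * (s_inf(v_out[k]) - s) / tau_s;

    // guard: at deep hyperpolarization (V < ~-120 mV) tau_m drops below
    // the step and the explicit update overshoots [0,1]; the clamped
    // value is the correct stiff limit there
    if (m < 0.0) m = 0.0; else if (m > 1.0) m = 1.0;
    if (h < 0.0) h = 0.0; else if (h > 1.0) h = 1.0;
    if (n < 0.0) n = 0.0; else if (n > 1.0) n = 1.0;
    if (s < 0.0) s = 0.0; else if (s > 1.0) s = 1.0;

    if (!std::isfinite(v)) {
      Rcpp::stop("integration blew up (non-finite V) at step %d (t = %.4f ms)",
                 k + 1, (k + 1) * dt);
    }
  }

  if (record_gating) {
    return Rcpp::List::create(
      Rcpp::Named("v") = v_out, Rcpp::Named("m") = m_out,
      Rcpp::Named("h") = h_out, Rcpp::Named("n") = n_out,
      Rcpp::Named("s") = s_out);
  }
  return Rcpp::List::create(Rcpp::Named("v") = v_out);
}
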