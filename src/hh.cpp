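#include <Rcpp.h>
using namespace Rcpp;

// Parameter packing (see pack_params() on the R side):
// 0 c_m  1 g_na  2 g_kd  3 g_a  4 g_l  5 e_na  6 e_k  7 e_l  8 v_t
// 9 a_vhalf  10 a_k  11 a_tau  12 b_vhalf  13 b_k  14 b_tau
// 15 g_m  16 p_tau_max  17 p_vhalf

// x / (exp(x / y) - 1) with the removable singularity at x = 0 filled in.
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

struct Gates {
  double am, bm, ah, bh, an, bn; // Na / Kd rate constants (1/ms)
  double ainf, binf;             // A-type steady states
  double pinf, ptau;             // M-type (adaptation) gate
};

// Traub-Miles style rate functions, voltage-shifted by v_t so the spike
// threshold lands in the -35..-25 mV range typical of immature human
// neurons; A-type gates are Boltzmann steady states with fixed taus; the
// slow M-type gate (spike-frequency adaptation) follows the standard
// minimal form with a bell-shaped tau capped at p_tau_max.
static inline Gates rates(double v, const double* p) {
  Gates g;
  double u = v - p[8];
  g.am = 0.32 * vtrap(13.0 - u, 4.0);
  g.bm = 0.28 * vtrap(u - 40.0, 5.0);
  g.ah = 0.128 * std::exp((17.0 - u) / 18.0);
  g.bh = 4.0 / (1.0 + std::exp((40.0 - u) / 5.0));
  g.an = 0.032 * vtrap(15.0 - u, 5.0);
  g.bn = 0.5 * std::exp((10.0 - u) / 40.0);
  g.ainf = 1.0 / (1.0 + std::exp(-(v - p[9]) / p[10]));
  g.binf = 1.0 / (1.0 + std::exp((v - p[12]) / p[13]));
  g.pinf = 1.0 / (1.0 + std::exp(-(v - p[17]) / 10.0));
  g.ptau = p[16] / (3.3 * std::exp((v - p[17]) / 20.0) +
                    std::exp(-(v - p[17]) / 20.0));
  return g;
}

// dy/dt for state y = (V, m, h, n, a, b, p); i_ext in pA, t in ms.
static inline void deriv(const double* y, double i_ext, const double* p,
                         double* dy) {
  Gates g = rates(y[0], p);
  double ina = p[1] * y[1] * y[1] * y[1] * y[2] * (y[0] - p[5]);
  double ikd = p[2] * y[3] * y[3] * y[3] * y[3] * (y[0] - p[6]);
  double ia  = p[3] * y[4] * y[5] * (y[0] - p[6]);
  double im  = p[15] * y[6] * (y[0] - p[6]);
  double il  = p[4] * (y[0] - p[7]);
  dy[0] = (-ina - ikd - ia - im - il + i_ext) / p[0]; // pF, pA, mV, ms
  dy[1] = g.am * (1.0 - y[1]) - g.bm * y[1];
  dy[2] = g.ah * (1.0 - y[2]) - g.bh * y[2];
  dy[3] = g.an * (1.0 - y[3]) - g.bn * y[3];
  dy[4] = (g.ainf - y[4]) / p[11];
  dy[5] = (g.binf - y[5]) / p[14];
  dy[6] = (g.pinf - y[6]) / g.ptau;
}

// [[Rcpp::export]]
NumericVector hh_steady_state(double v, NumericVector params) {
  const double* p = params.begin();
  Gates g = rates(v, p);
  NumericVector s(7);
  s[0] = v;
  s[1] = g.am / (g.am + g.bm);
  s[2] = g.ah / (g.ah + g.bh);
  s[3] = g.an / (g.an + g.bn);
  s[4] = g.ainf;
  s[5] = g.binf;
  s[6] = g.pinf;
  return s;
}

// Gate steady states and time constants at a fixed potential, one row per
// voltage. Taus in ms. Used by the analytic voltage-clamp solution.
// [[Rcpp::export]]
NumericMatrix hh_gate_table(NumericVector v, NumericVector params) {
  const double* p = params.begin();
  NumericMatrix out(v.size(), 12);
  for (int i = 0; i < v.size(); ++i) {
    Gates g = rates(v[i], p);
    out(i, 0) = g.am / (g.am + g.bm);
    out(i, 1) = g.ah / (g.ah + g.bh);
    out(i, 2) = g.an / (g.an + g.bn);
    out(i, 3) = g.ainf;
    out(i, 4) = g.binf;
    out(i, 5) = g.pinf;
    out(i, 6) = 1.0 / (g.am + g.bm);
    out(i, 7) = 1.0 / (g.ah + g.bh);
    out(i, 8) = 1.0 / (g.an + g.bn);
    out(i, 9) = p[11];
    out(i, 10) = p[14];
    out(i, 11) = g.ptau;
  }
  colnames(out) = CharacterVector::create(
    "m_inf", "h_inf", "n_inf", "a_inf", "b_inf", "p_inf",
    "tau_m", "tau_h", "tau_n", "tau_a", "tau_b", "tau_p");
  return out;
}

// Fixed-step RK4 integration of the current-clamp model. i_inj gives the
// injected current (pA) per integration step; noise (pA, may be empty) is
// held constant within each step. Every `stride`-th state is recorded,
// starting with the initial state, so the output matches an acquisition
// rate of 1/(stride*dt).
// [[Rcpp::export]]
List hh_integrate_cc(NumericVector params, NumericVector state0, double dt,
                     NumericVector i_inj, NumericVector noise, int stride) {
  const double* p = params.begin();
  int n_steps = i_inj.size();
  bool has_noise = noise.size() > 0;
  if (has_noise && noise.size() != n_steps)
    stop("noise must be empty or match i_inj length");
  double y[7], k1[7], k2[7], k3[7], k4[7], yt[7];
  for (int j = 0; j < 7; ++j) y[j] = state0[j];
  int n_out = n_steps / stride;
  NumericVector v_out(n_out);
  int rec = 0;
  for (int i = 0; i < n_steps; ++i) {
    if (i % stride == 0 && rec < n_out) v_out[rec++] = y[0];
    double i_ext = i_inj[i] + (has_noise ? noise[i] : 0.0);
    deriv(y, i_ext, p, k1);
    for (int j = 0; j < 7; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
    deriv(yt, i_ext, p, k2);
    for (int j = 0; j < 7; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
    deriv(yt, i_ext, p, k3);
    for (int j = 0; j < 7; ++j) yt[j] = y[j] + dt * k3[j];
    deriv(yt, i_ext, p, k4);
    for (int j = 0; j < 7; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
  }
  NumericVector state(7);
  for (int j = 0; j < 7; ++j) state[j] = y[j];
  return List::create(_["v"] = v_out, _["state"] = state);
}
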