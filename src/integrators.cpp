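#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step classical RK4 cores for the PD model and its linearized
// circuit.  Parameter packing is done on the R side (see R/integrator.R);
// the kinetics here must stay in lockstep with the R reference
// implementation in R/model.R, which the test suite checks step-by-step.

// parameter vector layout (index):
//  0 C, 1 gL, 2 EL, 3 gh, 4 Eh, 5 gT, 6 gS, 7 ECa, 8 gK, 9 EK,
// 10 F, 11 tauCa, 12 C0, 13 Kd,
// then 5 gates x 6 entries (half, slope, tau_base, tau_amp, tau_half,
// tau_slope) in the order m_h, m_CaT, h_CaT, m_CaS, m_KCa.
static const int GATE0 = 14;

static inline double ginf(const double *k, double V) {
  return 1.0 / (1.0 + std::exp((V - k[0]) / k[1]));
}
static inline double gtau(const double *k, double V) {
  return k[2] + k[3] / (1.0 + std::exp((V - k[4]) / k[5]));
}

// state: 0 V, 1 m_h, 2 m_CaT, 3 h_CaT, 4 m_CaS, 5 m_KCa, 6 Ca
static void pd_rhs(const double *y, double Iinp, const double *p, double *dy) {
  const double V = y[0], Ca = y[6];
  const double Ih   = p[3] * y[1] * (V - p[4]);
  const double ICaT = p[5] * y[2] * y[2] * y[2] * y[3] * (V - p[7]);
  const double ICaS = p[6] * y[4] * y[4] * y[4] * (V - p[7]);
  const double IKCa = p[8] * y[5] * y[5] * y[5] * y[5] * (V - p[9]);
  const double Ileak = p[1] * (V - p[2]);
  dy[0] = (-Ileak - Ih - ICaT - ICaS - IKCa + Iinp) / p[0];
  for (int g = 0; g < 5; ++g) {
    const double *k = p + GATE0 + 6 * g;
    double xi = ginf(k, V);
    if (g == 4) xi *= Ca / (Ca + p[13]);     // KCa calcium factor
    dy[1 + g] = (xi - y[1 + g]) / gtau(k, V);
  }
  dy[6] = (-p[10] * (ICaT + ICaS) - Ca + p[12]) / p[11];
}

// [[Rcpp::export]]
NumericMatrix rk4_pd_cpp(NumericVector y0, NumericVector I, double dt,
                         NumericVector par) {
  const int n = I.size(), ns = 7;
  if (y0.size() != ns) stop("state must have 7 elements");
  NumericMatrix out(n, ns);
  double y[7], k1[7], k2[7], k3[7], k4[7], tmp[7];
  const double *p = REAL(par);
  for (int j = 0; j < ns; ++j) { y[j] = y0[j]; out(0, j) = y[j]; }
  for (int i = 0; i < n - 1; ++i) {
    const double Ia = I[i], Ib = I[i + 1], Im = 0.5 * (Ia + Ib);
    pd_rhs(y, Ia, p, k1);
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    pd_rhs(tmp, Im, p, k2);
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    pd_rhs(tmp, Im, p, k3);
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + dt * k3[j];
    pd_rhs(tmp, Ib, p, k4);
    for (int j = 0; j < ns; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (!std::isfinite(y[0]))
      stop("integration blew up at t = %f ms", (i + 1) * dt);
    for (int j = 0; j < ns; ++j) out(i + 1, j) = y[j];
  }
  return out;
}

// Linearized circuit: state v plus one current per RL branch.
//   C dv/dt = -G v - sum(Iy) + Iinp ;  Ly dIy/dt = v - Ry Iy
// (v in mV, currents nA, C nF, G uS, R MOhm, L MOhm*ms)
// [[Rcpp::export]]
NumericMatrix rk4_linear_cpp(NumericVector Rb, NumericVector Lb, double C,
                             double G, NumericVector I, double dt) {
  const int nb = Rb.size(), ns = nb + 1, n = I.size();
  if (Lb.size() != nb) stop("R and L must have equal length");
  std::vector<double> y(ns, 0.0), k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  NumericMatrix out(n, ns);
  auto rhs = [&](const std::vector<double> &s, double Iinp,
                 std::vector<double> &d) {
    double sumI = 0.0;
    for (int b = 0; b < nb; ++b) sumI += s[1 + b];
    d[0] = (-G * s[0] - sumI + Iinp) / C;
    for (int b = 0; b < nb; ++b)
      d[1 + b] = (s[0] - Rb[b] * s[1 + b]) / Lb[b];
  };
  for (int i = 0; i < n - 1; ++i) {
    const double Ia = I[i], Ib = I[i + 1], Im = 0.5 * (Ia + Ib);
    rhs(y, Ia, k1);
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    rhs(tmp, Im, k2);
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    rhs(tmp, Im, k3);
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + dt * k3[j];
    rhs(tmp, Ib, k4);
    for (int j = 0; j < ns; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (!std::isfinite(y[0]))
      stop("linear-circuit integration blew up at t = %f ms", (i + 1) * dt);
    for (int j = 0; j < ns; ++j) out(i + 1, j) = y[j];
  }
  return out;
}
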