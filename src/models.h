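#ifndef VAGALFIB_MODELS_H
#define VAGALFIB_MODELS_H

#include <cmath>
#include <cstring>
#include <vector>
#include <stdexcept>

// ---------------------------------------------------------------------------
// Frozen constants of the ACh-activated potassium current (single source of
// truth).  I_KACh = dose(ACh) * rect(Vm) * (Vm - EK), with a Hill-type dose
// term saturating at 10 and an inward-rectification term.  ACh in uM, V in mV,
// result in pA/pF.
// ---------------------------------------------------------------------------
namespace ikach {
constexpr double DOSE_MAX   = 10.0;
constexpr double DOSE_HALF  = 9.14;
constexpr double DOSE_EXP   = 0.478;
constexpr double RECT_OFF   = 0.05;
constexpr double RECT_AMP   = 5.0;
constexpr double RECT_VMID  = -85.0;
constexpr double RECT_SLOPE = 5.0;

inline double dose_term(double ach) {
  if (ach <= 0.0) return 0.0;
  return DOSE_MAX / (1.0 + DOSE_HALF / std::pow(ach, DOSE_EXP));
}
inline double rect_term(double v) {
  return RECT_OFF + RECT_AMP / (1.0 + std::exp((v - RECT_VMID) / RECT_SLOPE));
}
inline double current(double v, double ach, double ek) {
  if (ach <= 0.0) return 0.0;
  return dose_term(ach) * rect_term(v) * (v - ek);
}
} // namespace ikach

// ---------------------------------------------------------------------------
// Courtemanche-Ramirez-Nattel human atrial myocyte (1998 formulation).
// State layout (21 doubles per node):
//   0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
//   10 d, 11 f, 12 fca, 13 u, 14 v, 15 w,
//   16 Nai, 17 Ki, 18 Cai, 19 Caup, 20 Carel
// ---------------------------------------------------------------------------
namespace crn {

constexpr int NSTATE = 21;

constexpr double Rgas = 8.3143;     // J/(mol K)
constexpr double Temp = 310.0;      // K
constexpr double Frdy = 96.4867;    // C/mmol
constexpr double RTF  = Rgas * Temp / Frdy;  // mV

constexpr double Vi   = 13668.0;    // um^3
constexpr double Vup  = 1109.52;
constexpr double Vrel = 96.48;

constexpr double Ko  = 5.4;   // mM
constexpr double Nao = 140.0;
constexpr double Cao = 1.8;

constexpr double KQ10 = 3.0;

constexpr double Km_Na_i = 10.0, Km_K_o = 1.5;
constexpr double K_mNa = 87.5, K_mCa = 1.38, K_sat = 0.1, gama = 0.35;
constexpr double Ca_up_max = 15.0, K_up = 0.00092;
constexpr double CMDN_max = 0.05, TRPN_max = 0.07, CSQN_max = 10.0;
constexpr double Km_CMDN = 0.00238, Km_TRPN = 0.0005, Km_CSQN = 0.8;
constexpr double tau_tr = 180.0, tau_fca = 2.0, tau_u = 8.0;

struct Params {
  double Cm;         // pF (100)
  double gNa;        // nS/pF
  double gK1;
  double gto;
  double gKr;
  double gKs;
  double gCaL;
  double gKur_sf;    // scale factor on the voltage-dependent gKur(V)
  double gbCa;
  double gbNa;
  double ipca_max;
  double inak_max;
  double inaca_max;
  double krel;
  double iup_max;
  bool   kach;       // I_KACh present in this cell
};

inline Params default_params() {
  Params p;
  p.Cm = 100.0;
  p.gNa = 7.8;
  p.gK1 = 0.09;
  p.gto = 0.1652;
  p.gKr = 0.029411765;
  p.gKs = 0.12941176;
  p.gCaL = 0.12375;
  p.gKur_sf = 1.0;
  p.gbCa = 0.001131;
  p.gbNa = 0.0006744375;
  p.ipca_max = 0.275;
  p.inak_max = 0.59933874;
  p.inaca_max = 1600.0;
  p.krel = 30.0;
  p.iup_max = 0.005;
  p.kach = false;
  return p;
}

// Original published initial conditions (quiescent model).
inline void initial_state(double* y) {
  const double y0[NSTATE] = {
    -81.18,      // V
    2.908e-3,    // m
    9.649e-1,    // h
    9.775e-1,    // j
    3.043e-2,    // oa
    9.992e-1,    // oi
    4.966e-3,    // ua
    9.986e-1,    // ui
    3.296e-5,    // xr
    1.869e-2,    // xs
    1.367e-4,    // d
    9.996e-1,    // f
    7.755e-1,    // fca
    0.0,         // u
    1.0,         // v
    9.992e-1,    // w
    1.117e1,     // Nai
    1.390e2,     // Ki
    1.013e-4,    // Cai
    1.488,       // Caup
    1.488        // Carel
  };
  std::memcpy(y, y0, sizeof(y0));
}

// Voltage-dependent quantities needed per step: gate targets + Rush-Larsen
// factors (exp(-dt/tau)) and auxiliary current factors.
struct VDep {
  double m_inf, m_rl, h_inf, h_rl, j_inf, j_rl;
  double oa_inf, oa_rl, oi_inf, oi_rl, ua_inf, ua_rl, ui_inf, ui_rl;
  double xr_inf, xr_rl, xs_inf, xs_rl, d_inf, d_rl, f_inf, f_rl, w_inf, w_rl;
  double k1_rect;   // 1/(1+exp(0.07(V+80)))
  double gkur;      // 0.005 + 0.05/(1+exp(-(V-15)/13))
  double kr_rect;   // 1/(1+exp((V+15)/22.4))
  double fnak;
  double e_gfv;     // exp(gamma F V/RT)
  double e_g1fv;    // exp((gamma-1) F V/RT)
  double kach_rect; // rectification factor of I_KACh
};

inline double safe_ratio(double num, double den, double lim) {
  return std::fabs(den) < 1e-10 ? lim : num / den;
}

inline void vdep_exact(double V, double dt, VDep& o) {
  double a, b, tau;

  a = std::fabs(V + 47.13) < 1e-10 ? 3.2
      : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  b = 0.08 * std::exp(-V / 11.0);
  o.m_inf = a / (a + b); o.m_rl = std::exp(-dt * (a + b));

  if (V >= -40.0) {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.135 * std::exp(-(V + 80.0) / 6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  }
  o.h_inf = a / (a + b); o.h_rl = std::exp(-dt * (a + b));

  if (V >= -40.0) {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
        * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  o.j_inf = a / (a + b); o.j_rl = std::exp(-dt * (a + b));

  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  tau = 1.0 / ((a + b) * KQ10);
  o.oa_inf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  o.oa_rl = std::exp(-dt / tau);
  o.ua_inf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  o.ua_rl = o.oa_rl;   // same alpha/beta as oa

  a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  tau = 1.0 / ((a + b) * KQ10);
  o.oi_inf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  o.oi_rl = std::exp(-dt / tau);

  a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  b = std::exp((V - 158.0) / 16.0);
  tau = 1.0 / ((a + b) * KQ10);
  o.ui_inf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  o.ui_rl = std::exp(-dt / tau);

  a = safe_ratio(0.0003 * (V + 14.1), 1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
  b = safe_ratio(7.3898e-5 * (V - 3.3328),
                 std::exp((V - 3.3328) / 5.1237) - 1.0, 3.7862e-4);
  o.xr_inf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  o.xr_rl = std::exp(-dt * (a + b));

  a = safe_ratio(4e-5 * (V - 19.9), 1.0 - std::exp(-(V - 19.9) / 17.0), 6.8e-4);
  b = safe_ratio(3.5e-5 * (V - 19.9), std::exp((V - 19.9) / 9.0) - 1.0, 3.15e-4);
  o.xs_inf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  o.xs_rl = std::exp(-dt * 2.0 * (a + b));   // tau_xs = 0.5/(a+b)

  {
    double e = std::exp(-(V + 10.0) / 6.24);
    tau = std::fabs(V + 10.0) < 1e-10
          ? 4.579 / (1.0 + e)
          : (1.0 - e) / (0.035 * (V + 10.0) * (1.0 + e));
  }
  o.d_inf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  o.d_rl = std::exp(-dt / tau);

  tau = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  o.f_inf = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  o.f_rl = std::exp(-dt / tau);

  {
    double e = std::exp(-(V - 7.9) / 5.0);
    tau = std::fabs(V - 7.9) < 1e-10
          ? 6.0 * 0.2 / 1.3
          : 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (V - 7.9));
  }
  o.w_inf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  o.w_rl = std::exp(-dt / tau);

  o.k1_rect = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
  o.gkur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  o.kr_rect = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));

  double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  o.fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF)
                  + 0.0365 * sigma * std::exp(-V / RTF));

  o.e_gfv  = std::exp(gama * V / RTF);
  o.e_g1fv = std::exp((gama - 1.0) * V / RTF);
  o.kach_rect = ikach::rect_term(V);
}

// Lookup table over membrane potential for the VDep block; linear
// interpolation between entries (0.05 mV grid).  Stored single-precision:
// the tabulated quantities are O(1) and the interpolation error dominates
// the storage rounding.  Rebuilt for each (dt) used by a run.
struct LUT {
  static constexpr int NF = sizeof(VDep) / sizeof(double);
  double vmin, vmax, inv_dv;
  int n;
  std::vector<float> tab;   // n x NF
  void build(double dt, double vmin_ = -120.0, double vmax_ = 70.0,
             double dv = 0.05) {
    vmin = vmin_; vmax = vmax_; inv_dv = 1.0 / dv;
    n = static_cast<int>((vmax - vmin) / dv) + 2;
    tab.resize(static_cast<size_t>(n) * NF);
    VDep o;
    for (int i = 0; i < n; ++i) {
      vdep_exact(vmin + i * dv, dt, o);
      const double* src = reinterpret_cast<const double*>(&o);
      for (int k = 0; k < NF; ++k) tab[(size_t)i * NF + k] = (float)src[k];
    }
  }
  inline void eval(double V, VDep& o) const {
    double x = (V - vmin) * inv_dv;
    if (x < 0.0) x = 0.0;
    if (x > n - 2) x = n - 2;
    int i = static_cast<int>(x);
    const float w = static_cast<float>(x - i);
    const float* __restrict a = &tab[(size_t)i * NF];
    const float* __restrict b = a + NF;
    float buf[NF];
    for (int k = 0; k < NF; ++k) buf[k] = a[k] + w * (b[k] - a[k]);
    double* __restrict out = reinterpret_cast<double*>(&o);
    for (int k = 0; k < NF; ++k) out[k] = buf[k];
  }
};

// Advance one myocyte node by dt.  Updates gates (Rush-Larsen) and
// concentrations (forward Euler); does NOT update V.  Returns the total ionic
// current in pA/pF (positive = outward), so the caller performs
//   V += dt * (-iion + istim) + diffusion.
// `nernst` caches (ENa, EK, ECa); they drift with the slow intracellular
// concentrations and are recomputed only when `refresh` is set (every 16
// steps = 0.32 ms at the default dt).
inline double node_step(double* y, const Params& p, double ach, double dt,
                        const VDep& vd, double rl_fca, double rl_u,
                        double* nernst, bool refresh) {
  const double V = y[0];
  const double Nai = y[16], Ki = y[17], Cai = y[18], Caup = y[19], Carel = y[20];
  const double Cm = p.Cm;

  if (refresh) {
    nernst[0] = RTF * std::log(Nao / Nai);
    nernst[1] = RTF * std::log(Ko / Ki);
    nernst[2] = 0.5 * RTF * std::log(Cao / Cai);
    const double knai = Km_Na_i / Nai;           // slow like the Nernst terms
    nernst[3] = 1.0 / (1.0 + knai * std::sqrt(knai));
  }
  const double ENa = nernst[0], EK = nernst[1], ECa = nernst[2];

  // currents in pA
  const double iNa  = Cm * p.gNa * y[1] * y[1] * y[1] * y[2] * y[3] * (V - ENa);
  const double iK1  = Cm * p.gK1 * (V - EK) * vd.k1_rect;
  const double ito  = Cm * p.gto * y[4] * y[4] * y[4] * y[5] * (V - EK);
  const double iKur = Cm * p.gKur_sf * vd.gkur * y[6] * y[6] * y[6] * y[7] * (V - EK);
  const double iKr  = Cm * p.gKr * y[8] * (V - EK) * vd.kr_rect;
  const double iKs  = Cm * p.gKs * y[9] * y[9] * (V - EK);
  const double iCaL = Cm * p.gCaL * y[10] * y[11] * y[12] * (V - 65.0);
  const double iNaK = Cm * p.inak_max * vd.fnak * (Ko / (Ko + Km_K_o))
      * nernst[3];
  const double naca_den = (K_mNa * K_mNa * K_mNa + Nao * Nao * Nao)
      * (K_mCa + Cao) * (1.0 + K_sat * vd.e_g1fv);
  const double naca_num = Cm * p.inaca_max
      * (vd.e_gfv * Nai * Nai * Nai * Cao - vd.e_g1fv * Nao * Nao * Nao * Cai);
  const double ibNa = Cm * p.gbNa * (V - ENa);
  const double ibCa = Cm * p.gbCa * (V - ECa);
  double iKACh = 0.0;
  if (p.kach && ach > 0.0)
    iKACh = Cm * ikach::dose_term(ach) * vd.kach_rect * (V - EK);

  // Ca-dependent denominators, inverted in pairs (one division per pair)
  const double dPCa = 0.0005 + Cai;               // sarcolemmal Ca pump
  const double dUp  = Cai + K_up;                 // SERCA uptake
  const double q1 = dPCa * dUp, inv1 = 1.0 / q1;
  const double ipCa = Cm * p.ipca_max * Cai * (inv1 * dUp);
  const double iup  = p.iup_max * Cai * (inv1 * dPCa);
  const double dFca = 0.00035 + Cai;              // fCa gate
  const double dRel = Carel + Km_CSQN;            // CSQN buffering
  const double q2 = dFca * (dRel * dRel), inv2 = 1.0 / q2;
  const double fca_inf = 0.00035 * (inv2 * dRel * dRel);
  const double csqn_fac = 1.0
      / (1.0 + CSQN_max * Km_CSQN * (inv2 * dFca));

  // NCX denominator grouped with the Ca-buffering terms of B2
  const double t1 = (Cai + Km_TRPN) * (Cai + Km_TRPN);
  const double t2 = (Cai + Km_CMDN) * (Cai + Km_CMDN);
  const double q3 = naca_den * (t1 * t2), inv3 = 1.0 / q3;
  const double iNaCa = naca_num * (inv3 * (t1 * t2));
  const double inv_t1t2 = inv3 * naca_den;
  const double B2 = 1.0 + TRPN_max * Km_TRPN * (t2 * inv_t1t2)
      + CMDN_max * Km_CMDN * (t1 * inv_t1t2);

  // SR fluxes (mM/ms)
  const double irel = p.krel * y[13] * y[13] * y[14] * y[15] * (Carel - Cai);
  const double itr  = (Caup - Carel) * (1.0 / tau_tr);
  const double iupleak = p.iup_max * Caup * (1.0 / Ca_up_max);

  // Ca-release trigger; the u/v sigmoids have sub-fF scales, so outside
  // +/-30 they are saturated and the exp can be skipped.
  const double Fn = 1.0e3 * (1.0e-15 * Vrel * irel
      - 1.0e-15 / (2.0 * Frdy) * (0.5 * iCaL - 0.2 * iNaCa));
  const double xu = (Fn - 3.4175e-13) * (1.0 / 1.367e-15);
  const double xv = (Fn - 6.835e-14) * (1.0 / 1.367e-15);
  const double su = xu > 30.0 ? 1.0 : (xu < -30.0 ? 0.0
                    : 1.0 / (1.0 + std::exp(-xu)));
  const double u_inf = su;
  const double v_inf = xv > 30.0 ? 0.0 : (xv < -30.0 ? 1.0
                    : 1.0 - 1.0 / (1.0 + std::exp(-xv)));
  const double tau_v = 1.91 + 2.09 * su;

  // Rush-Larsen gate updates
  y[1]  = vd.m_inf  + (y[1]  - vd.m_inf)  * vd.m_rl;
  y[2]  = vd.h_inf  + (y[2]  - vd.h_inf)  * vd.h_rl;
  y[3]  = vd.j_inf  + (y[3]  - vd.j_inf)  * vd.j_rl;
  y[4]  = vd.oa_inf + (y[4]  - vd.oa_inf) * vd.oa_rl;
  y[5]  = vd.oi_inf + (y[5]  - vd.oi_inf) * vd.oi_rl;
  y[6]  = vd.ua_inf + (y[6]  - vd.ua_inf) * vd.ua_rl;
  y[7]  = vd.ui_inf + (y[7]  - vd.ui_inf) * vd.ui_rl;
  y[8]  = vd.xr_inf + (y[8]  - vd.xr_inf) * vd.xr_rl;
  y[9]  = vd.xs_inf + (y[9]  - vd.xs_inf) * vd.xs_rl;
  y[10] = vd.d_inf  + (y[10] - vd.d_inf)  * vd.d_rl;
  y[11] = vd.f_inf  + (y[11] - vd.f_inf)  * vd.f_rl;
  y[12] = fca_inf + (y[12] - fca_inf) * rl_fca;
  y[13] = u_inf + (y[13] - u_inf) * rl_u;
  {
    // exp(-dt/tau_v) with dt/tau_v <= ~0.03: 3rd-order expansion is exact to
    // <1e-8 and avoids the only remaining per-step exp
    const double xq = dt / tau_v;
    y[14] = v_inf + (y[14] - v_inf)
        * (1.0 - xq * (1.0 - 0.5 * xq * (1.0 - xq / 3.0)));
  }
  y[15] = vd.w_inf + (y[15] - vd.w_inf) * vd.w_rl;

  // concentrations (forward Euler)
  constexpr double INV_ViF = 1.0 / (Vi * Frdy);
  constexpr double INV_2ViF = 1.0 / (2.0 * Vi * Frdy);
  y[16] += dt * (-3.0 * iNaK - 3.0 * iNaCa - ibNa - iNa) * INV_ViF;
  y[17] += dt * (2.0 * iNaK - iK1 - ito - iKur - iKr - iKs - iKACh) * INV_ViF;
  const double B1 = (2.0 * iNaCa - ipCa - iCaL - ibCa) * INV_2ViF
      + (Vup * (iupleak - iup) + irel * Vrel) * (1.0 / Vi);
  y[18] += dt * B1 / B2;
  y[19] += dt * (iup - iupleak - itr * (Vrel / Vup));
  y[20] += dt * (itr - irel) * csqn_fac;

  return (iNa + iK1 + ito + iKur + iKr + iKs + iCaL + iNaK + iNaCa
          + ibNa + ibCa + ipCa + iKACh) / Cm;
}

} // namespace crn

// ---------------------------------------------------------------------------
// MacCannell active fibroblast.  State layout (4 doubles):
//   0 Vf, 1 r (Kv activation), 2 s (Kv inactivation), 3 Ki_f
// ---------------------------------------------------------------------------
namespace fib {

constexpr int NSTATE = 4;

constexpr double Cm_f   = 6.3;       // pF
constexpr double Vol_f  = 1370.0;    // um^3
constexpr double Ko_f   = 5.4;       // mM (shared with the myocyte bath)
constexpr double Nao_f  = 130.011;
constexpr double Nai_f  = 8.5547;    // fixed
constexpr double g_Kv   = 0.25;      // nS/pF
constexpr double g_K1   = 0.4822;
constexpr double g_bNa  = 0.0095;
constexpr double inak_max = 2.002;   // pA/pF
constexpr double Km_K  = 1.0, Km_Na = 11.0;
constexpr double V_rev = -150.0, B_nak = -200.0;

inline void initial_state(double* y) {
  y[0] = -49.6;     // mV
  y[1] = 0.06;      // r
  y[2] = 0.96;      // s
  y[3] = 129.4349;  // Ki_f
}

// Advance one fibroblast node by dt; i_coupling (pA/pF, positive = outward,
// i.e., it enters the dVf/dt equation with a minus sign like an ionic
// current) stands for gap-junctional load when the node is run in isolation.
// In tissue the coupling enters through the shared diffusion operator and
// i_coupling is zero.  Returns total ionic current in pA/pF.
inline double node_step(double* y, double dt, double i_coupling = 0.0) {
  const double V = y[0], r = y[1], s = y[2], Kif = y[3];
  const double EK  = crn::RTF * std::log(Ko_f / Kif);
  const double ENa = crn::RTF * std::log(Nao_f / Nai_f);

  const double vk = V - EK;
  const double iKv = g_Kv * r * s * vk;
  const double aK1 = 0.1 / (1.0 + std::exp(0.06 * (vk - 200.0)));
  const double bK1 = (3.0 * std::exp(0.0002 * (vk + 100.0)) + std::exp(0.1 * (vk - 10.0)))
      / (1.0 + std::exp(-0.5 * vk));
  const double iK1 = g_K1 * aK1 / (aK1 + bK1) * vk;
  const double iNaK = inak_max * (Ko_f / (Ko_f + Km_K))
      * std::pow(Nai_f, 1.5) / (std::pow(Nai_f, 1.5) + std::pow(Km_Na, 1.5))
      * (V - V_rev) / (V - B_nak);
  const double ibNa = g_bNa * (V - ENa);

  const double r_inf = 1.0 / (1.0 + std::exp(-(V + 20.0) / 11.0));
  const double tau_r = 20.3 + 138.0 * std::exp(-std::pow((V + 20.0) / 25.9, 2));
  const double s_inf = 1.0 / (1.0 + std::exp((V + 23.0) / 7.0));
  const double tau_s = 1574.0 + 5268.0 * std::exp(-std::pow((V + 23.0) / 22.7, 2));

  y[1] = r_inf + (r - r_inf) * std::exp(-dt / tau_r);
  y[2] = s_inf + (s - s_inf) * std::exp(-dt / tau_s);
  y[3] += dt * (-(iK1 + iKv - 2.0 * iNaK) * Cm_f) / (Vol_f * crn::Frdy);

  return iKv + iK1 + iNaK + ibNa + i_coupling;
}

} // namespace fib

#endif
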