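#include <Rcpp.h>
#include "models.h"
using namespace Rcpp;

static crn::Params params_from_list(const List& pl) {
  crn::Params p;
  p.Cm        = as<double>(pl["Cm"]);
  p.gNa       = as<double>(pl["gNa"]);
  p.gK1       = as<double>(pl["gK1"]);
  p.gto       = as<double>(pl["gto"]);
  p.gKr       = as<double>(pl["gKr"]);
  p.gKs       = as<double>(pl["gKs"]);
  p.gCaL      = as<double>(pl["gCaL"]);
  p.gKur_sf   = as<double>(pl["gKur_sf"]);
  p.gbCa      = as<double>(pl["gbCa"]);
  p.gbNa      = as<double>(pl["gbNa"]);
  p.ipca_max  = as<double>(pl["ipca_max"]);
  p.inak_max  = as<double>(pl["inak_max"]);
  p.inaca_max = as<double>(pl["inaca_max"]);
  p.krel      = as<double>(pl["krel"]);
  p.iup_max   = as<double>(pl["iup_max"]);
  p.kach      = as<bool>(pl["kach"]);
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_ikach(NumericVector vm, NumericVector ach, NumericVector ek) {
  R_xlen_t n = std::max(vm.size(), std::max(ach.size(), ek.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = ach[i % ach.size()];
    if (a < 0) stop("negative ACh concentration");
    out[i] = ikach::current(vm[i % vm.size()], a, ek[i % ek.size()]);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_myocyte_initial_state() {
  NumericVector y(crn::NSTATE);
  crn::initial_state(REAL(y));
  return y;
}

static int first_nonfinite(const double* y, int n) {
  for (int k = 0; k < n; ++k)
    if (!std::isfinite(y[k])) return k;
  return -1;
}

// Advance a single myocyte n steps.  istim and ach recycle along the steps.
// [[Rcpp::export]]
List cpp_myocyte_run(NumericVector state, List params, NumericVector istim,
                     NumericVector ach, double dt, int n, double sample_dt) {
  if (state.size() != crn::NSTATE) stop("bad myocyte state length");
  crn::Params p = params_from_list(params);
  std::vector<double> y(state.begin(), state.end());
  crn::LUT lut; lut.build(dt);
  const double rl_fca = std::exp(-dt / crn::tau_fca), rl_u = std::exp(-dt / crn::tau_u);
  crn::VDep vd;
  double nernst[4];

  int stride = sample_dt > 0 ? std::max(1, (int)std::lround(sample_dt / dt)) : 0;
  std::vector<double> tv, vv;
  if (stride > 0) { tv.reserve(n / stride + 2); vv.reserve(n / stride + 2); }

  R_xlen_t ns = istim.size(), na = ach.size();
  for (int i = 0; i < n; ++i) {
    lut.eval(y[0], vd);
    double iion = crn::node_step(y.data(), p, na == 1 ? ach[0] : ach[i % na], dt, vd, rl_fca, rl_u, nernst, (i & 15) == 0);
    y[0] += dt * (-iion + (ns == 1 ? istim[0] : istim[i % ns]));
    if (stride > 0 && (i + 1) % stride == 0) {
      tv.push_back((i + 1) * dt);
      vv.push_back(y[0]);
    }
    if ((i & 1023) == 0 && !std::isfinite(y[0])) break;
  }
  int bad = first_nonfinite(y.data(), crn::NSTATE);
  NumericVector out(y.begin(), y.end());
  out.names() = state.names();
  return List::create(_["state"] = out, _["bad_index"] = bad + 1,
                      _["t"] = tv, _["v"] = vv);
}

// Pace a single myocyte: stimuli of (amp, dur) at onset + k*cl, k = 0,1,...
// Tracks per-beat biomarkers at full dt resolution.
// [[Rcpp::export]]
List cpp_myocyte_pace(NumericVector state, List params, double cl,
                      double duration, double dt, double ach,
                      double stim_amp, double stim_dur, double onset,
                      double sample_dt, double record_from) {
  if (state.size() != crn::NSTATE) stop("bad myocyte state length");
  crn::Params p = params_from_list(params);
  std::vector<double> y(state.begin(), state.end());
  crn::LUT lut; lut.build(dt);
  const double rl_fca = std::exp(-dt / crn::tau_fca), rl_u = std::exp(-dt / crn::tau_u);
  crn::VDep vd;
  double nernst[4];

  long n = (long)std::llround(duration / dt);
  int stride = sample_dt > 0 ? std::max(1, (int)std::lround(sample_dt / dt)) : 0;
  std::vector<double> tv, vv;

  // per-beat tracking
  std::vector<double> b_tup, b_apd, b_rmp, b_dvdt, b_peak;
  double cur_vpre = y[0], cur_dvdtmax = -1e30, cur_tup = -1, cur_peak = -1e30;
  bool in_beat = false, apd_done = true;
  int beat = -1;

  for (long i = 0; i < n; ++i) {
    double t = i * dt;
    double tb = t - onset;
    double istim = 0.0;
    if (tb >= 0) {
      int k = (int)std::floor(tb / cl);
      double phase = tb - k * cl;   // fmod(tb, cl) without fmod (glibc>=2.38)
      if (phase < stim_dur && stim_amp != 0.0) istim = stim_amp;
      if (k > beat) {  // new beat begins at this stimulus onset
        if (in_beat && !apd_done) { b_apd.push_back(NA_REAL); apd_done = true; }
        beat = k;
        cur_vpre = y[0];
        cur_dvdtmax = -1e30; cur_tup = -1; cur_peak = -1e30;
        in_beat = true; apd_done = false;
        b_tup.push_back(NA_REAL); b_apd.push_back(NA_REAL);
        b_rmp.push_back(cur_vpre); b_dvdt.push_back(NA_REAL);
        b_peak.push_back(NA_REAL);
        b_apd.pop_back();  // apd appended at repolarization
      }
    }
    lut.eval(y[0], vd);
    double iion = crn::node_step(y.data(), p, ach, dt, vd, rl_fca, rl_u, nernst, (i & 15) == 0);
    double dvdt_ion = -iion;
    y[0] += dt * (dvdt_ion + istim);
    if (in_beat) {
      if (dvdt_ion > cur_dvdtmax) {
        cur_dvdtmax = dvdt_ion; cur_tup = t;
        b_dvdt.back() = cur_dvdtmax; b_tup.back() = cur_tup;
      }
      if (y[0] > cur_peak) { cur_peak = y[0]; b_peak.back() = cur_peak; }
      if (!apd_done && cur_peak > 0 && cur_tup >= 0 && t > cur_tup + 2.0) {
        double v90 = cur_peak - 0.9 * (cur_peak - cur_vpre);
        if (y[0] <= v90) { b_apd.push_back(t - cur_tup); apd_done = true; }
      }
    }
    if (stride > 0 && t >= record_from && ((i + 1) % stride == 0)) {
      tv.push_back((i + 1) * dt); vv.push_back(y[0]);
    }
    if ((i & 2047) == 0 && !std::isfinite(y[0]))
      stop("membrane potential became non-finite at t = %f ms", t);
  }
  if (in_beat && !apd_done) b_apd.push_back(NA_REAL);

  NumericVector out(y.begin(), y.end());
  out.names() = state.names();
  return List::create(
    _["state"] = out, _["t"] = tv, _["v"] = vv,
    _["beat_t_up"] = b_tup, _["beat_apd90"] = b_apd, _["beat_rmp"] = b_rmp,
    _["beat_dvdt_max"] = b_dvdt, _["beat_peak"] = b_peak);
}

// [[Rcpp::export]]
NumericVector cpp_fibroblast_initial_state() {
  NumericVector y(fib::NSTATE);
  fib::initial_state(REAL(y));
  return y;
}

// Advance a single fibroblast n steps with a (recycled) coupling current.
// [[Rcpp::export]]
List cpp_fibroblast_run(NumericVector state, NumericVector i_coupling,
                        double dt, int n, double sample_dt) {
  if (state.size() != fib::NSTATE) stop("bad fibroblast state length");
  std::vector<double> y(state.begin(), state.end());
  int stride = sample_dt > 0 ? std::max(1, (int)std::lround(sample_dt / dt)) : 0;
  std::vector<double> tv, vv;
  R_xlen_t nc = i_coupling.size();
  for (int i = 0; i < n; ++i) {
    double iion = fib::node_step(y.data(), dt, nc == 1 ? i_coupling[0] : i_coupling[i % nc]);
    y[0] += dt * (-iion);
    if (stride > 0 && (i + 1) % stride == 0) {
      tv.push_back((i + 1) * dt); vv.push_back(y[0]);
    }
  }
  int bad = first_nonfinite(y.data(), fib::NSTATE);
  NumericVector out(y.begin(), y.end());
  out.names() = state.names();
  return List::create(_["state"] = out, _["bad_index"] = bad + 1,
                      _["t"] = tv, _["v"] = vv);
}
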