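#include <Rcpp.h>
#include "models.h"
using namespace Rcpp;

// Anisotropic 2D monodomain solver on a regular grid, explicit operator
// splitting: Rush-Larsen / forward-Euler reaction step plus a 5-point
// finite-difference diffusion step with no-flux boundaries.  Fibers run
// bottom-to-top (the y direction carries the longitudinal diffusivity).
//
// celltype: 0 = myocyte, 1 = fibroblast (length nx*ny, column ix fastest:
//           node index = ix + nx*iy, iy = 0 is the bottom row).
// Dl, Dt_: longitudinal / transverse diffusivity (mm^2/ms); h: spacing (mm).
// Gap-junction rule: myocyte-myocyte weight 1, fibroblast-fibroblast 1/4,
// myocyte-fibroblast 1/n_f where n_f is the myocyte's fibroblast-neighbor
// count.
//
// ach_par: (mean uM, peak-to-peak uM, freq Hz, phase rad, delay ms);
// release nodes follow the waveform, all other nodes see zero ACh.
// stims: matrix with columns (onset ms, duration ms, amplitude pA/pF,
// mask id); stim_masks: list of 1-based node index vectors.

static crn::Params params_from_list2(const List& pl) {
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
  p.inaca_max = as<double>(pl["inaca_max"]);
  p.inak_max  = as<double>(pl["inak_max"]);
  p.krel      = as<double>(pl["krel"]);
  p.iup_max   = as<double>(pl["iup_max"]);
  p.kach      = as<bool>(pl["kach"]);
  return p;
}

// [[Rcpp::export]]
List cpp_tissue_run(IntegerVector celltype, int nx, int ny,
                    double Dl, double Dt_, double h,
                    List params,
                    NumericVector myo_init, NumericVector fb_init,
                    Nullable<NumericMatrix> myo_init_full,
                    Nullable<NumericMatrix> fb_init_full,
                    IntegerVector ach_mask, NumericVector ach_par,
                    NumericMatrix stims, List stim_masks,
                    double duration, double dt,
                    IntegerVector probes, double sample_dt,
                    double snapshot_dt, bool return_state) {
  const int N = nx * ny;
  if (celltype.size() != N) stop("celltype length != nx*ny");
  if (ach_mask.size() != N) stop("ach_mask length != nx*ny");
  crn::Params p = params_from_list2(params);

  // state arrays
  std::vector<double> my(static_cast<size_t>(N) * crn::NSTATE);
  std::vector<double> fb(static_cast<size_t>(N) * fib::NSTATE);
  if (myo_init_full.isNotNull()) {
    NumericMatrix m(myo_init_full);
    if (m.nrow() != crn::NSTATE || m.ncol() != N) stop("bad myo_init_full");
    std::copy(m.begin(), m.end(), my.begin());
  } else {
    if (myo_init.size() != crn::NSTATE) stop("bad myo_init");
    for (int i = 0; i < N; ++i)
      std::copy(myo_init.begin(), myo_init.end(), my.begin() + (size_t)i * crn::NSTATE);
  }
  if (fb_init_full.isNotNull()) {
    NumericMatrix m(fb_init_full);
    if (m.nrow() != fib::NSTATE || m.ncol() != N) stop("bad fb_init_full");
    std::copy(m.begin(), m.end(), fb.begin());
  } else {
    if (fb_init.size() != fib::NSTATE) stop("bad fb_init");
    for (int i = 0; i < N; ++i)
      std::copy(fb_init.begin(), fb_init.end(), fb.begin() + (size_t)i * fib::NSTATE);
  }

  std::vector<double> V(N);
  for (int i = 0; i < N; ++i)
    V[i] = celltype[i] == 0 ? my[(size_t)i * crn::NSTATE] : fb[(size_t)i * fib::NSTATE];

  // edge conductances (units 1/ms after division by h^2)
  const double bx = Dt_ / (h * h), by = Dl / (h * h);
  std::vector<int> nfib(N, 0);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      int i = ix + nx * iy;
      if (celltype[i] != 0) continue;
      if (ix > 0      && celltype[i - 1]  == 1) ++nfib[i];
      if (ix < nx - 1 && celltype[i + 1]  == 1) ++nfib[i];
      if (iy > 0      && celltype[i - nx] == 1) ++nfib[i];
      if (iy < ny - 1 && celltype[i + nx] == 1) ++nfib[i];
    }
  auto edge_w = [&](int a, int b) -> double {
    int ta = celltype[a], tb = celltype[b];
    if (ta == 0 && tb == 0) return 1.0;
    if (ta == 1 && tb == 1) return 0.25;
    int m = ta == 0 ? a : b;
    return 1.0 / std::max(1, nfib[m]);
  };
  std::vector<double> gx((size_t)N, 0.0), gy((size_t)N, 0.0);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      int i = ix + nx * iy;
      if (ix < nx - 1) gx[i] = bx * edge_w(i, i + 1);
      if (iy < ny - 1) gy[i] = by * edge_w(i, i + nx);
    }

  // stimulus bookkeeping
  const int nst = stims.nrow();
  std::vector<double> istim(N, 0.0);
  unsigned long active_sig = 0, prev_sig = 1; // force initial rebuild
  std::vector<std::vector<int>> masks(stim_masks.size());
  for (int k = 0; k < stim_masks.size(); ++k) {
    IntegerVector m = stim_masks[k];
    masks[k].assign(m.begin(), m.end());
    for (int& idx : masks[k]) --idx;   // to 0-based
  }

  const double ach_mean = ach_par[0], ach_delta = ach_par[1];
  const double ach_f = ach_par[2], ach_phase = ach_par[3], ach_delay = ach_par[4];

  crn::LUT lut; lut.build(dt);
  const double rl_fca = std::exp(-dt / crn::tau_fca), rl_u = std::exp(-dt / crn::tau_u);
  crn::VDep vd;

  const long nsteps = (long)std::llround(duration / dt);
  const int pstride = std::max(1, (int)std::lround(sample_dt / dt));
  const int sstride = snapshot_dt > 0 ? std::max(1, (int)std::lround(snapshot_dt / dt)) : 0;
  const int nprobe = probes.size();
  const int nsamp = (int)(nsteps / pstride);
  NumericMatrix ptrace(nsamp, nprobe);
  NumericVector ptime(nsamp);
  const int nsnap = sstride > 0 ? (int)(nsteps / sstride) : 0;
  NumericMatrix snaps(sstride > 0 ? N : 0, nsnap);
  NumericVector snap_t(nsnap);
  int isamp = 0, isnap = 0;

  std::vector<double> lap(N);
  std::vector<double> nernst(static_cast<size_t>(N) * 4);  // ENa, EK, ECa, NaK factor

  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;

    // stimulus field
    active_sig = 0;
    for (int k = 0; k < nst; ++k)
      if (t >= stims(k, 0) && t < stims(k, 0) + stims(k, 1))
        active_sig = active_sig * 131ul + (unsigned long)(k + 1);
    if (active_sig != prev_sig) {
      std::fill(istim.begin(), istim.end(), 0.0);
      for (int k = 0; k < nst; ++k)
        if (t >= stims(k, 0) && t < stims(k, 0) + stims(k, 1)) {
          int mi = (int)stims(k, 3) - 1;
          for (int idx : masks[mi]) istim[idx] += stims(k, 2);
        }
      prev_sig = active_sig;
    }

    const double ach_t = ach_mean + 0.5 * ach_delta *
        std::sin(2.0 * M_PI * ach_f * (t - ach_delay) / 1000.0 + ach_phase);

    // diffusion operator on current V
    std::fill(lap.begin(), lap.end(), 0.0);
    for (int iy = 0; iy < ny; ++iy) {
      const int row = nx * iy;
      for (int ix = 0; ix < nx - 1; ++ix) {
        const int i = row + ix;
        const double fl = gx[i] * (V[i + 1] - V[i]);
        lap[i] += fl; lap[i + 1] -= fl;
      }
    }
    for (int i = 0; i < N - nx; ++i) {
      const double fl = gy[i] * (V[i + nx] - V[i]);
      lap[i] += fl; lap[i + nx] -= fl;
    }

    // reaction step + explicit update
    const bool refresh = (step & 15) == 0;
    for (int i = 0; i < N; ++i) {
      double iion;
      if (celltype[i] == 0) {
        double* y = my.data() + (size_t)i * crn::NSTATE;
        y[0] = V[i];
        lut.eval(V[i], vd);
        iion = crn::node_step(y, p, ach_mask[i] ? ach_t : 0.0, dt, vd, rl_fca, rl_u,
                              nernst.data() + (size_t)i * 4, refresh);
      } else {
        double* y = fb.data() + (size_t)i * fib::NSTATE;
        y[0] = V[i];
        iion = fib::node_step(y, dt);
      }
      V[i] += dt * (-iion + istim[i] + lap[i]);
    }

    if ((step & 63) == 0) {
      double vmax = 0.0;
      for (int i = 0; i < N; ++i) vmax = std::max(vmax, std::fabs(V[i]));
      if (vmax > 200.0 || !std::isfinite(vmax))
        stop("numerical blow-up (|V| > 200 mV) at t = %f ms", t);
      Rcpp::checkUserInterrupt();
    }

    if ((step + 1) % pstride == 0 && isamp < nsamp) {
      for (int q = 0; q < nprobe; ++q) ptrace(isamp, q) = V[probes[q] - 1];
      ptime[isamp] = (step + 1) * dt;
      ++isamp;
    }
    if (sstride > 0 && (step + 1) % sstride == 0 && isnap < nsnap) {
      for (int i = 0; i < N; ++i) snaps(i, isnap) = V[i];
      snap_t[isnap] = (step + 1) * dt;
      ++isnap;
    }
  }

  List out = List::create(
    _["t"] = ptime, _["v"] = ptrace,
    _["snap_t"] = snap_t, _["snapshots"] = snaps);
  if (return_state) {
    for (int i = 0; i < N; ++i) {
      if (celltype[i] == 0) my[(size_t)i * crn::NSTATE] = V[i];
      else fb[(size_t)i * fib::NSTATE] = V[i];
    }
    NumericMatrix ms(crn::NSTATE, N), fs(fib::NSTATE, N);
    std::copy(my.begin(), my.end(), ms.begin());
    std::copy(fb.begin(), fb.end(), fs.begin());
    out["myo_state"] = ms;
    out["fb_state"] = fs;
  }
  NumericVector vfinal(V.begin(), V.end());
  out["v_final"] = vfinal;
  return out;
}
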