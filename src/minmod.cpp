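// Explicit-Euler integrators for the four-variable minimal ionic model
// (membrane potential u + gates v, w, s) in 0D, on a 1D cable and on a
// 2D sheet, monodomain formulation with no-flux (mirror-ghost) boundaries.
//
// All voltage-dependent rate coefficients are functions of u alone, so they
// are tabulated once per run on a fine u-grid and linearly interpolated in
// the inner loop; gate targets are clamped to [0,1] at table-build time so
// gates remain in [0,1] under forward Euler. The exact (untabulated)
// right-hand side is exposed to R separately via ionic_derivatives().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// canonical parameter order; must match atriafit:::mm_par_names in R/params.R
enum ParIdx {
  U_O = 0, U_U, THETA_V, THETA_W, THETA_VMINUS, THETA_O,
  TAU_V1M, TAU_V2M, TAU_VP, TAU_W1M, TAU_W2M, K_WM, U_WM, TAU_WP,
  TAU_FI, TAU_O1, TAU_O2, TAU_SO1, TAU_SO2, K_SO, U_SO,
  TAU_S1, TAU_S2, K_S, U_S, TAU_SI, TAU_WINF, W_INF_STAR, NPAR
};

static const double U_LO = -0.5;  // guard range for u; outside => blow-up
static const double U_HI = 2.0;
static const int NTAB = 25001;    // u-grid resolution 1e-4

// coefficients interleaved per u-grid row: cfi, cso, csi, av, bv, aw, bw,
// as, bs — one lookup touches two adjacent 72-byte rows
struct RateTable {
  double inv_du;
  std::vector<double> tab;  // NTAB x 9
};

static inline double heav(double x) { return x >= 0.0 ? 1.0 : 0.0; }

static RateTable build_table(const double* p) {
  RateTable T;
  const double du = (U_HI - U_LO) / (NTAB - 1);
  T.inv_du = 1.0 / du;
  T.tab.resize((size_t)NTAB * 9);
  for (int i = 0; i < NTAB; ++i) {
    const double u = U_LO + i * du;
    const bool Hv = u >= p[THETA_V];
    const bool Hw = u >= p[THETA_W];
    const bool Hvm = u >= p[THETA_VMINUS];
    const bool Ho = u >= p[THETA_O];
    const double tau_vm = Hvm ? p[TAU_V2M] : p[TAU_V1M];
    const double tau_wm = p[TAU_W1M] + (p[TAU_W2M] - p[TAU_W1M]) *
      0.5 * (1.0 + std::tanh(p[K_WM] * (u - p[U_WM])));
    const double tau_so = p[TAU_SO1] + (p[TAU_SO2] - p[TAU_SO1]) *
      0.5 * (1.0 + std::tanh(p[K_SO] * (u - p[U_SO])));
    const double tau_s = Hw ? p[TAU_S2] : p[TAU_S1];
    const double tau_o = Ho ? p[TAU_O2] : p[TAU_O1];
    const double v_inf = Hvm ? 0.0 : 1.0;
    double w_inf = Ho ? p[W_INF_STAR] : (1.0 - u / p[TAU_WINF]);
    if (w_inf < 0.0) w_inf = 0.0;     // clamp targets: keeps gates in [0,1]
    if (w_inf > 1.0) w_inf = 1.0;
    const double s_inf = 0.5 * (1.0 + std::tanh(p[K_S] * (u - p[U_S])));

    double* row = &T.tab[(size_t)i * 9];
    // -J_fi = v * row[0]; J_so = row[1]; -J_si = w*s*row[2]
    row[0] = Hv ? (u - p[THETA_V]) * (p[U_U] - u) / p[TAU_FI] : 0.0;
    row[1] = Hw ? 1.0 / tau_so : (u - p[U_O]) / tau_o;
    row[2] = Hw ? 1.0 / p[TAU_SI] : 0.0;
    // dv/dt = row[3] + row[4]*v, dw/dt = row[5] + row[6]*w, ds/dt = row[7] + row[8]*s
    row[3] = Hv ? 0.0 : v_inf / tau_vm;
    row[4] = Hv ? -1.0 / p[TAU_VP] : -1.0 / tau_vm;
    row[5] = Hw ? 0.0 : w_inf / tau_wm;
    row[6] = Hw ? -1.0 / p[TAU_WP] : -1.0 / tau_wm;
    row[7] = s_inf / tau_s;
    row[8] = -1.0 / tau_s;
  }
  return T;
}

struct Rates { double cfi, cso, csi, av, bv, aw, bw, as_, bs; };

static inline bool lookup(const RateTable& T, double u, Rates& r) {
  if (!(u >= U_LO && u <= U_HI)) return false;  // also catches NaN
  double x = (u - U_LO) * T.inv_du;
  int i = (int)x;
  if (i >= NTAB - 1) i = NTAB - 2;
  const double f = x - i;
  const double* a = &T.tab[(size_t)i * 9];
  const double* b = a + 9;
  r.cfi = a[0] + f * (b[0] - a[0]);
  r.cso = a[1] + f * (b[1] - a[1]);
  r.csi = a[2] + f * (b[2] - a[2]);
  r.av  = a[3] + f * (b[3] - a[3]);
  r.bv  = a[4] + f * (b[4] - a[4]);
  r.aw  = a[5] + f * (b[5] - a[5]);
  r.bw  = a[6] + f * (b[6] - a[6]);
  r.as_ = a[7] + f * (b[7] - a[7]);
  r.bs  = a[8] + f * (b[8] - a[8]);
  return true;
}

static inline double clamp_gate(double g, bool& bad) {
  if (g < 0.0) { if (g < -1e-6) bad = true; return 0.0; }
  if (g > 1.0) { if (g > 1.0 + 1e-6) bad = true; return 1.0; }
  return g;
}

// exact (untabulated) right-hand side, one state; used by mm_derivs
static void exact_rhs(const double* p, double u, double v, double w, double s,
                      double* out) {
  const double Hv = heav(u - p[THETA_V]);
  const double Hw = heav(u - p[THETA_W]);
  const double Hvm = heav(u - p[THETA_VMINUS]);
  const double Ho = heav(u - p[THETA_O]);
  const double tau_vm = (1.0 - Hvm) * p[TAU_V1M] + Hvm * p[TAU_V2M];
  const double tau_wm = p[TAU_W1M] + (p[TAU_W2M] - p[TAU_W1M]) *
    0.5 * (1.0 + std::tanh(p[K_WM] * (u - p[U_WM])));
  const double tau_so = p[TAU_SO1] + (p[TAU_SO2] - p[TAU_SO1]) *
    0.5 * (1.0 + std::tanh(p[K_SO] * (u - p[U_SO])));
  const double tau_s = (1.0 - Hw) * p[TAU_S1] + Hw * p[TAU_S2];
  const double tau_o = (1.0 - Ho) * p[TAU_O1] + Ho * p[TAU_O2];
  const double v_inf = 1.0 - Hvm;
  const double w_inf = (1.0 - Ho) * (1.0 - u / p[TAU_WINF]) + Ho * p[W_INF_STAR];
  const double s_inf = 0.5 * (1.0 + std::tanh(p[K_S] * (u - p[U_S])));

  const double J_fi = -v * Hv * (u - p[THETA_V]) * (p[U_U] - u) / p[TAU_FI];
  const double J_so = (u - p[U_O]) * (1.0 - Hw) / tau_o + Hw / tau_so;
  const double J_si = -Hw * w * s / p[TAU_SI];
  out[0] = J_fi + J_so + J_si;                                   // J_ion
  out[1] = (1.0 - Hv) * (v_inf - v) / tau_vm - Hv * v / p[TAU_VP];
  out[2] = (1.0 - Hw) * (w_inf - w) / tau_wm - Hw * w / p[TAU_WP];
  out[3] = (s_inf - s) / tau_s;
}

// [[Rcpp::export]]
NumericMatrix mm_derivs(NumericVector par, NumericMatrix states) {
  if (par.size() != NPAR) stop("parameter vector must have %d entries", NPAR);
  const int n = states.nrow();
  NumericMatrix out(n, 4);
  double d[4];
  for (int i = 0; i < n; ++i) {
    exact_rhs(par.begin(), states(i, 0), states(i, 1), states(i, 2),
              states(i, 3), d);
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2]; out(i, 3) = d[3];
  }
  return out;
}

// single cell: stimuli are a sorted vector of onset times, all with the same
// duration/amplitude
// [[Rcpp::export]]
List mm_cell_run(NumericVector par, NumericVector state0, double t0,
                 double t_end, double dt, NumericVector stim_times,
                 double stim_dur, double stim_amp, int record_every) {
  if (par.size() != NPAR) stop("parameter vector must have %d entries", NPAR);
  RateTable T = build_table(par.begin());
  double u = state0[0], v = state0[1], w = state0[2], s = state0[3];
  const long n_steps = (long)std::llround((t_end - t0) / dt);
  const long ns = n_steps / record_every + 1;
  NumericVector rt(ns), ru(ns), rv(ns), rw(ns), rs(ns);
  long isamp = 0;
  int sp = 0;
  const int nstim = stim_times.size();
  bool ok = true, gate_bad = false;
  double t_blow = NA_REAL;
  Rates r;
  for (long k = 0; k <= n_steps; ++k) {
    const double t = t0 + k * dt;
    if (k % record_every == 0 && isamp < ns) {
      rt[isamp] = t; ru[isamp] = u; rv[isamp] = v; rw[isamp] = w; rs[isamp] = s;
      ++isamp;
    }
    if (k == n_steps) break;
    while (sp < nstim && t >= stim_times[sp] + stim_dur) ++sp;
    const double ist = (sp < nstim && t >= stim_times[sp]) ? stim_amp : 0.0;
    if (!lookup(T, u, r)) { ok = false; t_blow = t; break; }
    const double react = r.cfi * v - r.cso + r.csi * w * s;
    const double un = u + dt * (react + ist);
    v = clamp_gate(v + dt * (r.av + r.bv * v), gate_bad);
    w = clamp_gate(w + dt * (r.aw + r.bw * w), gate_bad);
    s = clamp_gate(s + dt * (r.as_ + r.bs * s), gate_bad);
    u = un;
  }
  if (gate_bad) ok = false;
  NumericVector fin = NumericVector::create(u, v, w, s);
  return List::create(_["time"] = rt[Range(0, isamp - 1)],
                      _["u"] = ru[Range(0, isamp - 1)],
                      _["v"] = rv[Range(0, isamp - 1)],
                      _["w"] = rw[Range(0, isamp - 1)],
                      _["s"] = rs[Range(0, isamp - 1)],
                      _["state"] = fin, _["ok"] = ok,
                      _["t_blowup"] = t_blow);
}

// 1D cable. state0 is n_cells x 4 (u,v,w,s); stim_cells/record_sites are
// 0-based. Activation times (upward crossings of act_thresh, sub-dt linear
// interpolation, refractory guard) are recorded for every cell.
// [[Rcpp::export]]
List mm_cable_run(NumericVector par, NumericMatrix state0, double t0,
                  double t_end, double dx, double dt, double D,
                  NumericVector stim_times, double stim_dur, double stim_amp,
                  IntegerVector stim_cells, IntegerVector record_sites,
                  int record_every, double act_thresh, double act_refractory,
                  bool diffusion_only = false) {
  if (par.size() != NPAR) stop("parameter vector must have %d entries", NPAR);
  const int n = state0.nrow();
  if (n < 3) stop("cable needs at least 3 cells");
  RateTable T = build_table(par.begin());
  std::vector<double> uo(n), un(n), vv(n), ww(n), ss(n);
  for (int i = 0; i < n; ++i) {
    uo[i] = state0(i, 0); vv[i] = state0(i, 1);
    ww[i] = state0(i, 2); ss[i] = state0(i, 3);
  }
  std::vector<char> is_stim(n, 0);
  for (int j = 0; j < stim_cells.size(); ++j) {
    const int c = stim_cells[j];
    if (c < 0 || c >= n) stop("stim cell index out of range");
    is_stim[c] = 1;
  }
  const long n_steps = (long)std::llround((t_end - t0) / dt);
  const long ns = n_steps / record_every + 1;
  const int nrec = record_sites.size();
  NumericMatrix U(ns, nrec);
  NumericVector rt(ns);
  std::vector<std::vector<double> > act(n);
  std::vector<double> last_act(n, -1e18);
  const double inv_dx2 = 1.0 / (dx * dx);
  long isamp = 0;
  int sp = 0;
  const int nstim = stim_times.size();
  bool ok = true, gate_bad = false;
  double t_blow = NA_REAL;
  Rates r;
  for (long k = 0; k <= n_steps; ++k) {
    const double t = t0 + k * dt;
    if (k % record_every == 0 && isamp < ns) {
      rt[isamp] = t;
      for (int j = 0; j < nrec; ++j) U(isamp, j) = uo[record_sites[j]];
      ++isamp;
    }
    if (k == n_steps || !ok) break;
    while (sp < nstim && t >= stim_times[sp] + stim_dur) ++sp;
    const bool stim_on = (sp < nstim && t >= stim_times[sp]);
    for (int i = 0; i < n; ++i) {
      const double u = uo[i];
      const double ul = (i == 0) ? uo[1] : uo[i - 1];       // mirror ghosts
      const double ur = (i == n - 1) ? uo[n - 2] : uo[i + 1];
      const double lap = (ul - 2.0 * u + ur) * inv_dx2;
      const double ist = (stim_on && is_stim[i]) ? stim_amp : 0.0;
      double react = 0.0;
      if (!diffusion_only) {
        if (!lookup(T, u, r)) { ok = false; t_blow = t; break; }
        react = r.cfi * vv[i] - r.cso + r.csi * ww[i] * ss[i];
        vv[i] = clamp_gate(vv[i] + dt * (r.av + r.bv * vv[i]), gate_bad);
        ww[i] = clamp_gate(ww[i] + dt * (r.aw + r.bw * ww[i]), gate_bad);
        ss[i] = clamp_gate(ss[i] + dt * (r.as_ + r.bs * ss[i]), gate_bad);
      }
      un[i] = u + dt * (react + D * lap + ist);
      if (!std::isfinite(un[i]) || un[i] < U_LO || un[i] > U_HI) {
        ok = false; t_blow = t;
      }
    }
    if (!ok) break;
    const double tn = t + dt;
    for (int i = 0; i < n; ++i) {
      if (uo[i] < act_thresh && un[i] >= act_thresh &&
          tn - last_act[i] > act_refractory) {
        const double tc = t + dt * (act_thresh - uo[i]) / (un[i] - uo[i]);
        act[i].push_back(tc);
        last_act[i] = tc;
      }
    }
    uo.swap(un);
  }
  if (gate_bad) ok = false;
  NumericMatrix fin(n, 4);
  for (int i = 0; i < n; ++i) {
    fin(i, 0) = uo[i]; fin(i, 1) = vv[i]; fin(i, 2) = ww[i]; fin(i, 3) = ss[i];
  }
  List actL(n);
  for (int i = 0; i < n; ++i) actL[i] = wrap(act[i]);
  return List::create(_["time"] = rt[Range(0, isamp - 1)],
                      _["U"] = U(Range(0, isamp - 1), _),
                      _["act"] = actL, _["state"] = fin, _["ok"] = ok,
                      _["t_blowup"] = t_blow);
}

// 2D isotropic sheet, nx x ny cells stored column-major (R matrix layout,
// row index i = x, column index j = y). stims: list of
// list(t_on, dur, amp, i0, i1, j0, j1) with 0-based inclusive cell ranges.
// probes: m x 2 matrix of 0-based (i, j).
// [[Rcpp::export]]
List mm_sheet_run(NumericVector par, NumericMatrix U0, NumericMatrix V0,
                  NumericMatrix W0, NumericMatrix S0, double dx, double dt,
                  double D, double t0, double t_end, List stims,
                  int frame_every, IntegerMatrix probes, int probe_every) {
  if (par.size() != NPAR) stop("parameter vector must have %d entries", NPAR);
  const int nx = U0.nrow(), ny = U0.ncol();
  if (nx < 3 || ny < 3) stop("sheet needs at least 3x3 cells");
  RateTable T = build_table(par.begin());
  const long ncell = (long)nx * ny;
  std::vector<double> uo(ncell), un(ncell), vv(ncell), ww(ncell), ss(ncell);
  for (long q = 0; q < ncell; ++q) {
    uo[q] = U0[q]; vv[q] = V0[q]; ww[q] = W0[q]; ss[q] = S0[q];
  }
  const int nstim = stims.size();
  std::vector<double> s_ton(nstim), s_dur(nstim), s_amp(nstim);
  std::vector<int> s_i0(nstim), s_i1(nstim), s_j0(nstim), s_j1(nstim);
  for (int q = 0; q < nstim; ++q) {
    List st = stims[q];
    s_ton[q] = as<double>(st["t_on"]); s_dur[q] = as<double>(st["dur"]);
    s_amp[q] = as<double>(st["amp"]);
    s_i0[q] = as<int>(st["i0"]); s_i1[q] = as<int>(st["i1"]);
    s_j0[q] = as<int>(st["j0"]); s_j1[q] = as<int>(st["j1"]);
  }
  const long n_steps = (long)std::llround((t_end - t0) / dt);
  const long nf = n_steps / frame_every + 1;
  NumericVector frames((R_xlen_t)(nf * ncell));
  NumericVector ftime(nf);
  const int nprobe = probes.nrow();
  const long nsp = n_steps / probe_every + 1;
  NumericMatrix P(nsp, nprobe);
  NumericVector pt(nsp);
  const double inv_dx2 = 1.0 / (dx * dx);
  long iframe = 0, ip = 0;
  bool ok = true, gate_bad = false;
  double t_blow = NA_REAL;
  Rates r;
  for (long k = 0; k <= n_steps; ++k) {
    const double t = t0 + k * dt;
    if (k % frame_every == 0 && iframe < nf) {
      std::copy(uo.begin(), uo.end(), frames.begin() + iframe * ncell);
      ftime[iframe] = t;
      ++iframe;
    }
    if (k % probe_every == 0 && ip < nsp) {
      pt[ip] = t;
      for (int m = 0; m < nprobe; ++m)
        P(ip, m) = uo[(long)probes(m, 0) + (long)nx * probes(m, 1)];
      ++ip;
    }
    if (k == n_steps || !ok) break;
    // stimulus mask for this step (few stimuli; rebuild only while active)
    for (int j = 0; j < ny; ++j) {
      const long col = (long)nx * j;
      const long colL = (j == 0) ? (long)nx * 1 : col - nx;
      const long colR = (j == ny - 1) ? (long)nx * (ny - 2) : col + nx;
      for (int i = 0; i < nx; ++i) {
        const long q = col + i;
        const double u = uo[q];
        const double ul = (i == 0) ? uo[col + 1] : uo[q - 1];
        const double ur = (i == nx - 1) ? uo[col + nx - 2] : uo[q + 1];
        const double ud = uo[colL + i];
        const double uu2 = uo[colR + i];
        const double lap = (ul + ur + ud + uu2 - 4.0 * u) * inv_dx2;
        if (!lookup(T, u, r)) { ok = false; t_blow = t; break; }
        const double react = r.cfi * vv[q] - r.cso + r.csi * ww[q] * ss[q];
        double ist = 0.0;
        for (int m = 0; m < nstim; ++m) {
          if (t >= s_ton[m] && t < s_ton[m] + s_dur[m] &&
              i >= s_i0[m] && i <= s_i1[m] && j >= s_j0[m] && j <= s_j1[m])
            ist += s_amp[m];
        }
        un[q] = u + dt * (react + D * lap + ist);
        vv[q] = clamp_gate(vv[q] + dt * (r.av + r.bv * vv[q]), gate_bad);
        ww[q] = clamp_gate(ww[q] + dt * (r.aw + r.bw * ww[q]), gate_bad);
        ss[q] = clamp_gate(ss[q] + dt * (r.as_ + r.bs * ss[q]), gate_bad);
        if (!std::isfinite(un[q]) || un[q] < U_LO || un[q] > U_HI) {
          ok = false; t_blow = t;
        }
      }
      if (!ok) break;
    }
    if (!ok) break;
    uo.swap(un);
  }
  if (gate_bad) ok = false;
  NumericMatrix Ufin(nx, ny), Vfin(nx, ny), Wfin(nx, ny), Sfin(nx, ny);
  for (long q = 0; q < ncell; ++q) {
    Ufin[q] = uo[q]; Vfin[q] = vv[q]; Wfin[q] = ww[q]; Sfin[q] = ss[q];
  }
  if (iframe < nf) {   // truncated run (blow-up): shrink the frame stack
    NumericVector fr2((R_xlen_t)(iframe * ncell));
    std::copy(frames.begin(), frames.begin() + iframe * ncell, fr2.begin());
    frames = fr2;
  }
  frames.attr("dim") = IntegerVector::create(nx, ny, (int)iframe);
  return List::create(
      _["frames"] = frames, _["frame_time"] = ftime[Range(0, iframe - 1)],
      _["probe_time"] = pt[Range(0, std::max(ip - 1, (long)0))],
      _["probe_u"] = P(Range(0, std::max(ip - 1, (long)0)), _),
      _["U"] = Ufin, _["v"] = Vfin, _["w"] = Wfin, _["s"] = Sfin,
      _["ok"] = ok, _["t_blowup"] = t_blow);
}
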