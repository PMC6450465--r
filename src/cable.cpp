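#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Explicit monodomain integrator for a 1D fiber of phenomenological
// ventricular myocytes.  Each cell carries a normalized membrane variable u
// (vm = -85 + 125*u mV), a recovery gate h, cytosolic calcium c (uM),
// SR load s (uM, cytosol-equivalent) and an exponentially releasing SR
// store 'rrem' that is charged at each regenerative upstroke with a steeply
// load-dependent fraction of s.  Forward Euler with explicit diffusion and
// no-flux boundaries; dt is chosen by the caller (default 0.02 ms).
//
// The SR has two compartments: an uptake pool 'nsr' filled by SERCA flux
// and a release pool 'jsr' refilled from nsr with time constant tau_tr.
// Slow jsr refill makes the beat-to-beat release map rate dependent.
//
// Parameter columns (one row per cell):
//  0 tau_in    1 tau_out   2 tau_open  3 tau_close 4 u_gate
//  5 g_cv      6 c_base    7 v_up      8 K_up      9 tau_ca_out
// 10 g_in     11 tau_rel  12 rel_fmax 13 rel_K    14 rel_gamma
// 15 u_rel_gate 16 rel_refrac 17 tau_tr 18 tau_cv
//
// The voltage coupling acts through cw, a low-pass filter of cytosolic
// calcium (time constant tau_cv) standing for the slow, NCX-weighted
// calcium the membrane integrates over the plateau.
//
// State columns: 0 u, 1 h, 2 c, 3 nsr, 4 jsr, 5 rrem, 6 cw,
// 7 last_rel (absolute ms).
//
// stim rows: t_on, dur, amp (du/dt units), cell_lo, cell_hi (0-based,
// inclusive), sorted by t_on.

// [[Rcpp::export]]
List cpp_run_cable(NumericMatrix par, NumericMatrix state0,
                   double t0, double t_end, double dt,
                   NumericMatrix stim, double D, double dx,
                   double record_start, double record_every) {
  const int n = state0.nrow();
  if (par.nrow() != n) stop("parameter/state row mismatch");
  const int nstim = stim.nrow();

  std::vector<double> u(n), h(n), c(n), nsr(n), jsr(n), rrem(n), cw(n),
      lastrel(n);
  for (int i = 0; i < n; ++i) {
    u[i] = state0(i, 0); h[i] = state0(i, 1); c[i] = state0(i, 2);
    nsr[i] = state0(i, 3); jsr[i] = state0(i, 4); rrem[i] = state0(i, 5);
    cw[i] = state0(i, 6); lastrel[i] = state0(i, 7);
  }
  std::vector<double> tau_in(n), tau_out(n), tau_open(n), tau_close(n),
      u_gate(n), g_cv(n), c_base(n), v_up(n), K_up(n), tau_ca_out(n),
      g_in(n), tau_rel(n), rel_fmax(n), rel_K(n), rel_gamma(n),
      u_rel_gate(n), rel_refrac(n), tau_tr(n), tau_cv(n);
  for (int i = 0; i < n; ++i) {
    tau_in[i] = par(i, 0); tau_out[i] = par(i, 1); tau_open[i] = par(i, 2);
    tau_close[i] = par(i, 3); u_gate[i] = par(i, 4); g_cv[i] = par(i, 5);
    c_base[i] = par(i, 6); v_up[i] = par(i, 7); K_up[i] = par(i, 8);
    tau_ca_out[i] = par(i, 9); g_in[i] = par(i, 10); tau_rel[i] = par(i, 11);
    rel_fmax[i] = par(i, 12); rel_K[i] = par(i, 13); rel_gamma[i] = par(i, 14);
    u_rel_gate[i] = par(i, 15); rel_refrac[i] = par(i, 16);
    tau_tr[i] = par(i, 17); tau_cv[i] = par(i, 18);
  }

  // recording plan
  std::vector<double> rec_times;
  if (record_every > 0) {
    double tr = t0 + record_start;
    while (tr <= t_end + 1e-9) { rec_times.push_back(tr); tr += record_every; }
  }
  const int nrec = (int)rec_times.size();
  NumericMatrix vm_out(n, std::max(nrec, 0));
  NumericMatrix cai_out(n, std::max(nrec, 0));
  NumericMatrix sr_out(n, std::max(nrec, 0));
  int irec = 0;

  const double dcoef = (n > 1) ? D / (dx * dx) : 0.0;
  std::vector<double> istim(n, 0.0), unew(n);
  int stim_lo = 0;
  const long nsteps = (long)std::ceil((t_end - t0) / dt - 1e-9);
  double t = t0;

  for (long step = 0; step <= nsteps; ++step) {
    // record (state at time t)
    while (irec < nrec && rec_times[irec] <= t + dt * 0.5) {
      for (int i = 0; i < n; ++i) {
        vm_out(i, irec) = -85.0 + 125.0 * u[i];
        cai_out(i, irec) = c[i];
        sr_out(i, irec) = jsr[i] + rrem[i];
      }
      ++irec;
    }
    if (step == nsteps) break;

    // active stimuli
    std::fill(istim.begin(), istim.end(), 0.0);
    while (stim_lo < nstim && stim(stim_lo, 0) + stim(stim_lo, 1) <= t) ++stim_lo;
    for (int k = stim_lo; k < nstim; ++k) {
      if (stim(k, 0) > t) break;
      if (t >= stim(k, 0) && t < stim(k, 0) + stim(k, 1)) {
        int lo = (int)stim(k, 3), hi = (int)stim(k, 4);
        if (lo < 0 || hi >= n) stop("stimulus segment out of bounds");
        double amp = stim(k, 2);
        for (int i = lo; i <= hi; ++i) istim[i] += amp;
      }
    }

    for (int i = 0; i < n; ++i) {
      double ui = u[i], hi_ = h[i], ci = c[i];
      double lap = 0.0;
      if (n > 1) {
        double ul = (i > 0) ? u[i - 1] : u[i + 1];     // no-flux mirrors
        double ur = (i < n - 1) ? u[i + 1] : u[i - 1];
        lap = ul + ur - 2.0 * ui;
      }
      double jin = hi_ * ui * ui * (1.0 - ui) / tau_in[i];
      double jout = -ui / tau_out[i];
      double jcv = g_cv[i] * (cw[i] - c_base[i]) * ui * ui * (1.0 - ui);
      double du = jin + jout + jcv + istim[i] + dcoef * lap;
      unew[i] = ui + dt * du;

      double dh = (ui < u_gate[i]) ? (1.0 - hi_) / tau_open[i]
                                   : -hi_ / tau_close[i];
      h[i] = hi_ + dt * dh;

      // calcium subsystem
      double jrel = rrem[i] / tau_rel[i];
      double jup = v_up[i] * ci * ci / (ci * ci + K_up[i] * K_up[i]);
      double jefx = (ci - c_base[i]) / tau_ca_out[i];
      double jlcc = (ui > u_gate[i]) ? g_in[i] : 0.0;
      c[i] = ci + dt * (jrel - jup - jefx + jlcc);
      if (c[i] < 1e-6) c[i] = 1e-6;
      double jtr = (nsr[i] - jsr[i]) / tau_tr[i];
      nsr[i] += dt * (jup - jtr);
      jsr[i] += dt * jtr;
      cw[i] += dt * (ci - cw[i]) / tau_cv[i];
      rrem[i] -= dt * jrel;
      if (rrem[i] < 0) rrem[i] = 0;
    }
    // SR release triggered on regenerative upstroke
    for (int i = 0; i < n; ++i) {
      if (unew[i] >= u_rel_gate[i] && u[i] < u_rel_gate[i] &&
          (t - lastrel[i]) > rel_refrac[i]) {
        double sg = std::pow(jsr[i], rel_gamma[i]);
        double kg = std::pow(rel_K[i], rel_gamma[i]);
        double rel = rel_fmax[i] * jsr[i] * sg / (sg + kg);
        if (rel > jsr[i]) rel = jsr[i];
        jsr[i] -= rel;
        rrem[i] += rel;
        lastrel[i] = t;
      }
      u[i] = unew[i];
    }
    t = t0 + (step + 1) * dt;

    if ((step & 8191) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(u[i]) || !std::isfinite(c[i]))
          stop("integration failure: non-finite state at t=%f ms, cell %d",
               t, i + 1);
    }
  }

  NumericMatrix state_final(n, 8);
  for (int i = 0; i < n; ++i) {
    state_final(i, 0) = u[i]; state_final(i, 1) = h[i];
    state_final(i, 2) = c[i]; state_final(i, 3) = nsr[i];
    state_final(i, 4) = jsr[i]; state_final(i, 5) = rrem[i];
    state_final(i, 6) = cw[i]; state_final(i, 7) = lastrel[i];
  }
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(u[i]) || !std::isfinite(c[i]))
      stop("integration failure: non-finite final state at cell %d", i + 1);

  return List::create(_["times"] = wrap(rec_times), _["vm"] = vm_out,
                      _["cai"] = cai_out, _["sr"] = sr_out,
                      _["state"] = state_final, _["t_end"] = t_end);
}
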