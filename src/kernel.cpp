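// Core numerics: reference ventricular membrane model (Hodgkin-Huxley type)
// and the explicit operator-split cable integrator. All analysis lives in R;
// only the inner time-stepping loops are compiled.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout (see R/ionic_models.R for the user-facing names)
enum Par {
  P_GNA = 0, P_GNAL, P_GCAL, P_GKR, P_GKS, P_GK1, P_GTO,
  P_KNACA, P_GB, P_SKR, P_SCAL, P_ENA, P_EK, P_EB,
  P_TAUF_SCALE, P_TAUXS_SCALE, P_GKP, P_GPUMP, P_NPAR
};

// State vector layout
enum St {
  S_V = 0, S_M, S_H, S_J, S_D, S_F, S_XR, S_XS, S_R, S_S, S_HL, S_KP, S_CAI, S_CAS,
  S_NSTATE
};

static const int N_GATES = 10; // m..hL (indices 1..10)

struct Rates {
  double inf[S_NSTATE];
  double tau[S_NSTATE];
};

static inline double safe_ratio(double num, double den, double lim) {
  return (std::fabs(den) < 1e-9) ? lim : num / den;
}

// Gate steady states and time constants (ms) at voltage v (mV).
static void gate_rates(double v, const double* p, Rates& rt) {
  // Fast sodium current gates (classic alpha/beta formulation)
  double am = safe_ratio(0.32 * (v + 47.13), 1.0 - std::exp(-0.1 * (v + 47.13)), 3.2);
  double bm = 0.08 * std::exp(-v / 11.0);
  double ah, bh, aj, bj;
  if (v < -40.0) {
    ah = 0.135 * std::exp(-(80.0 + v) / 6.8);
    bh = 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v);
    aj = (-1.2714e5 * std::exp(0.2444 * v) - 3.474e-5 * std::exp(-0.04391 * v)) *
         (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * v) / (1.0 + std::exp(-0.1378 * (v + 40.14)));
  } else {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  }
  rt.inf[S_M] = am / (am + bm); rt.tau[S_M] = 1.0 / (am + bm);
  rt.inf[S_H] = ah / (ah + bh); rt.tau[S_H] = 1.0 / (ah + bh);
  rt.inf[S_J] = aj / (aj + bj); rt.tau[S_J] = 1.0 / (aj + bj);

  // L-type calcium current gates: activation centred above 0 mV so that the
  // dome is regenerative only with substantial conductance; slow
  // voltage-dependent inactivation sets plateau duration and EAD propensity
  rt.inf[S_D] = 1.0 / (1.0 + std::exp(-(v - 5.0) / 8.5));
  double dd = (v + 12.0) / 16.0;
  rt.tau[S_D] = 2.0 + 25.0 * std::exp(-dd * dd);
  rt.inf[S_F] = 1.0 / (1.0 + std::exp((v + 8.0) / 5.0));
  double df_ = (v - 15.0) / 18.0;
  rt.tau[S_F] = p[P_TAUF_SCALE] * (15.0 + 170.0 * std::exp(-df_ * df_)) +
                30.0 / (1.0 + std::exp((v + 70.0) / 8.0));

  // Rapid delayed rectifier activation
  rt.inf[S_XR] = 1.0 / (1.0 + std::exp(-(v + 21.5) / 7.5));
  double dxr = (v + 15.0) / 35.0;
  rt.tau[S_XR] = 30.0 + 370.0 * std::exp(-dxr * dxr);

  // Slow delayed rectifier activation
  rt.inf[S_XS] = 1.0 / (1.0 + std::exp(-(v - 1.5) / 16.7));
  rt.tau[S_XS] = p[P_TAUXS_SCALE] *
                 (150.0 + 900.0 / (1.0 + std::exp(-(v + 10.0) / 10.0)));

  // Transient outward current gates
  rt.inf[S_R] = 1.0 / (1.0 + std::exp((20.0 - v) / 6.0));
  rt.tau[S_R] = 9.5 * std::exp(-(v + 40.0) * (v + 40.0) / 1800.0) + 0.8;
  rt.inf[S_S] = 1.0 / (1.0 + std::exp((v + 28.0) / 5.0));
  rt.tau[S_S] = 85.0 * std::exp(-(v + 45.0) * (v + 45.0) / 320.0) +
                5.0 / (1.0 + std::exp((v - 20.0) / 5.0)) + 3.0;

  // Late sodium slow inactivation
  rt.inf[S_HL] = 1.0 / (1.0 + std::exp((v + 91.0) / 6.1));
  rt.tau[S_HL] = 800.0;

  // Plateau potassium slow inactivation: the current opposes early domes but
  // has faded by the time late repolarization failure (EADs) can develop
  rt.inf[S_KP] = 1.0 / (1.0 + std::exp((v + 20.0) / 6.0));
  double dkp = (v + 20.0) / 25.0;
  rt.tau[S_KP] = 30.0 + 250.0 * std::exp(-dkp * dkp);
}

// Ionic currents (uA/uF). out[0] = total, then per-current breakdown.
enum Cur { C_TOT = 0, C_NA, C_NAL, C_CAL, C_KR, C_KS, C_K1, C_TO, C_KP, C_NACA, C_PUMP, C_B, C_NCUR };

static void currents(const double* s, const double* p, double* out) {
  double v = s[S_V];
  double e_na = p[P_ENA], e_k = p[P_EK];
  double cai = s[S_CAI];
  double e_si = 7.7 - 13.0287 * std::log(cai);

  double i_na = p[P_GNA] * s[S_M] * s[S_M] * s[S_M] * s[S_H] * s[S_J] * (v - e_na);
  double ml_inf = 1.0 / (1.0 + std::exp(-(v + 42.0) / 6.0));
  double i_nal = p[P_GNAL] * ml_inf * s[S_HL] * (v - e_na);
  double i_cal = p[P_GCAL] * p[P_SCAL] * s[S_D] * s[S_F] * (v - e_si);
  double rkr = 1.0 / (1.0 + std::exp((v + 20.0) / 20.0));
  double i_kr = p[P_GKR] * p[P_SKR] * s[S_XR] * rkr * (v - e_k);
  double i_ks = p[P_GKS] * s[S_XS] * s[S_XS] * (v - e_k);
  double k1_inf = 1.0 / (1.0 + std::exp(0.1 * (v + 60.0)));
  double i_k1 = p[P_GK1] * k1_inf * (v - e_k);
  double i_to = p[P_GTO] * s[S_R] * s[S_S] * (v - e_k);
  double kp_inf = 1.0 / (1.0 + std::exp((2.0 - v) / 4.0));
  double i_kp = p[P_GKP] * kp_inf * s[S_KP] * (v - e_k);
  double i_naca = -p[P_KNACA] * cai / (cai + 0.0012);
  // electrogenic pump: tracks the slow Ca pool, i.e. recent beat rate;
  // supplies extra repolarizing drive at fast pacing
  // two-phase rate-dependent repolarizing drive: a late component active
  // once the plateau K inactivation gate has closed (EAD-time protection at
  // fast rates) and a steeper early component active while it is open
  // (plateau shortening at fast rates, gone by EAD time)
  double cs2 = (s[S_CAS] / 0.003) * (s[S_CAS] / 0.003);
  double cs4 = (s[S_CAS] / 0.0048) * (s[S_CAS] / 0.0048);
  cs4 *= cs4;
  double i_pump = p[P_GPUMP] *
                  ((1.0 - s[S_KP]) * (cs2 / (1.0 + cs2)) +
                   0.5 * s[S_KP] * (cs4 / (1.0 + cs4))) /
                  (1.0 + std::exp(-(v + 25.0) / 6.0));
  double i_b = p[P_GB] * (v - p[P_EB]);

  out[C_NA] = i_na; out[C_NAL] = i_nal; out[C_CAL] = i_cal;
  out[C_KR] = i_kr; out[C_KS] = i_ks; out[C_K1] = i_k1;
  out[C_TO] = i_to; out[C_KP] = i_kp; out[C_NACA] = i_naca;
  out[C_PUMP] = i_pump; out[C_B] = i_b;
  out[C_TOT] = i_na + i_nal + i_cal + i_kr + i_ks + i_k1 + i_to + i_kp +
               i_naca + i_pump + i_b;
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// One reaction step: exponential (Rush-Larsen) gate update, forward Euler for
// Cai and (optionally) V. Returns dV/dt used.
static double reaction_step(double* s, const double* p, double dt,
                            double i_stim, bool update_v) {
  Rates rt;
  gate_rates(s[S_V], p, rt);
  double cur[C_NCUR];
  currents(s, p, cur);
  double dvdt = -(cur[C_TOT] + i_stim);
  double i_cal = cur[C_CAL];
  for (int g = S_M; g <= S_KP; ++g) {
    double e = std::exp(-dt / rt.tau[g]);
    s[g] = clamp01(rt.inf[g] + (s[g] - rt.inf[g]) * e);
  }
  double cai = s[S_CAI] + dt * (-1e-4 * i_cal + 0.07 * (1e-4 - s[S_CAI]));
  s[S_CAI] = cai < 1e-6 ? 1e-6 : cai;
  s[S_CAS] += dt * (s[S_CAI] - s[S_CAS]) / 1500.0;
  if (update_v) s[S_V] += dt * dvdt;
  return dvdt;
}

// [[Rcpp::export]]
NumericVector cell_currents_cpp(NumericVector state, NumericVector params) {
  double cur[C_NCUR];
  currents(REAL(state), REAL(params), cur);
  NumericVector out(C_NCUR);
  for (int i = 0; i < C_NCUR; ++i) out[i] = cur[i];
  out.attr("names") = CharacterVector::create(
    "i_total", "i_na", "i_nal", "i_cal", "i_kr", "i_ks", "i_k1", "i_to",
    "i_kp", "i_naca", "i_pump", "i_b");
  return out;
}

// [[Rcpp::export]]
NumericVector cell_step_cpp(NumericVector state, NumericVector params,
                            double dt, double i_stim, bool update_v) {
  NumericVector s = clone(state);
  reaction_step(REAL(s), REAL(params), dt, i_stim, update_v);
  return s;
}

// Adaptive time-step choice shared by both integrators: dt shrinks with the
// previous step's fastest voltage rate and never exceeds a stability cap.
static inline double choose_dt(double max_dvdt, double dt_min, double dt_max,
                               double dt_cap) {
  double dt = (max_dvdt > 1e-12) ? 0.5 / max_dvdt : dt_max;
  if (dt > dt_max) dt = dt_max;
  if (dt < dt_min) dt = dt_min;
  if (dt > dt_cap) dt = dt_cap;
  return dt;
}

// [[Rcpp::export]]
List run_cable_cpp(NumericMatrix state0,   // S_NSTATE x n_cells
                   NumericMatrix params,   // P_NPAR   x n_cells
                   NumericVector face_d,   // n_cells - 1, mm^2/ms
                   double dx_mm,           // mm
                   IntegerVector stim_cells, // 0-based
                   double stim_amp, double stim_dur,
                   double cl, int n_beats, int record_last,
                   double output_dt, double dt_min, double dt_max) {
  const int nc = state0.ncol();
  const int ns = S_NSTATE;
  if (state0.nrow() != ns) stop("state0 must have %d rows", ns);
  if (params.nrow() != P_NPAR) stop("params must have %d rows", P_NPAR);
  if ((int)face_d.size() != nc - 1) stop("face_d must have n_cells - 1 entries");

  std::vector<double> S(state0.begin(), state0.end()); // column-major
  const double* Pm = params.begin();
  const double* Df = face_d.begin();

  double max_d = 0.0;
  for (int f = 0; f < nc - 1; ++f) if (Df[f] > max_d) max_d = Df[f];
  // explicit stability bound for the diffusion operator
  double dt_cap = (max_d > 0.0) ? 0.8 * dx_mm * dx_mm / (2.0 * max_d) : dt_max;
  if (dt_cap > dt_max) dt_cap = dt_max;

  const double t_end = (double)n_beats * cl;
  const double t_rec = (double)(n_beats - record_last) * cl;
  const int n_out = (int)std::floor((t_end - t_rec) / output_dt + 1.5);
  NumericMatrix vout(nc, n_out);
  NumericVector tout(n_out);
  for (int k = 0; k < n_out; ++k) tout[k] = t_rec + k * output_dt;

  std::vector<double> dvdt(nc, 0.0), flux(nc, 0.0);
  double t = 0.0, max_dvdt = 0.0;
  int out_idx = 0;
  const double inv_dx2 = 1.0 / (dx_mm * dx_mm);

  // record t = t_rec sample lazily inside the loop (handles t_rec = 0)
  while (t < t_end - 1e-9) {
    if (out_idx < n_out && t >= tout[out_idx] - 1e-9) {
      for (int i = 0; i < nc; ++i) vout(i, out_idx) = S[i * ns + S_V];
      ++out_idx;
    }
    double dt = choose_dt(max_dvdt, dt_min, dt_max, dt_cap);
    // do not step across a stimulus edge or an output sample time
    double beat_start = cl * std::floor(t / cl + 1e-12);
    double t_in_beat = t - beat_start;
    double next_edge = (t_in_beat < stim_dur - 1e-9) ? (beat_start + stim_dur)
                                                     : (beat_start + cl);
    if (out_idx < n_out && tout[out_idx] < next_edge) next_edge = tout[out_idx];
    if (next_edge > t + 1e-9 && t + dt > next_edge) dt = next_edge - t;
    if (t + dt > t_end) dt = t_end - t;

    bool stim_on = (t_in_beat < stim_dur - 1e-9) && ((int)(t / cl) < n_beats);

    // reaction step (V held; dv/dt accumulated, applied with diffusion below)
    max_dvdt = 0.0;
    for (int i = 0; i < nc; ++i) {
      double istim = 0.0;
      if (stim_on) {
        for (int k = 0; k < (int)stim_cells.size(); ++k)
          if (stim_cells[k] == i) { istim = stim_amp; break; }
      }
      dvdt[i] = reaction_step(&S[i * ns], Pm + i * P_NPAR, dt, istim, false);
    }
    // diffusion (flux-conservative, sealed ends) + voltage update
    for (int i = 0; i < nc; ++i) {
      double lap = 0.0;
      double vi = S[i * ns + S_V];
      if (i < nc - 1) lap += Df[i] * (S[(i + 1) * ns + S_V] - vi);
      if (i > 0)      lap -= Df[i - 1] * (vi - S[(i - 1) * ns + S_V]);
      double dv = dvdt[i] + lap * inv_dx2;
      S[i * ns + S_V] = vi + dt * dv;
      double adv = std::fabs(dv);
      if (adv > max_dvdt) max_dvdt = adv;
      if (std::fabs(S[i * ns + S_V]) > 200.0)
        stop("numeric divergence: |V| > 200 mV at cell %d, t = %.3f ms",
             i + 1, t + dt);
    }
    t += dt;
  }
  if (out_idx < n_out) { // final sample at t_end
    for (int i = 0; i < nc; ++i) vout(i, out_idx) = S[i * ns + S_V];
    ++out_idx;
  }

  NumericVector stim_times(n_beats);
  for (int b = 0; b < n_beats; ++b) stim_times[b] = b * cl;
  NumericMatrix final_state(ns, nc);
  std::copy(S.begin(), S.end(), final_state.begin());
  return List::create(_["times"] = tout, _["v"] = vout,
                      _["stim_times"] = stim_times,
                      _["final_state"] = final_state);
}

// [[Rcpp::export]]
NumericVector diffusion_step_cpp(NumericVector v, NumericVector face_d,
                                 double dx_mm, double dt) {
  int n = v.size();
  NumericVector out(n);
  double inv_dx2 = dt / (dx_mm * dx_mm);
  for (int i = 0; i < n; ++i) {
    double lap = 0.0;
    if (i < n - 1) lap += face_d[i] * (v[i + 1] - v[i]);
    if (i > 0)     lap -= face_d[i - 1] * (v[i] - v[i - 1]);
    out[i] = v[i] + inv_dx2 * lap;
  }
  return out;
}
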