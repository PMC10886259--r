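// Event-driven RK4 integrator for the four-compartment tumor-immune system.
//
// Continuous dynamics (per day):
//   dTI/dt  = a*TI  - w1*m(t)*TI *L/(g+TI+TNI)
//   dTNI/dt = a*TNI - w1*m(t)*TNI*L/(g+TI+TNI)
//   dI/dt   = -r*I
//   dL/dt   = w2*(TI+TNI)*L/(g+TI+TNI) + w3*I*L/(g+I) + s - f*L
// with m(t) >= 1 the checkpoint-inhibitor multiplier (reset convention:
// m = 1 + delta*Cmax*2^(-(t - t_last)/t_half_ici), t_last the most recent
// dose at or before t).
//
// Radiation is applied as instantaneous linear-quadratic survival events:
//   TI' = TI*exp(-aT*d - bT*d^2), I' = I + TI - TI', L' = L*exp(-aL*dl),
// with bT = aT/ab_ratio; the non-targeted compartment is never irradiated.
//
// The stepper lands exactly on every radiation and ICI dose instant, so
// events are applied at their scheduled times regardless of the step size.

#include <Rcpp.h>
using namespace Rcpp;

struct Pars {
  double a, f, r, w1, w2, w3, g, s, alphaL, Cmax, thalf_ici, ab_ratio;
};

static Pars unpack(const List& pars) {
  Pars P;
  P.a = as<double>(pars["a"]);
  P.f = as<double>(pars["f"]);
  P.r = as<double>(pars["r"]);
  P.w1 = as<double>(pars["omega1"]);
  P.w2 = as<double>(pars["omega2"]);
  P.w3 = as<double>(pars["omega3"]);
  P.g = as<double>(pars["g"]);
  P.s = as<double>(pars["s"]);
  P.alphaL = as<double>(pars["alphaL"]);
  P.Cmax = as<double>(pars["Cmax"]);
  P.thalf_ici = as<double>(pars["t_half_ici"]);
  P.ab_ratio = as<double>(pars["ab_ratio"]);
  return P;
}

static inline void deriv(const double y[4], double mult, const Pars& P,
                         double dy[4]) {
  const double TI = y[0], TNI = y[1], I = y[2], L = y[3];
  const double den = P.g + TI + TNI;
  const double kill = P.w1 * mult * L / den;
  dy[0] = P.a * TI - kill * TI;
  dy[1] = P.a * TNI - kill * TNI;
  dy[2] = -P.r * I;
  dy[3] = P.w2 * (TI + TNI) * L / den + P.w3 * I * L / (P.g + I) + P.s -
          P.f * L;
}

static inline double ici_mult(double t, double t_last, bool dosed,
                              double delta, const Pars& P) {
  if (!dosed || delta <= 0.0) return 1.0;
  return 1.0 + delta * P.Cmax * std::exp(-M_LN2 * (t - t_last) / P.thalf_ici);
}

// one RK4 step from t over h; the ICI reference dose (t_last/dosed) is the
// state at the start of the step -- dose instants are step boundaries.
static inline void rk4_step(double y[4], double t, double h, double t_last,
                            bool dosed, double delta, const Pars& P) {
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  double m0 = ici_mult(t, t_last, dosed, delta, P);
  double mh = ici_mult(t + 0.5 * h, t_last, dosed, delta, P);
  double m1 = ici_mult(t + h, t_last, dosed, delta, P);
  deriv(y, m0, P, k1);
  for (int j = 0; j < 4; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
  deriv(tmp, mh, P, k2);
  for (int j = 0; j < 4; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
  deriv(tmp, mh, P, k3);
  for (int j = 0; j < 4; ++j) tmp[j] = y[j] + h * k3[j];
  deriv(tmp, m1, P, k4);
  for (int j = 0; j < 4; ++j)
    y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
}

static inline void apply_event(double y[4], double d_tumor, double d_lymph,
                               double aT, double ab_ratio, double aL) {
  const double bT = aT / ab_ratio;
  const double sf = std::exp(-aT * d_tumor - bT * d_tumor * d_tumor);
  const double killed = y[0] * (1.0 - sf);
  y[0] -= killed;
  y[2] += killed;
  y[3] *= std::exp(-aL * d_lymph);
}

static inline void clamp_check(double y[4], const double tol[4], double t,
                               int patient) {
  for (int j = 0; j < 4; ++j) {
    if (!R_finite(y[j]))
      stop("non-finite state (compartment %d) at t = %.3f d for patient %d",
           j + 1, t, patient);
    if (y[j] < 0.0) {
      if (y[j] < -tol[j])
        stop("state undershoot beyond tolerance (compartment %d) at t = %.3f "
             "d for patient %d",
             j + 1, t, patient);
      y[j] = 0.0;
    }
  }
}

// Batch endpoint simulator: one row per patient, shared treatment schedule.
// ev_phys is the *physical* per-event dose (Gy); the tumor dose for patient i
// is qeff[i] * ev_phys. prog_nadir selects the progressive-disease reference:
// 1 = running nadir (RECIST 1.1 style, >=20% diameter rise over the smallest
// size seen so far), 0 = pre-treatment baseline. nadir_floor (cells) is the
// detection limit: the reference nadir cannot fall below the smallest
// measurable lesion, so deeply responding tumors must regrow past
// prog_ratio * nadir_floor before progressing. Returns columns: prog_day,
// dm_day, TI_assess, TI_end, L_end (NA where the event never occurs / no
// assessment requested).
// [[Rcpp::export]]
NumericMatrix cpp_batch_endpoints(NumericMatrix state0, NumericVector alphaT,
                                  NumericVector qeff, NumericVector delta,
                                  NumericVector ev_time, NumericVector ev_phys,
                                  NumericVector ev_dlymph,
                                  NumericVector ici_times, List pars,
                                  double horizon, double dt, double prog_ratio,
                                  double dm_thresh, double assess_day,
                                  int prog_nadir, double nadir_floor) {
  const Pars P = unpack(pars);
  const int n = state0.nrow();
  const int nev = ev_time.size();
  const int nici = ici_times.size();
  NumericMatrix out(n, 5);
  std::fill(out.begin(), out.end(), NA_REAL);

  for (int i = 0; i < n; ++i) {
    double y[4] = {state0(i, 0), state0(i, 1), state0(i, 2), state0(i, 3)};
    double tol[4];
    for (int j = 0; j < 4; ++j)
      tol[j] = 1e-6 * (y[j] > 1.0 ? y[j] : 1.0);
    const double aT = alphaT[i], q = qeff[i], del = delta[i];
    double ti_min = y[0];  // running nadir of the targeted compartment
    const double ti0 = y[0];
    double t = 0.0, t_last = 0.0;
    bool dosed = false;
    int je = 0, ji = 0;
    double prog_day = NA_REAL, dm_day = NA_REAL, ti_assess = NA_REAL;

    if (y[1] > dm_thresh) dm_day = dt;  // above threshold at baseline

    while (t < horizon - 1e-9) {
      // events scheduled at the current instant
      while (je < nev && ev_time[je] <= t + 1e-9) {
        apply_event(y, q * ev_phys[je], ev_dlymph[je], aT, P.ab_ratio,
                    P.alphaL);
        if (y[0] < ti_min) ti_min = y[0];
        ++je;
      }
      while (ji < nici && ici_times[ji] <= t + 1e-9) {
        t_last = ici_times[ji];
        dosed = true;
        ++ji;
      }
      double h = dt;
      if (t + h > horizon) h = horizon - t;
      if (je < nev && ev_time[je] < t + h - 1e-9) h = ev_time[je] - t;
      if (ji < nici && ici_times[ji] < t + h - 1e-9) h = ici_times[ji] - t;
      const double ti_prev = y[0], tni_prev = y[1];
      rk4_step(y, t, h, t_last, dosed, del, P);
      const double t_new = t + h;
      clamp_check(y, tol, t_new, i + 1);
      const double ref =
          prog_nadir ? (ti_min > nadir_floor ? ti_min : nadir_floor) : ti0;
      const double prog_thr = prog_ratio * ref;
      if (!R_finite(prog_day) && y[0] >= prog_thr && prog_thr > 0.0) {
        double fr = (y[0] > ti_prev)
                        ? (prog_thr - ti_prev) / (y[0] - ti_prev)
                        : 1.0;
        if (fr < 0.0) fr = 0.0;
        prog_day = t + fr * h;
      }
      if (y[0] < ti_min) ti_min = y[0];
      if (!R_finite(dm_day) && y[1] > dm_thresh) {
        double fr = (y[1] > tni_prev)
                        ? (dm_thresh - tni_prev) / (y[1] - tni_prev)
                        : 1.0;
        dm_day = t + fr * h;
      }
      if (assess_day >= 0.0 && !R_finite(ti_assess) &&
          t_new >= assess_day - 1e-9) {
        double fr = (assess_day - t) / h;
        if (fr < 0.0) fr = 0.0;
        if (fr > 1.0) fr = 1.0;
        ti_assess = ti_prev + fr * (y[0] - ti_prev);
      }
      t = t_new;
    }
    out(i, 0) = prog_day;
    out(i, 1) = dm_day;
    out(i, 2) = ti_assess;
    out(i, 3) = y[0];
    out(i, 4) = y[3];
  }
  colnames(out) = CharacterVector::create("prog_day", "dm_day", "TI_assess",
                                          "TI_end", "L_end");
  return out;
}

// Dense single-patient trajectory sampled at out_times (sorted, >= 0).
// States at event instants are right-continuous (post-event).
// [[Rcpp::export]]
NumericMatrix cpp_sim_traj(NumericVector state0, double alphaT, double qeff,
                           double delta, NumericVector ev_time,
                           NumericVector ev_phys, NumericVector ev_dlymph,
                           NumericVector ici_times, List pars,
                           NumericVector out_times, double dt) {
  const Pars P = unpack(pars);
  const int nev = ev_time.size();
  const int nici = ici_times.size();
  const int nout = out_times.size();
  const double horizon = out_times[nout - 1];
  NumericMatrix out(nout, 4);
  colnames(out) = CharacterVector::create("TI", "TNI", "I", "L");

  double y[4] = {state0[0], state0[1], state0[2], state0[3]};
  double tol[4];
  for (int j = 0; j < 4; ++j) tol[j] = 1e-6 * (y[j] > 1.0 ? y[j] : 1.0);
  double t = 0.0, t_last = 0.0;
  bool dosed = false;
  int je = 0, ji = 0, jo = 0;

  while (t < horizon - 1e-9 || jo < nout) {
    while (je < nev && ev_time[je] <= t + 1e-9) {
      apply_event(y, qeff * ev_phys[je], ev_dlymph[je], alphaT, P.ab_ratio,
                  P.alphaL);
      ++je;
    }
    while (ji < nici && ici_times[ji] <= t + 1e-9) {
      t_last = ici_times[ji];
      dosed = true;
      ++ji;
    }
    // emit any output times that coincide with the current instant
    while (jo < nout && out_times[jo] <= t + 1e-9) {
      for (int j = 0; j < 4; ++j) out(jo, j) = y[j];
      ++jo;
    }
    if (t >= horizon - 1e-9) break;
    double h = dt;
    if (t + h > horizon) h = horizon - t;
    if (je < nev && ev_time[je] < t + h - 1e-9) h = ev_time[je] - t;
    if (ji < nici && ici_times[ji] < t + h - 1e-9) h = ici_times[ji] - t;
    if (jo < nout && out_times[jo] < t + h - 1e-9) h = out_times[jo] - t;
    rk4_step(y, t, h, t_last, dosed, delta, P);
    t += h;
    clamp_check(y, tol, t, 1);
  }
  return out;
}
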