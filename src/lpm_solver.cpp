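// Implicit-trapezoidal integrator for the 0D circulation model.
//
// State: v_lv, v_la [mL], p_ao, p_sa [mmHg], q_av, q_mv, q_coa, q_ar, q_mr
// [mL/s]. Valve conduits are ideal diodes: the inertial flow ODE is active
// while flow is positive or the opening gradient favorable; zero crossings
// are localized by step bisection before the conduit is clamped shut.
// The Newton iteration uses a finite-difference Jacobian and partial-pivot
// Gaussian elimination; the residual tolerance and the trapezoidal rule
// mirror the reference protocol (initial step 0.1 ms, residual 1e-6).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

constexpr int NS = 9;

struct Params {
  double T, t_ee, q_mpv;
  double r_ao, r_sv, r_sa, r_pda, r_ub, r_graft;
  double c_ao, c_sac, p_cv0;
  double lv_emax, lv_emin, lv_m1, lv_m2, lv_tau1, lv_tau2, lv_v0;
  double la_emax, la_emin, la_m1, la_m2, la_tau1, la_tau2, la_v0;
  double kick;
  double av_k1, av_k2, mv_k1, mv_k2, coa_k1, coa_k2, ar_k1, ar_k2, mr_k1, mr_k2;
  bool graft, has_ar, has_mr;
  // cached
  double g_par, inv_gtot, r_sasv;
};

inline double elast(double t, double T, double emax, double emin,
                    double m1, double m2, double tau1, double tau2) {
  double tm = t - T * std::floor(t / T);
  double h1 = std::pow(tm / tau1, m1);
  double h2 = std::pow(tm / tau2, m2);
  return (emax - emin) / 2.0 * (h1 / (1.0 + h1)) / (1.0 + h2) + emin;
}

inline void rhs(const double* y, double t, const Params& p, const bool* act,
                double* dy) {
  const double v_lv = y[0], v_la = y[1], p_ao = y[2], p_sa = y[3];
  const double q_av = y[4], q_mv = y[5], q_coa = y[6], q_ar = y[7], q_mr = y[8];

  const double p_lv = elast(t, p.T, p.lv_emax, p.lv_emin, p.lv_m1, p.lv_m2,
                            p.lv_tau1, p.lv_tau2) * (v_lv - p.lv_v0);
  const double p_la = elast(t + p.kick, p.T, p.la_emax, p.la_emin, p.la_m1,
                            p.la_m2, p.la_tau1, p.la_tau2) * (v_la - p.la_v0);

  const double p_apost = (p_ao / p.r_ao + p_sa * p.g_par - q_coa) * p.inv_gtot;
  const double q_ub = (p_apost - p_sa) / p.r_ub;
  const double q_graft = p.graft ? (p_apost - p_sa) / p.r_graft : 0.0;
  const double tm = t - p.T * std::floor(t / p.T);
  const double q_pv = (tm <= p.t_ee) ? p.q_mpv * std::sin(M_PI * tm / p.t_ee) : 0.0;

  const double dq_av = act[0] ? (p_lv - p_ao - p.av_k2 * q_av * std::fabs(q_av)) / p.av_k1 : 0.0;
  const double dq_mv = act[1] ? (p_la - p_lv - p.mv_k2 * q_mv * std::fabs(q_mv)) / p.mv_k1 : 0.0;
  const double dq_ar = act[2] ? (p_ao - p_lv - p.ar_k2 * q_ar * std::fabs(q_ar)) / p.ar_k1 : 0.0;
  const double dq_mr = act[3] ? (p_lv - p_la - p.mr_k2 * q_mr * std::fabs(q_mr)) / p.mr_k1 : 0.0;
  const double dq_coa = (p_apost - p_sa - p.r_pda * q_coa -
                         p.coa_k2 * q_coa * std::fabs(q_coa)) / p.coa_k1;

  dy[0] = q_mv - q_av - q_mr + q_ar;
  dy[1] = q_pv - q_mv + q_mr;
  dy[2] = (q_av - q_ar - (p_ao - p_apost) / p.r_ao) / p.c_ao;
  dy[3] = (q_ub + q_coa + q_graft - (p_sa - p.p_cv0) / p.r_sasv) / p.c_sac;
  dy[4] = dq_av;
  dy[5] = dq_mv;
  dy[6] = dq_coa;
  dy[7] = dq_ar;
  dy[8] = dq_mr;
}

inline void aux(const double* y, double t, const Params& p, double* out) {
  const double p_lv = elast(t, p.T, p.lv_emax, p.lv_emin, p.lv_m1, p.lv_m2,
                            p.lv_tau1, p.lv_tau2) * (y[0] - p.lv_v0);
  const double p_la = elast(t + p.kick, p.T, p.la_emax, p.la_emin, p.la_m1,
                            p.la_m2, p.la_tau1, p.la_tau2) * (y[1] - p.la_v0);
  const double p_apost = (y[2] / p.r_ao + y[3] * p.g_par - y[6]) * p.inv_gtot;
  const double q_ub = (p_apost - y[3]) / p.r_ub;
  const double q_graft = p.graft ? (p_apost - y[3]) / p.r_graft : 0.0;
  const double tm = t - p.T * std::floor(t / p.T);
  const double q_pv = (tm <= p.t_ee) ? p.q_mpv * std::sin(M_PI * tm / p.t_ee) : 0.0;
  out[0] = p_lv; out[1] = p_la; out[2] = p_apost;
  out[3] = q_ub; out[4] = q_graft; out[5] = q_pv;
}

// solve A x = b in place (A destroyed), partial pivoting; returns false if singular
bool lu_solve(double A[NS][NS], double* b) {
  int piv[NS];
  for (int i = 0; i < NS; ++i) piv[i] = i;
  for (int k = 0; k < NS; ++k) {
    int m = k;
    double amax = std::fabs(A[k][k]);
    for (int i = k + 1; i < NS; ++i)
      if (std::fabs(A[i][k]) > amax) { amax = std::fabs(A[i][k]); m = i; }
    if (amax < 1e-14) return false;
    if (m != k) {
      for (int j = 0; j < NS; ++j) std::swap(A[k][j], A[m][j]);
      std::swap(b[k], b[m]);
    }
    for (int i = k + 1; i < NS; ++i) {
      const double f = A[i][k] / A[k][k];
      A[i][k] = 0.0;
      for (int j = k + 1; j < NS; ++j) A[i][j] -= f * A[k][j];
      b[i] -= f * b[k];
    }
  }
  for (int i = NS - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < NS; ++j) s -= A[i][j] * b[j];
    b[i] = s / A[i][i];
  }
  return true;
}

// one trapezoidal step with full Newton; returns true on residual < tol
bool trap_step(const double* y0, double t0, double dt, const double* f0,
               const Params& p, const bool* act, double tol, double* y) {
  double f[NS], r[NS], J[NS][NS], Jw[NS][NS], fp[NS], yp[NS];
  for (int i = 0; i < NS; ++i) y[i] = y0[i] + dt * f0[i];
  for (int it = 0; it < 10; ++it) {
    rhs(y, t0 + dt, p, act, f);
    double res = 0.0;
    for (int i = 0; i < NS; ++i) {
      r[i] = y[i] - y0[i] - dt / 2.0 * (f0[i] + f[i]);
      res = std::max(res, std::fabs(r[i]));
    }
    if (!std::isfinite(res)) return false;
    if (res < tol) return true;
    // finite-difference Jacobian of the residual at current iterate
    for (int j = 0; j < NS; ++j) {
      const double h = std::max(1e-6, 1e-7 * std::fabs(y[j]));
      for (int i = 0; i < NS; ++i) yp[i] = y[i];
      yp[j] += h;
      rhs(yp, t0 + dt, p, act, fp);
      for (int i = 0; i < NS; ++i)
        J[i][j] = (i == j ? 1.0 : 0.0) - dt / 2.0 * (fp[i] - f[i]) / h;
    }
    for (int i = 0; i < NS; ++i)
      for (int j = 0; j < NS; ++j) Jw[i][j] = J[i][j];
    if (!lu_solve(Jw, r)) return false;
    for (int i = 0; i < NS; ++i) y[i] -= r[i];
  }
  return false;
}

} // namespace

// [[Rcpp::export(name = ".lpm_run_cpp")]]
List lpm_run_cpp(NumericVector par, NumericVector y0, int n_cycles,
                 double dt_init, double dt_max, double tol, double steady_tol,
                 int store_stride) {
  Params p;
  int k = 0;
  p.T = par[k++]; p.t_ee = par[k++]; p.q_mpv = par[k++];
  p.r_ao = par[k++]; p.r_sv = par[k++]; p.r_sa = par[k++];
  p.r_pda = par[k++]; p.r_ub = par[k++]; p.r_graft = par[k++];
  p.c_ao = par[k++]; p.c_sac = par[k++]; p.p_cv0 = par[k++];
  p.lv_emax = par[k++]; p.lv_emin = par[k++]; p.lv_m1 = par[k++];
  p.lv_m2 = par[k++]; p.lv_tau1 = par[k++]; p.lv_tau2 = par[k++]; p.lv_v0 = par[k++];
  p.la_emax = par[k++]; p.la_emin = par[k++]; p.la_m1 = par[k++];
  p.la_m2 = par[k++]; p.la_tau1 = par[k++]; p.la_tau2 = par[k++]; p.la_v0 = par[k++];
  p.kick = par[k++];
  p.av_k1 = par[k++]; p.av_k2 = par[k++];
  p.mv_k1 = par[k++]; p.mv_k2 = par[k++];
  p.coa_k1 = par[k++]; p.coa_k2 = par[k++];
  p.ar_k1 = par[k++]; p.ar_k2 = par[k++];
  p.mr_k1 = par[k++]; p.mr_k2 = par[k++];
  p.graft = par[k++] > 0.5;
  p.has_ar = par[k++] > 0.5;
  p.has_mr = par[k++] > 0.5;
  p.g_par = 1.0 / p.r_ub + (p.graft ? 1.0 / p.r_graft : 0.0);
  p.inv_gtot = 1.0 / (1.0 / p.r_ao + p.g_par);
  p.r_sasv = p.r_sa + p.r_sv;

  double y[NS];
  for (int i = 0; i < NS; ++i) y[i] = y0[i];
  bool act[4] = {false, false, false, false};
  const double dt_min = 1e-6;
  const double T = p.T;

  NumericMatrix summary(n_cycles, 3);
  std::vector<double> rt, ry;  // recorded final-cycle rows (t + 15 signals)
  bool converged = false;
  int cycles_run = 0;
  double prev[3] = {0, 0, 0};

  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    double t = (cyc - 1) * T;
    const double t_end = cyc * T;
    double dt = dt_init;
    rt.clear(); ry.clear();
    double sbp = -1e300, dbp = 1e300, sv = 0.0;
    double t_prev = t, qav_prev = y[4];
    int stride_ct = 0;

    auto record = [&](double tt, const double* yy) {
      if (stride_ct++ % store_stride != 0 && tt < t_end - 1e-12) return;
      double a[6];
      aux(yy, tt, p, a);
      rt.push_back(tt);
      for (int i = 0; i < NS; ++i) ry.push_back(yy[i]);
      for (int i = 0; i < 6; ++i) ry.push_back(a[i]);
    };
    record(t, y);

    long guard = 0;
    while (t < t_end - 1e-12) {
      if (++guard > 40000000L) stop("integration failure: step guard exceeded");
      double dt_eff = std::min(dt, t_end - t);
      // valve opening on favorable gradient
      double a6[6];
      aux(y, t, p, a6);
      const double p_lv = a6[0], p_la = a6[1];
      if (!act[0] && p_lv > y[2]) act[0] = true;
      if (!act[1] && p_la > p_lv) act[1] = true;
      if (p.has_ar && !act[2] && y[2] > p_lv) act[2] = true;
      if (p.has_mr && !act[3] && p_lv > p_la) act[3] = true;

      double f0[NS], yn[NS];
      rhs(y, t, p, act, f0);
      if (!trap_step(y, t, dt_eff, f0, p, act, tol, yn)) {
        dt = dt_eff / 2.0;
        if (dt < dt_min) stop("integration failure: step underflow at t=%f", t);
        continue;
      }
      const bool closing[4] = {act[0] && yn[4] < 0.0, act[1] && yn[5] < 0.0,
                               act[2] && yn[7] < 0.0, act[3] && yn[8] < 0.0};
      if (closing[0] || closing[1] || closing[2] || closing[3]) {
        if (dt_eff > dt_min * 2.0) { dt = dt_eff / 2.0; continue; }
        const int idx[4] = {4, 5, 7, 8};
        for (int v = 0; v < 4; ++v)
          if (closing[v]) { yn[idx[v]] = 0.0; act[v] = false; }
      }
      if (yn[0] <= 0.0 || yn[1] <= 0.0)
        stop("integration failure: non-positive chamber volume at t=%f", t + dt_eff);
      t += dt_eff;
      sv += (t - t_prev) * (qav_prev + yn[4]) / 2.0;
      t_prev = t; qav_prev = yn[4];
      for (int i = 0; i < NS; ++i) y[i] = yn[i];
      sbp = std::max(sbp, y[2]);
      dbp = std::min(dbp, y[2]);
      record(t, y);
      if (dt < dt_max) dt = std::min(dt * 1.4, dt_max);
    }

    cycles_run = cyc;
    summary(cyc - 1, 0) = sbp; summary(cyc - 1, 1) = dbp; summary(cyc - 1, 2) = sv;
    if (cyc > 1) {
      const double cur[3] = {sbp, dbp, sv};
      bool ok = true;
      for (int i = 0; i < 3; ++i)
        if (std::fabs(cur[i] - prev[i]) / std::max(std::fabs(prev[i]), 1e-9) >= steady_tol)
          ok = false;
      if (ok) converged = true;
    }
    prev[0] = sbp; prev[1] = dbp; prev[2] = sv;
    if (converged) break;
  }

  const int nrec = rt.size();
  NumericMatrix waves(nrec, 16);
  for (int i = 0; i < nrec; ++i) {
    waves(i, 0) = rt[i];
    for (int j = 0; j < 15; ++j) waves(i, j + 1) = ry[i * 15 + j];
  }
  NumericVector yfin(NS);
  for (int i = 0; i < NS; ++i) yfin[i] = y[i];
  return List::create(_["waves"] = waves,
                      _["summary"] = summary(Range(0, cycles_run - 1), _),
                      _["converged"] = converged,
                      _["cycles_run"] = cycles_run,
                      _["final_state"] = yfin);
}
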