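#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Frenet-Serret frame kinematics.
//
// The swimmer is described by its position x and the orthonormal moving frame
// (t, n, b).  Over a sub-step with constant curvature kappa and torsion tau
// the frame precesses rigidly about the Darboux vector w = v (tau t + kappa b)
// and the position follows the corresponding circular arc (2D) or helix (3D).
// Both updates are applied in closed form, so the integrator is exact for
// piecewise-constant (kappa, tau); results do not depend on the sub-step size.
// ---------------------------------------------------------------------------

namespace {

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

inline void normalize3(double* a) {
  double nrm = std::sqrt(dot3(a, a));
  a[0] /= nrm; a[1] /= nrm; a[2] /= nrm;
}

// Modified Gram-Schmidt on (t, n); b is rebuilt as t x n so the frame stays
// right-handed.  Applied after every sub-step to suppress round-off drift.
inline void reorthonormalize(double* t, double* n, double* b) {
  normalize3(t);
  double d = dot3(n, t);
  n[0] -= d * t[0]; n[1] -= d * t[1]; n[2] -= d * t[2];
  normalize3(n);
  cross3(t, n, b);
}

// Rodrigues rotation of v about the unit axis u by the angle whose cosine /
// sine are c / s.
inline void rotate3(double* v, const double* u, double c, double s) {
  double uxv[3];
  cross3(u, v, uxv);
  double uv = dot3(u, v);
  for (int i = 0; i < 3; ++i)
    v[i] = v[i] * c + uxv[i] * s + u[i] * uv * (1.0 - c);
}

inline double dist3(const double* x, const double* xc) {
  double d0 = x[0] - xc[0], d1 = x[1] - xc[1], d2 = x[2] - xc[2];
  return std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
}

// One exact sub-step of duration dt.
void frame_substep(double* x, double* t, double* n, double* b,
                   double kappa, double tau, double v, double dt) {
  double w[3] = { v * (tau * t[0] + kappa * b[0]),
                  v * (tau * t[1] + kappa * b[1]),
                  v * (tau * t[2] + kappa * b[2]) };
  double om = std::sqrt(dot3(w, w));
  if (om * dt < 1e-12) {  // straight-line limit
    for (int i = 0; i < 3; ++i) x[i] += v * dt * t[i];
    return;
  }
  double u[3] = { w[0] / om, w[1] / om, w[2] / om };
  double th = om * dt;
  double c = std::cos(th), s = std::sin(th);
  // Displacement: integral of v t(s) ds with t(s) the rotated tangent.
  double uxt[3];
  cross3(u, t, uxt);
  double ut = dot3(u, t);
  for (int i = 0; i < 3; ++i)
    x[i] += v * (t[i] * s / om + uxt[i] * (1.0 - c) / om +
                 u[i] * ut * (dt - s / om));
  rotate3(t, u, c, s);
  rotate3(n, u, c, s);
  rotate3(b, u, c, s);
  reorthonormalize(t, n, b);
}

// epsilon-greedy selection over one Q row.  Ties among maximal actions are
// resolved either deterministically -- scanning from the preferred action
// tie_pref in cyclic order (increase, decrease, keep) -- or uniformly at
// random.  Uses R's RNG so set.seed() governs draws.
int select_action_row(const double* q0, const double* q1, const double* q2,
                      double epsilon, bool tie_first, int tie_pref = 0) {
  double q[3] = { *q0, *q1, *q2 };
  if (epsilon > 0.0 && unif_rand() < epsilon) {
    int a = static_cast<int>(unif_rand() * 3.0);
    return a > 2 ? 2 : a;
  }
  double m = std::max(q[0], std::max(q[1], q[2]));
  if (tie_first) {
    int pref = tie_pref;
    for (int i = 0; i < 3; ++i) { int a = (pref + i) % 3; if (q[a] == m) return a; }
  }
  int best[3]; int nb = 0;
  for (int a = 0; a < 3; ++a) if (q[a] == m) best[nb++] = a;
  if (nb == 1) return best[0];
  int j = static_cast<int>(unif_rand() * nb);
  if (j >= nb) j = nb - 1;
  return best[j];
}

}  // namespace

// [[Rcpp::export]]
List cpp_advance_frame(NumericVector x, NumericVector t, NumericVector n,
                       NumericVector b, double kappa, double tau,
                       double v, double dt_total, int n_sub) {
  double X[3], T[3], N[3], B[3];
  for (int i = 0; i < 3; ++i) { X[i] = x[i]; T[i] = t[i]; N[i] = n[i]; B[i] = b[i]; }
  double dt = dt_total / n_sub;
  NumericMatrix path(n_sub + 1, 3);
  for (int i = 0; i < 3; ++i) path(0, i) = X[i];
  for (int k = 0; k < n_sub; ++k) {
    frame_substep(X, T, N, B, kappa, tau, v, dt);
    for (int i = 0; i < 3; ++i) path(k + 1, i) = X[i];
  }
  return List::create(_["x"] = NumericVector(X, X + 3),
                      _["t"] = NumericVector(T, T + 3),
                      _["n"] = NumericVector(N, N + 3),
                      _["b"] = NumericVector(B, B + 3),
                      _["path"] = path);
}

// [[Rcpp::export]]
int cpp_select_action(NumericVector q, double epsilon, bool tie_first,
                      int tie_pref = 0) {
  return select_action_row(&q[0], &q[1], &q[2], epsilon, tie_first, tie_pref);
}

// ---------------------------------------------------------------------------
// One Q-learning episode.
//
// Action encoding: 0 = increase, 1 = decrease, 2 = keep.
// stop_mode: 0 = fixed length, 1 = stop at first d < d_threshold,
//            2 = stop once a stable orbit is established (trailing window of
//                W learning steps has mean d <= d_threshold, with no
//                excursion above 2*d_threshold since the qualifying entry).
// Q is modified in place; the caller owns (and, across episodes, carries) it.
// The first learning step is measurement-only (no action) so that the signal
// memory holds two samples before the first decision.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_episode(NumericMatrix Q,
                     NumericVector x0, NumericVector t0, NumericVector n0,
                     double kappa0, double tau0,
                     double d_kappa, double d_tau,
                     int X, double alpha, double gamma_, double epsilon,
                     double beta, int Nt,
                     double v, double dt_learn, int n_sub,
                     double c0, NumericVector xc, bool three_d,
                     bool noise_on, double lambda, double sigma_kappa_sd,
                     int stop_mode, double d_threshold, int W, double t_p,
                     bool record, bool tie_first, bool aligned_credit,
                     bool sense_integrated, int tie_pref) {
  const int L = 2 * X + 1;
  double xcv[3] = { xc[0], xc[1], xc[2] };

  double x[3], t[3], n[3], b[3];
  for (int i = 0; i < 3; ++i) { x[i] = x0[i]; t[i] = t0[i]; n[i] = n0[i]; }
  cross3(t, n, b);
  reorthonormalize(t, n, b);

  int k = 0, tq = 0;
  double kappa_cmd = kappa0;
  double tau_cmd = three_d ? tau0 : 0.0;

  int floor_count = 0, clamp_count = 0;
  double cum_r = 0.0;
  int n_r = -1;     // first step with d < d_threshold
  int entry = -1;   // first sub-threshold entry since the last big excursion

  // trailing-window ring buffer of d values (includes the step-0 value)
  std::vector<double> ring(std::max(W, 1), 0.0);
  int rcount = 0, rpos = 0;
  double rsum = 0.0;
  bool success = false;

  NumericMatrix traj;
  if (record) traj = NumericMatrix(Nt + 1, 11);

  auto measure = [&](const double* pos) -> double {
    double c = c0 / dist3(pos, xcv);
    if (!noise_on) return c;
    double qrate = lambda * c;
    double val = qrate + std::sqrt(qrate) * norm_rand();
    if (val < 1e-12) { val = 1e-12; ++floor_count; }
    return val;
  };

  auto push_d = [&](double d, int step) {
    if (n_r < 0 && d < d_threshold) n_r = step;
    if (d > 2.0 * d_threshold) entry = -1;
    else if (entry < 0 && d < d_threshold) entry = step;
    if (rcount < W) { ring[rpos] = d; rsum += d; ++rcount; }
    else { rsum += d - ring[rpos]; ring[rpos] = d; }
    rpos = (rpos + 1) % std::max(W, 1);
  };

  auto record_row = [&](int step, double action, double reward) {
    if (!record) return;
    double d = dist3(x, xcv);
    traj(step, 0) = step;
    traj(step, 1) = step * dt_learn;
    traj(step, 2) = x[0]; traj(step, 3) = x[1]; traj(step, 4) = x[2];
    traj(step, 5) = kappa_cmd;
    traj(step, 6) = tau_cmd;
    traj(step, 7) = c0 / d;
    traj(step, 8) = d;
    traj(step, 9) = action;
    traj(step, 10) = reward;
  };

  auto stable_now = [&]() -> bool {
    return entry >= 0 && entry * dt_learn <= t_p && rcount >= W &&
           rsum / rcount <= d_threshold;
  };

  double d = dist3(x, xcv);
  push_d(d, 0);
  record_row(0, NA_REAL, NA_REAL);

  int m = 0;
  if (Nt > 0) {
    double dts = dt_learn / n_sub;
    // advance one learning step and return the sensed concentration: either
    // the end-point sample or the average over the sub-step samples
    auto swim_and_sense = [&](double kappa_real) -> double {
      if (!sense_integrated) {
        for (int ss = 0; ss < n_sub; ++ss)
          frame_substep(x, t, n, b, kappa_real, tau_cmd, v, dts);
        return measure(x);
      }
      double acc = 0.0;
      for (int ss = 0; ss < n_sub; ++ss) {
        frame_substep(x, t, n, b, kappa_real, tau_cmd, v, dts);
        acc += measure(x);
      }
      return acc / n_sub;
    };

    double c_prev = sense_integrated ? c0 / dist3(x, xcv) : measure(x);
    // measurement-only first step: curvature held at its initial value
    double kappa_real = kappa_cmd + (noise_on ? sigma_kappa_sd * norm_rand() : 0.0);
    m = 1;
    double c_curr = swim_and_sense(kappa_real);
    d = dist3(x, xcv);
    push_d(d, 1);
    record_row(1, NA_REAL, NA_REAL);

    bool done = false;
    if (stop_mode == 1 && d < d_threshold) done = true;
    if (stop_mode == 2 && stable_now()) { done = true; success = true; }

    int s_pend = -1, a_pend = -1;  // decision awaiting its (lagged) reward

    while (m < Nt && !done) {
      // state: sign of the last concentration change + the curvature level
      // in force for the upcoming interval
      int dcb = (c_curr - c_prev) > 0 ? 1 : 0;
      int s = three_d ? dcb * L * L + (k + X) * L + (tq + X) : dcb * L + (k + X);
      int a = select_action_row(&Q(s, 0), &Q(s, 1), &Q(s, 2), epsilon,
                                tie_first, tie_pref);

      // swim this interval with the current curvature level; the chosen
      // action modifies the level for the *next* interval (one-step
      // actuation latency of the flagellar response)
      kappa_cmd = kappa0 + k * d_kappa;
      if (three_d) tau_cmd = tau0 + tq * d_tau;
      kappa_real = kappa_cmd + (noise_on ? sigma_kappa_sd * norm_rand() : 0.0);
      double c_next = swim_and_sense(kappa_real);
      ++m;

      int shift = (a == 0 ? 1 : 0) - (a == 1 ? 1 : 0);
      if (shift != 0) {
        int k2 = k + shift;
        if (k2 < -X || k2 > X) { ++clamp_count; k2 = std::max(-X, std::min(X, k2)); }
        k = k2;
        if (three_d) {
          int t2 = tq + shift;
          if (t2 < -X || t2 > X) { ++clamp_count; t2 = std::max(-X, std::min(X, t2)); }
          tq = t2;
        }
      }

      double r = beta * (1.0 / c_curr - 1.0 / c_next);
      if (aligned_credit) {
        // the interval just swum was driven by the curvature set at the
        // previous decision: credit that decision, bootstrapping from the
        // state in which the current decision was made
        if (s_pend >= 0) {
          double mx = std::max(Q(s, 0), std::max(Q(s, 1), Q(s, 2)));
          Q(s_pend, a_pend) += alpha * (r + gamma_ * mx - Q(s_pend, a_pend));
        }
        s_pend = s; a_pend = a;
      } else {
        int dcb2 = (c_next - c_curr) > 0 ? 1 : 0;
        int s2 = three_d ? dcb2 * L * L + (k + X) * L + (tq + X)
                         : dcb2 * L + (k + X);
        double mx = std::max(Q(s2, 0), std::max(Q(s2, 1), Q(s2, 2)));
        Q(s, a) += alpha * (r + gamma_ * mx - Q(s, a));
      }
      cum_r += r;

      c_prev = c_curr;
      c_curr = c_next;
      d = dist3(x, xcv);
      push_d(d, m);
      record_row(m, a, r);

      if (stop_mode == 1 && d < d_threshold) break;
      if (stop_mode == 2 && stable_now()) { success = true; break; }
    }
  }

  if (stop_mode == 1) {
    success = (n_r >= 0 && n_r * dt_learn <= t_p);
  } else if (!success) {
    // end-of-episode evaluation: qualifying entry within t_p and trailing
    // window mean at or below the threshold
    success = entry >= 0 && entry * dt_learn <= t_p && rcount > 0 &&
              rsum / rcount <= d_threshold;
  }

  List out = List::create(
    _["n_r"] = (n_r < 0 ? NA_INTEGER : n_r),
    _["success"] = success,
    _["steps"] = m,
    _["cum_reward"] = cum_r,
    _["clamp_events"] = clamp_count,
    _["floor_events"] = floor_count,
    _["final_d"] = dist3(x, xcv),
    _["x"] = NumericVector(x, x + 3),
    _["t"] = NumericVector(t, t + 3),
    _["n"] = NumericVector(n, n + 3),
    _["b"] = NumericVector(b, b + 3),
    _["k_index"] = k,
    _["t_index"] = tq);
  if (record) {
    out["trajectory"] = traj(Range(0, m), _);
  } else {
    out["trajectory"] = R_NilValue;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Stimulus-response (adaptation) model: eta a' = p c - a, mu p' = 1 - a,
// steering through kappa(t) = kappa0 + kappa1 (a - 1).
// ---------------------------------------------------------------------------

namespace {

inline void fj_rk4(double& a, double& p, double c, double eta, double mu,
                   double dt) {
  double k1a = (p * c - a) / eta;
  double k1p = (1.0 - a) / mu;
  double a2 = a + 0.5 * dt * k1a, p2 = p + 0.5 * dt * k1p;
  double k2a = (p2 * c - a2) / eta;
  double k2p = (1.0 - a2) / mu;
  double a3 = a + 0.5 * dt * k2a, p3 = p + 0.5 * dt * k2p;
  double k3a = (p3 * c - a3) / eta;
  double k3p = (1.0 - a3) / mu;
  double a4 = a + dt * k3a, p4 = p + dt * k3p;
  double k4a = (p4 * c - a4) / eta;
  double k4p = (1.0 - a4) / mu;
  a += dt / 6.0 * (k1a + 2.0 * k2a + 2.0 * k3a + k4a);
  p += dt / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_fj_relax(double a, double p, double c, double eta, double mu,
                           double dt, int n_steps) {
  for (int i = 0; i < n_steps; ++i) fj_rk4(a, p, c, eta, mu, dt);
  return NumericVector::create(a, p);
}

// response_every: number of motion sub-steps between response updates.
// 1 integrates the response continuously alongside the frame;  larger values
// sample the concentration once per window, relax (a, p) over the window at
// that frozen value, and -- with latency -- steer with the curvature computed
// in the previous window (the same sensing-to-actuation lag as the learning
// agent's decision cycle).
// [[Rcpp::export]]
List cpp_simulate_fj(NumericVector x0, NumericVector t0, NumericVector n0,
                     double kappa0, double kappa1, double eta, double mu,
                     double v, double c0, NumericVector xc,
                     double t_max, double dt, double d_stop,
                     bool stop_on_reach, int sample_every,
                     int response_every, bool latency) {
  double xcv[3] = { xc[0], xc[1], xc[2] };
  double x[3], t[3], n[3], b[3];
  for (int i = 0; i < 3; ++i) { x[i] = x0[i]; t[i] = t0[i]; n[i] = n0[i]; }
  cross3(t, n, b);
  reorthonormalize(t, n, b);

  int n_steps = static_cast<int>(std::ceil(t_max / dt));
  double d = dist3(x, xcv);
  double a = 1.0, p = 1.0 / (c0 / d);  // start at the adapted fixed point
  double kappa = kappa0;

  int n_rows = n_steps / sample_every + 2;
  NumericMatrix traj(n_rows, 9);
  int row = 0;
  auto record_row = [&](double time) {
    if (row >= n_rows) return;
    double dd = dist3(x, xcv);
    traj(row, 0) = time;
    traj(row, 1) = x[0]; traj(row, 2) = x[1]; traj(row, 3) = x[2];
    traj(row, 4) = kappa;
    traj(row, 5) = a;
    traj(row, 6) = p;
    traj(row, 7) = c0 / dd;
    traj(row, 8) = dd;
    ++row;
  };
  record_row(0.0);

  double t_reach = NA_REAL;
  bool reached = false;
  double kappa_pending = kappa0;
  for (int i = 0; i < n_steps; ++i) {
    if (response_every <= 1) {
      double c = c0 / dist3(x, xcv);
      fj_rk4(a, p, c, eta, mu, dt);
      kappa = kappa0 + kappa1 * (a - 1.0);
    } else if (i % response_every == 0) {
      double c = c0 / dist3(x, xcv);
      for (int j = 0; j < response_every; ++j) fj_rk4(a, p, c, eta, mu, dt);
      double kappa_new = kappa0 + kappa1 * (a - 1.0);
      kappa = latency ? kappa_pending : kappa_new;
      kappa_pending = kappa_new;
    }
    frame_substep(x, t, n, b, kappa, 0.0, v, dt);
    double time = (i + 1) * dt;
    d = dist3(x, xcv);
    if (!reached && d < d_stop) { reached = true; t_reach = time; }
    if ((i + 1) % sample_every == 0) record_row(time);
    if (reached && stop_on_reach) { record_row(time); break; }
  }

  return List::create(
    _["trajectory"] = traj(Range(0, row - 1), _),
    _["reached"] = reached,
    _["t_reach"] = t_reach,
    _["a"] = a, _["p"] = p,
    _["x"] = NumericVector(x, x + 3),
    _["t"] = NumericVector(t, t + 3),
    _["final_d"] = d);
}
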