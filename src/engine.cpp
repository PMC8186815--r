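// Hybrid integrator and adjoint engine for the two-process sleep/circadian
// models.  Fixed-step classical RK4 (default dt = 0.005 h) with
// bisection-based event localization for sleepiness-threshold crossings,
// exact stopping at control breakpoints and scheduled switch times, and a
// backward co-state pass with jump conditions at state-triggered switches.
//
// Model variants (state layout / internal control unit):
//   3  S+C3   y = [n, x, xc, H]   control = alpha (retinal activation rate)
//   2  S+C2   y = [x, xc, H]      control = u (circadian drive)
//   1  S+C1   y = [theta, H]      control = u
//   0  C-only y = [n, x, xc]      control = alpha, no sleep automaton
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

struct Pars {
  double alpha0, gamma, I0, G, p, mu, q, tau_x, k, k_c,
         omega0, tau_r, tau_d, H_m, L_m, A_c, B1_max, B2_max;
};

static Pars unpack(const NumericVector& pv) {
  Pars P;
  P.alpha0 = pv[0];  P.gamma = pv[1];  P.I0 = pv[2];   P.G = pv[3];
  P.p = pv[4];       P.mu = pv[5];     P.q = pv[6];    P.tau_x = pv[7];
  P.k = pv[8];       P.k_c = pv[9];    P.omega0 = pv[10];
  P.tau_r = pv[11];  P.tau_d = pv[12]; P.H_m = pv[13]; P.L_m = pv[14];
  P.A_c = pv[15];    P.B1_max = pv[16]; P.B2_max = pv[17];
  return P;
}

static int state_dim(int variant) {
  switch (variant) {
    case 3: return 4;
    case 2: return 3;
    case 1: return 2;
    case 0: return 3;
  }
  stop("unknown variant");
  return -1;
}


// floor-based modulo (avoids libm fmod, keeps glibc symbol deps minimal)
static inline double mod_pos(double x, double m) {
  return x - std::floor(x / m) * m;
}

// Piecewise-linear periodic interpolation of the PRC on a uniform grid
// over [0, 2*pi).  The grid is dense (built from a periodic cubic spline in
// R), so linear interpolation here keeps the forward model and its exact
// derivative (segment slope) mutually consistent for the adjoint.
struct PRC {
  const double* f;
  int n;
  double val(double th) const {
    double two_pi = 2.0 * M_PI;
    th = mod_pos(th, two_pi);
    double pos = th / two_pi * n;
    int i = (int)std::floor(pos);
    double w = pos - i;
    int i0 = i % n, i1 = (i + 1) % n;
    return f[i0] * (1.0 - w) + f[i1] * w;
  }
  double deriv(double th) const {
    double two_pi = 2.0 * M_PI;
    th = mod_pos(th, two_pi);
    double pos = th / two_pi * n;
    int i = (int)std::floor(pos);
    int i0 = i % n, i1 = (i + 1) % n;
    double h = two_pi / n;
    return (f[i1] - f[i0]) / h;
  }
};



static const double C12 = M_PI / 12.0;

static void rhs(int variant, const double* y, double c, int beta,
                const Pars& P, const PRC& prc, double* dy) {
  if (variant == 3 || variant == 0) {
    double a = beta ? 0.0 : c;
    double n = y[0], x = y[1], xc = y[2];
    double u = P.G * a * (1.0 - n);
    double M = (1.0 - 0.4 * x) * (1.0 - P.k_c * xc);
    double nu = 24.0 / (0.99729 * P.tau_x);
    dy[0] = 60.0 * (a * (1.0 - n) - P.gamma * n);
    dy[1] = C12 * (xc + P.mu * (x / 3.0 + 4.0 / 3.0 * x * x * x
                   - 256.0 / 105.0 * std::pow(x, 7)) + M * u);
    dy[2] = C12 * ((P.q * xc - P.k * x) * M * u - nu * nu * x);
    if (variant == 3)
      dy[3] = beta ? (-y[3] / P.tau_d) : ((1.0 - y[3]) / P.tau_r);
  } else if (variant == 2) {
    double u = beta ? 0.0 : c;
    double x = y[0], xc = y[1];
    double M = (1.0 - 0.4 * x) * (1.0 - P.k_c * xc);
    double nu = 24.0 / (0.99729 * P.tau_x);
    dy[0] = C12 * (xc + P.mu * (x / 3.0 + 4.0 / 3.0 * x * x * x
                   - 256.0 / 105.0 * std::pow(x, 7)) + M * u);
    dy[1] = C12 * ((P.q * xc - P.k * x) * M * u - nu * nu * x);
    dy[2] = beta ? (-y[2] / P.tau_d) : ((1.0 - y[2]) / P.tau_r);
  } else { // variant 1
    double u = beta ? 0.0 : c;
    dy[0] = P.omega0 + prc.val(y[0]) * u;
    dy[1] = beta ? (-y[1] / P.tau_d) : ((1.0 - y[1]) / P.tau_r);
  }
}

// Jacobian dF/dy, row-major J[i*dim+j] = dF_i/dy_j
static void jac(int variant, const double* y, double c, int beta,
                const Pars& P, const PRC& prc, double* J) {
  int d = state_dim(variant);
  for (int i = 0; i < d * d; ++i) J[i] = 0.0;
  if (variant == 3 || variant == 0) {
    double a = beta ? 0.0 : c;
    double n = y[0], x = y[1], xc = y[2];
    double u = P.G * a * (1.0 - n);
    double du_dn = -P.G * a;
    double M = (1.0 - 0.4 * x) * (1.0 - P.k_c * xc);
    double Mx = -0.4 * (1.0 - P.k_c * xc);
    double Mxc = -P.k_c * (1.0 - 0.4 * x);
    double nu = 24.0 / (0.99729 * P.tau_x);
    J[0 * d + 0] = -60.0 * (a + P.gamma);
    double poly_x = P.mu * (1.0 / 3.0 + 4.0 * x * x
                            - 256.0 * 7.0 / 105.0 * std::pow(x, 6));
    J[1 * d + 0] = C12 * M * du_dn;
    J[1 * d + 1] = C12 * (poly_x + Mx * u);
    J[1 * d + 2] = C12 * (1.0 + Mxc * u);
    double s = P.q * xc - P.k * x;
    J[2 * d + 0] = C12 * s * M * du_dn;
    J[2 * d + 1] = C12 * ((-P.k * M + s * Mx) * u - nu * nu);
    J[2 * d + 2] = C12 * ((P.q * M + s * Mxc) * u);
    if (variant == 3)
      J[3 * d + 3] = beta ? (-1.0 / P.tau_d) : (-1.0 / P.tau_r);
  } else if (variant == 2) {
    double u = beta ? 0.0 : c;
    double x = y[0], xc = y[1];
    double M = (1.0 - 0.4 * x) * (1.0 - P.k_c * xc);
    double Mx = -0.4 * (1.0 - P.k_c * xc);
    double Mxc = -P.k_c * (1.0 - 0.4 * x);
    double nu = 24.0 / (0.99729 * P.tau_x);
    double poly_x = P.mu * (1.0 / 3.0 + 4.0 * x * x
                            - 256.0 * 7.0 / 105.0 * std::pow(x, 6));
    J[0 * d + 0] = C12 * (poly_x + Mx * u);
    J[0 * d + 1] = C12 * (1.0 + Mxc * u);
    double s = P.q * xc - P.k * x;
    J[1 * d + 0] = C12 * ((-P.k * M + s * Mx) * u - nu * nu);
    J[1 * d + 1] = C12 * ((P.q * M + s * Mxc) * u);
    J[2 * d + 2] = beta ? (-1.0 / P.tau_d) : (-1.0 / P.tau_r);
  } else {
    double u = beta ? 0.0 : c;
    J[0 * d + 0] = prc.deriv(y[0]) * u;
    J[1 * d + 1] = beta ? (-1.0 / P.tau_d) : (-1.0 / P.tau_r);
  }
}

// dF/dc (c = alpha for variants 3/0, u for 2/1); zero while asleep.
static void dF_dc(int variant, const double* y, double c, int beta,
                  const Pars& P, const PRC& prc, double* g) {
  int d = state_dim(variant);
  for (int i = 0; i < d; ++i) g[i] = 0.0;
  if (beta) return;
  if (variant == 3 || variant == 0) {
    double n = y[0], x = y[1], xc = y[2];
    double M = (1.0 - 0.4 * x) * (1.0 - P.k_c * xc);
    double du_da = P.G * (1.0 - n);
    g[0] = 60.0 * (1.0 - n);
    g[1] = C12 * M * du_da;
    g[2] = C12 * (P.q * xc - P.k * x) * M * du_da;
  } else if (variant == 2) {
    double x = y[0], xc = y[1];
    double M = (1.0 - 0.4 * x) * (1.0 - P.k_c * xc);
    g[0] = C12 * M;
    g[1] = C12 * (P.q * xc - P.k * x) * M;
  } else {
    g[0] = prc.val(y[0]);
  }
}

static double sleepiness_of(int variant, const double* y, const Pars& P) {
  if (variant == 3) return y[3] - P.A_c * y[1];
  if (variant == 2) return y[2] - P.A_c * y[0];
  if (variant == 1) return y[1] - P.A_c * std::cos(y[0]);
  return NA_REAL;
}

static void sleepiness_grad(int variant, const double* y, const Pars& P,
                            double* g) {
  int d = state_dim(variant);
  for (int i = 0; i < d; ++i) g[i] = 0.0;
  if (variant == 3) { g[1] = -P.A_c; g[3] = 1.0; }
  else if (variant == 2) { g[0] = -P.A_c; g[2] = 1.0; }
  else if (variant == 1) { g[0] = P.A_c * std::sin(y[0]); g[1] = 1.0; }
}

static void rk4_step(int variant, const double* y, double c, int beta,
                     const Pars& P, const PRC& prc, double h, double* out) {
  int d = state_dim(variant);
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  rhs(variant, y, c, beta, P, prc, k1);
  for (int i = 0; i < d; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  rhs(variant, tmp, c, beta, P, prc, k2);
  for (int i = 0; i < d; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  rhs(variant, tmp, c, beta, P, prc, k3);
  for (int i = 0; i < d; ++i) tmp[i] = y[i] + h * k3[i];
  rhs(variant, tmp, c, beta, P, prc, k4);
  for (int i = 0; i < d; ++i)
    out[i] = y[i] + h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

struct Event {
  int node;            // index into the node arrays (event occurs at node time)
  double t;
  int beta_old, beta_new;
  int trigger;         // 0 spontaneous, 1 scheduled, 2 safety (state-triggered),
                       // 3 immediate (time-triggered re-arm), 4 forced window end
  double B;
  int sched_idx;       // >=0 for scheduled events
};

struct Path {
  std::vector<double> t;     // node times (N+1)
  std::vector<double> y;     // node states (N+1)*dim
  std::vector<int> beta;     // beta on step starting at node i (length N+1; last = final beta)
  std::vector<double> c;     // control level on step i (length N)
  std::vector<int> bin;      // control interval index of step i (length N)
  std::vector<Event> events;
  bool ok = true;
  std::string err;
};

// policy: 0 spontaneous, 1 scheduled, 2 forced-awake
static void integrate_path(int variant, const double* y0, int beta0,
                           const NumericVector& cb, const NumericVector& clev,
                           int policy, const NumericVector& sw_times,
                           const IntegerVector& sw_beta,
                           double t0, double tf, double dt,
                           double force_wake_until,
                           const Pars& P, const PRC& prc, Path& path) {
  const int d = state_dim(variant);
  const double teps = 1e-9;
  double y[4], ytrial[4];
  for (int i = 0; i < d; ++i) y[i] = y0[i];
  int beta = beta0;
  double t = t0;
  int nb = clev.size();
  int ib = 0;
  while (ib < nb - 1 && cb[ib + 1] <= t + teps) ++ib;
  int isw = 0;
  while (isw < sw_times.size() && sw_times[isw] <= t0 + teps) ++isw;

  size_t est = (size_t)((tf - t0) / dt) + 16;
  path.t.reserve(est + 8);
  path.y.reserve((est + 8) * d);
  path.beta.reserve(est + 8);
  path.c.reserve(est + 8);
  path.bin.reserve(est + 8);

  bool transitions = (variant != 0) && (policy != 2);

  // immediate transition check when the automaton (re-)arms
  auto immediate_check = [&](int trig) {
    if (!transitions || t < force_wake_until - teps) return;
    double B = sleepiness_of(variant, y, P);
    double up = (policy == 0) ? P.H_m : P.B1_max;
    int nb_new = beta;
    if (beta == 0 && B >= up - 1e-12) nb_new = 1;
    else if (beta == 1 && B <= P.L_m + 1e-12) nb_new = 0;
    if (nb_new != beta) {
      Event ev;
      ev.node = (int)path.t.size();  // event at the node about to be pushed? handled by caller ordering
      ev.t = t; ev.beta_old = beta; ev.beta_new = nb_new;
      ev.trigger = trig; ev.B = B; ev.sched_idx = -1;
      path.events.push_back(ev);
      beta = nb_new;
    }
  };

  // push initial node after possible immediate transition at t0
  immediate_check(3);
  path.t.push_back(t);
  for (int i = 0; i < d; ++i) path.y.push_back(y[i]);
  path.beta.push_back(beta);
  if (!path.events.empty() && path.events.back().t == t0)
    path.events.back().node = 0;

  long guard_iter = 0;
  while (t < tf - teps) {
    if (++guard_iter > 200000000L) { path.ok = false; path.err = "step cap"; return; }
    // control interval containing the step start
    while (ib < nb - 1 && cb[ib + 1] <= t + teps) ++ib;
    double barrier = tf;
    if (ib < nb - 1 && cb[ib + 1] < barrier) barrier = cb[ib + 1];
    if (policy == 1 && isw < sw_times.size() && sw_times[isw] < barrier)
      barrier = sw_times[isw];
    bool forced_now = (t < force_wake_until - teps);
    if (forced_now && force_wake_until < barrier) barrier = force_wake_until;

    double c = clev[ib];
    int bin_here = ib;
    double h = barrier - t;
    if (h > dt) h = dt;
    rk4_step(variant, y, c, beta, P, prc, h, ytrial);
    bool finite = true;
    for (int i = 0; i < d; ++i) if (!std::isfinite(ytrial[i])) finite = false;
    if (!finite) { path.ok = false; path.err = "non-finite state"; return; }

    bool crossed = false;
    if (transitions && !forced_now) {
      double up = (policy == 0) ? P.H_m : P.B1_max;
      double g0, g1;
      if (beta == 0) {
        g0 = sleepiness_of(variant, y, P) - up;
        g1 = sleepiness_of(variant, ytrial, P) - up;
      } else {
        g0 = P.L_m - sleepiness_of(variant, y, P);
        g1 = P.L_m - sleepiness_of(variant, ytrial, P);
      }
      if (g0 < 0.0 && g1 >= 0.0) {
        // bisection on the step length; localized far below the 1e-6 h
        // event tolerance so finite-difference gradient checks stay clean
        double lo = 0.0, hi = h, ys[4];
        for (int it = 0; it < 50 && (hi - lo) > 1e-12; ++it) {
          double mid = 0.5 * (lo + hi);
          rk4_step(variant, y, c, beta, P, prc, mid, ys);
          double gm = (beta == 0)
            ? sleepiness_of(variant, ys, P) - up
            : P.L_m - sleepiness_of(variant, ys, P);
          if (gm >= 0.0) hi = mid; else lo = mid;
        }
        rk4_step(variant, y, c, beta, P, prc, hi, ytrial);
        h = hi;
        crossed = true;
      }
    }

    t += h;
    for (int i = 0; i < d; ++i) y[i] = ytrial[i];

    if (crossed) {
      Event ev;
      ev.node = (int)path.t.size();
      ev.t = t; ev.beta_old = beta; ev.beta_new = 1 - beta;
      ev.trigger = (policy == 0) ? 0 : 2;
      ev.B = sleepiness_of(variant, y, P);
      ev.sched_idx = -1;
      path.events.push_back(ev);
      beta = 1 - beta;
    } else if (std::abs(t - barrier) <= teps) {
      t = barrier;
      bool was_forced = forced_now;
      if (policy == 1 && isw < sw_times.size()
          && std::abs(sw_times[isw] - t) <= teps) {
        Event ev;
        ev.node = (int)path.t.size();
        ev.t = t; ev.beta_old = beta; ev.beta_new = sw_beta[isw];
        ev.trigger = 1; ev.B = sleepiness_of(variant, y, P);
        ev.sched_idx = isw;
        path.events.push_back(ev);
        beta = sw_beta[isw];
        ++isw;
      }
      if (was_forced && t >= force_wake_until - teps)
        immediate_check(4);
    }

    path.t.push_back(t);
    for (int i = 0; i < d; ++i) path.y.push_back(y[i]);
    path.beta.push_back(beta);
    path.c.push_back(c);
    path.bin.push_back(bin_here);
  }
}

static PRC make_prc(const NumericVector& prcf) {
  PRC prc;
  prc.f = prcf.size() ? &prcf[0] : nullptr;
  prc.n = prcf.size();
  return prc;
}

// [[Rcpp::export]]
List sim_hybrid_cpp(int variant, NumericVector y0, int beta0,
                    NumericVector cb, NumericVector clev,
                    int policy, NumericVector sw_times, IntegerVector sw_beta,
                    double t0, double tf, double dt, double force_wake_until,
                    NumericVector pars, NumericVector prcf, int thin) {
  Pars P = unpack(pars);
  PRC prc = make_prc(prcf);
  Path path;
  integrate_path(variant, &y0[0], beta0, cb, clev, policy, sw_times, sw_beta,
                 t0, tf, dt, force_wake_until, P, prc, path);
  if (!path.ok) stop("integration failure: %s", path.err.c_str());
  int d = state_dim(variant);
  int N = (int)path.t.size();
  // keep nodes at thinning stride but always keep event nodes and the last node
  std::vector<bool> keep(N, false);
  for (int i = 0; i < N; i += (thin < 1 ? 1 : thin)) keep[i] = true;
  keep[N - 1] = true;
  for (auto& ev : path.events)
    if (ev.node >= 0 && ev.node < N) keep[ev.node] = true;
  int M = 0;
  for (int i = 0; i < N; ++i) if (keep[i]) ++M;
  NumericVector t(M); NumericMatrix Y(M, d);
  IntegerVector beta(M); NumericVector cc(M);
  int j = 0;
  for (int i = 0; i < N; ++i) {
    if (!keep[i]) continue;
    t[j] = path.t[i];
    for (int kk = 0; kk < d; ++kk) Y(j, kk) = path.y[(size_t)i * d + kk];
    beta[j] = path.beta[i];
    cc[j] = (i < N - 1) ? path.c[i] : (path.c.empty() ? NA_REAL : path.c.back());
    ++j;
  }
  int ne = (int)path.events.size();
  NumericVector ev_t(ne), ev_B(ne);
  IntegerVector ev_old(ne), ev_new(ne), ev_trig(ne), ev_sched(ne);
  for (int i = 0; i < ne; ++i) {
    ev_t[i] = path.events[i].t;
    ev_B[i] = path.events[i].B;
    ev_old[i] = path.events[i].beta_old;
    ev_new[i] = path.events[i].beta_new;
    ev_trig[i] = path.events[i].trigger;
    ev_sched[i] = path.events[i].sched_idx;
  }
  return List::create(_["t"] = t, _["Y"] = Y, _["beta"] = beta,
                      _["c"] = cc,
                      _["ev_t"] = ev_t, _["ev_B"] = ev_B,
                      _["ev_old"] = ev_old, _["ev_new"] = ev_new,
                      _["ev_trig"] = ev_trig, _["ev_sched"] = ev_sched);
}

// Terminal residual phi and its state gradient at tf.
// zref: comparison vector — variant 3: (x, xc, H); 2: (x, xc, H);
// 1: (theta, H); 0: (x, xc).
static double terminal_phi(int variant, const double* y,
                           const NumericVector& zref, double tol,
                           double* lam) {
  int d = state_dim(variant);
  for (int i = 0; i < d; ++i) lam[i] = 0.0;
  double phi = -tol;
  if (variant == 3) {
    double dx = y[1] - zref[0], dxc = y[2] - zref[1], dH = y[3] - zref[2];
    phi += dx * dx + dxc * dxc + dH * dH;
    lam[1] = 2 * dx; lam[2] = 2 * dxc; lam[3] = 2 * dH;
  } else if (variant == 2) {
    double dx = y[0] - zref[0], dxc = y[1] - zref[1], dH = y[2] - zref[2];
    phi += dx * dx + dxc * dxc + dH * dH;
    lam[0] = 2 * dx; lam[1] = 2 * dxc; lam[2] = 2 * dH;
  } else if (variant == 1) {
    double dth = mod_pos(y[0] - zref[0], 2.0 * M_PI);
    if (dth > M_PI) dth -= 2.0 * M_PI;
    double dH = y[1] - zref[1];
    phi += dth * dth + dH * dH;
    lam[0] = 2 * dth; lam[1] = 2 * dH;
  } else {
    double dx = y[1] - zref[0], dxc = y[2] - zref[1];
    phi += dx * dx + dxc * dxc;
    lam[1] = 2 * dx; lam[2] = 2 * dxc;
  }
  return phi;
}

// [[Rcpp::export]]
List adjoint_grad_cpp(int variant, NumericVector y0, int beta0,
                      NumericVector cb, NumericVector clev,
                      int policy, NumericVector sw_times, IntegerVector sw_beta,
                      double t0, double tf, double dt, double force_wake_until,
                      NumericVector pars, NumericVector prcf,
                      NumericVector zref, double tol) {
  Pars P = unpack(pars);
  PRC prc = make_prc(prcf);
  Path path;
  integrate_path(variant, &y0[0], beta0, cb, clev, policy, sw_times, sw_beta,
                 t0, tf, dt, force_wake_until, P, prc, path);
  if (!path.ok) stop("integration failure: %s", path.err.c_str());
  int d = state_dim(variant);
  int N = (int)path.t.size();     // nodes
  int nsteps = N - 1;
  double lam[4];
  double phi = terminal_phi(variant, &path.y[(size_t)(N - 1) * d], zref, tol, lam);

  NumericVector grad_c(clev.size());
  NumericVector grad_T(sw_times.size());
  int jumps_skipped = 0;

  // map events by node for the backward sweep
  std::vector<int> ev_at_node(N, -1);
  for (int e = 0; e < (int)path.events.size(); ++e)
    ev_at_node[path.events[e].node] = e;

  double J[16], k1[4], k2[4], k3[4], k4[4], tmp[4], ym[4], gi[4];
  for (int s = nsteps - 1; s >= 0; --s) {
    const double* ya = &path.y[(size_t)s * d];
    const double* yb = &path.y[(size_t)(s + 1) * d];
    double h = path.t[s + 1] - path.t[s];
    int beta = path.beta[s];
    double c = path.c[s];
    int bin = path.bin[s];
    if (h > 0) {
      for (int i = 0; i < d; ++i) ym[i] = 0.5 * (ya[i] + yb[i]);
      // gradient accumulation (Simpson) with lambda at (b, mid~avg, a)
      // computed after the backward RK4 below; first integrate lambda back.
      // backward RK4 on dlam/ds = +J(y)^T lam, s measured from t_{s+1} down
      auto JTlam = [&](const double* yy, const double* lv, double* out) {
        jac(variant, yy, c, beta, P, prc, J);
        for (int i = 0; i < d; ++i) {
          out[i] = 0.0;
          for (int r = 0; r < d; ++r) out[i] += J[r * d + i] * lv[r];
        }
      };
      double l0[4];
      for (int i = 0; i < d; ++i) l0[i] = lam[i];
      JTlam(yb, l0, k1);
      for (int i = 0; i < d; ++i) tmp[i] = l0[i] + 0.5 * h * k1[i];
      JTlam(ym, tmp, k2);
      for (int i = 0; i < d; ++i) tmp[i] = l0[i] + 0.5 * h * k2[i];
      JTlam(ym, tmp, k3);
      for (int i = 0; i < d; ++i) tmp[i] = l0[i] + h * k3[i];
      JTlam(ya, tmp, k4);
      double la[4], lm[4];
      for (int i = 0; i < d; ++i) {
        la[i] = l0[i] + h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
        lm[i] = 0.5 * (l0[i] + la[i]);
      }
      // Simpson quadrature of lam^T dF/dc over the step
      double qa = 0, qm = 0, qb = 0;
      dF_dc(variant, yb, c, beta, P, prc, gi);
      for (int i = 0; i < d; ++i) qb += gi[i] * l0[i];
      dF_dc(variant, ym, c, beta, P, prc, gi);
      for (int i = 0; i < d; ++i) qm += gi[i] * lm[i];
      dF_dc(variant, ya, c, beta, P, prc, gi);
      for (int i = 0; i < d; ++i) qa += gi[i] * la[i];
      grad_c[bin] += h / 6.0 * (qb + 4.0 * qm + qa);
      for (int i = 0; i < d; ++i) lam[i] = la[i];
    }
    // event exactly at node s (mode differs between step s-1 and step s)
    int e = ev_at_node[s];
    if (e >= 0 && s > 0) {
      const Event& ev = path.events[e];
      const double* ye = &path.y[(size_t)s * d];
      double Fm[4], Fp[4];
      double c_minus = path.c[s - 1];
      rhs(variant, ye, c_minus, ev.beta_old, P, prc, Fm);
      rhs(variant, ye, path.c[s], ev.beta_new, P, prc, Fp);
      if (ev.trigger == 0 || ev.trigger == 2) {
        double gB[4];
        sleepiness_grad(variant, ye, P, gB);
        double denom = 0.0, num = 0.0;
        for (int i = 0; i < d; ++i) denom += gB[i] * Fm[i];
        for (int i = 0; i < d; ++i) num += (Fm[i] - Fp[i]) * lam[i];
        if (std::abs(denom) > 1e-8) {
          double fac = num / denom;
          for (int i = 0; i < d; ++i) lam[i] -= fac * gB[i];
        } else {
          ++jumps_skipped;
        }
      } else if (ev.trigger == 1 && ev.sched_idx >= 0) {
        double g = 0.0;
        for (int i = 0; i < d; ++i) g += lam[i] * (Fm[i] - Fp[i]);
        grad_T[ev.sched_idx] = g;
      }
      // triggers 3/4: time-triggered re-arm, no jump, no schedule gradient
    }
  }
  NumericVector yT(d), lam0(d);
  for (int i = 0; i < d; ++i) {
    yT[i] = path.y[(size_t)(N - 1) * d + i];
    lam0[i] = lam[i];
  }
  return List::create(_["phi"] = phi, _["grad_c"] = grad_c,
                      _["grad_T"] = grad_T, _["y_tf"] = yT,
                      _["lambda_t0"] = lam0,
                      _["jumps_skipped"] = jumps_skipped,
                      _["n_events"] = (int)path.events.size());
}

// Brute-force 1-nearest-neighbour lookup used by the feedback controller.
// Features are prepared (already embedded) columns; ties broken by lowest
// row index via strict inequality.
// [[Rcpp::export]]
IntegerVector nn1_lookup_cpp(NumericMatrix train, NumericMatrix query) {
  int n = train.nrow(), m = query.nrow(), d = train.ncol();
  IntegerVector idx(m);
  for (int qi = 0; qi < m; ++qi) {
    double best = R_PosInf; int bi = 0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        double dd = train(i, j) - query(qi, j);
        s += dd * dd;
        if (s >= best) break;
      }
      if (s < best) { best = s; bi = i; }
    }
    idx[qi] = bi + 1;
  }
  return idx;
}
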