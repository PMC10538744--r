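#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact flow of de/dt = ell * e * (c - e) with c > 0 held fixed:
// e(dt) = c e0 / (e0 + (c - e0) exp(-ell c dt)).
static inline double env_exact(double e, double c, double ell, double dt) {
  if (dt <= 0.0 || ell == 0.0) return e;
  double ex = std::exp(-ell * c * dt);
  return c * e / (e + (c - e) * ex);
}

// Explicit Euler with step capped at h.
static inline double env_euler(double e, double c, double ell, double dt,
                               double h) {
  if (dt <= 0.0 || ell == 0.0) return e;
  double t = 0.0;
  while (t < dt) {
    double step = std::min(h, dt - t);
    e += step * ell * e * (c - e);
    t += step;
  }
  return e;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Thinning (uniformization) simulation of the behavior-environment PDMP.
// Candidate times ~ Exp(xi); each candidate fires one of four channels
// (social B->A, social A->B, assessment B->A, assessment A->B) with
// probability rate/xi, else is a phantom. x jumps by +/-1/N; e flows
// deterministically between candidates with x held fixed. Uses R's RNG so
// set.seed() in R governs reproducibility.
// event type codes: 0 phantom, 1 social B->A, 2 social A->B,
//                   3 env B->A, 4 env A->B.
// [[Rcpp::export]]
List pdmp_simulate_cpp(double kappa, double gamma_A, double gamma_B,
                       double delta_A, double delta_B, double tau,
                       double ell, double l_A, double l_B,
                       int N, int nA0, double e0, double t_end,
                       double xi, bool exact_env, double euler_dt,
                       bool log_events, bool log_phantom, double grid_dt) {
  int nA = nA0;
  double e = e0;
  double t = 0.0;
  const double dN = static_cast<double>(N);

  int n_grid = static_cast<int>(std::floor(t_end / grid_dt + 1e-9)) + 1;
  NumericVector gt(n_grid), gx(n_grid), ge(n_grid);
  int gi = 0;

  std::vector<double> ev_t, ev_x, ev_e;
  std::vector<int> ev_type;
  IntegerVector counts(5);  // phantom, sBA, sAB, eBA, eAB

  double x = nA / dN;
  // grid point at t = 0
  gt[gi] = 0.0; gx[gi] = x; ge[gi] = e; ++gi;

  while (t < t_end) {
    double dt = R::rexp(1.0 / xi);
    double t_new = t + dt;
    double c = l_A * x + l_B * (1.0 - x);

    // fill grid points in (t, min(t_new, t_end)]
    while (gi < n_grid) {
      double tg = gi * grid_dt;
      if (tg > t_new || tg > t_end) break;
      double eg = exact_env ? env_exact(e, c, ell, tg - t)
                            : env_euler(e, c, ell, tg - t, euler_dt);
      gt[gi] = tg; gx[gi] = x; ge[gi] = clampd(eg, l_A, l_B); ++gi;
    }

    if (t_new >= t_end) {
      t = t_end;
      break;
    }

    e = exact_env ? env_exact(e, c, ell, dt) : env_euler(e, c, ell, dt, euler_dt);
    e = clampd(e, l_A, l_B);
    t = t_new;

    double r1 = dN * kappa * x * (1.0 - x) * (gamma_A + delta_A * x);
    double r2 = dN * kappa * x * (1.0 - x) * (gamma_B + delta_B * (1.0 - x));
    double r3 = dN * (1.0 - x) * tau * (e - l_A);
    double r4 = dN * x * tau * (l_B - e);

    double u = unif_rand() * xi;
    int type = 0;
    if (u < r1)                       { type = 1; ++nA; }
    else if (u < r1 + r2)             { type = 2; --nA; }
    else if (u < r1 + r2 + r3)        { type = 3; ++nA; }
    else if (u < r1 + r2 + r3 + r4)   { type = 4; --nA; }
    ++counts[type];
    x = nA / dN;

    if (log_events && (type != 0 || log_phantom)) {
      ev_t.push_back(t);
      ev_type.push_back(type);
      ev_x.push_back(x);
      ev_e.push_back(e);
    }
  }

  // trailing grid points (absorbing or quiet tail): x constant, e flows
  if (gi < n_grid) {
    double c = l_A * x + l_B * (1.0 - x);
    double t_ref = gt[gi - 1];
    double e_ref = ge[gi - 1];
    // re-flow from the last committed grid state to keep e continuous
    while (gi < n_grid) {
      double tg = gi * grid_dt;
      double eg = exact_env ? env_exact(e_ref, c, ell, tg - t_ref)
                            : env_euler(e_ref, c, ell, tg - t_ref, euler_dt);
      gt[gi] = tg; gx[gi] = x; ge[gi] = clampd(eg, l_A, l_B); ++gi;
    }
  }

  RObject events = R_NilValue;
  if (log_events) {
    events = DataFrame::create(
        _["t"] = NumericVector(ev_t.begin(), ev_t.end()),
        _["type"] = IntegerVector(ev_type.begin(), ev_type.end()),
        _["x"] = NumericVector(ev_x.begin(), ev_x.end()),
        _["e"] = NumericVector(ev_e.begin(), ev_e.end()));
  }
  counts.attr("names") =
      CharacterVector::create("phantom", "social_B_to_A", "social_A_to_B",
                              "env_B_to_A", "env_A_to_B");
  return List::create(_["grid"] = DataFrame::create(_["t"] = gt, _["x"] = gx,
                                                    _["e"] = ge),
                      _["events"] = events, _["counts"] = counts,
                      _["x_final"] = x, _["e_final"] = e);
}

// Euler-Maruyama path of the linear fluctuation SDE
//   d eta = A eta dt + (sqrt_omega dW, 0)
// Noise enters the behavior coordinate only.
// [[Rcpp::export]]
NumericMatrix ou_simulate_cpp(NumericMatrix A, double sqrt_omega,
                              double eta_A0, double eta_E0,
                              double dt, int n_steps) {
  NumericMatrix out(n_steps + 1, 2);
  double a = eta_A0, b = eta_E0;
  out(0, 0) = a; out(0, 1) = b;
  const double a11 = A(0, 0), a12 = A(0, 1), a21 = A(1, 0), a22 = A(1, 1);
  const double sdt = std::sqrt(dt);
  for (int i = 1; i <= n_steps; ++i) {
    double da = (a11 * a + a12 * b) * dt + sqrt_omega * sdt * norm_rand();
    double db = (a21 * a + a22 * b) * dt;
    a += da; b += db;
    out(i, 0) = a; out(i, 1) = b;
  }
  return out;
}

// Exact logistic environment flow, exported for the environment_update()
// fidelity checks.
// [[Rcpp::export]]
double env_flow_cpp(double e, double c, double ell, double dt,
                    bool exact_env, double euler_dt) {
  return exact_env ? env_exact(e, c, ell, dt)
                   : env_euler(e, c, ell, dt, euler_dt);
}
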