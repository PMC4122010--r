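// Bounded-variable two-phase primal simplex.
//
// Solves  min c'x  s.t.  A x = b,  lb <= x <= ub
// with finite lower bounds and possibly infinite upper bounds.
// Dense arithmetic (Armadillo); problems here are desk-scale
// (tens to a few hundred variables). Anti-cycling via Bland's rule
// after a run of degenerate pivots; basis inverse refactorized
// periodically for numerical hygiene.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double COST_TOL = 1e-9;   // reduced-cost optimality tolerance
const double PIV_TOL  = 1e-8;   // minimal acceptable pivot magnitude
const double DEG_TOL  = 1e-10;  // step considered degenerate below this
const double FEAS_TOL = 1e-7;   // phase-I residual => infeasible above this

enum Status { OPTIMAL = 0, INFEASIBLE = 1, UNBOUNDED = 2, ITLIMIT = 3 };

struct Work {
  mat A;            // m x N full matrix (structural + artificial)
  vec b;
  vec lb, ub;       // N
  vec x;            // current point, length N
  uvec basis;       // m basic variable indices
  ivec nb_at;       // 0 = basic, 1 = nonbasic at lower, 2 = nonbasic at upper
  mat Binv;         // m x m basis inverse
  int m, N;
};

void refactorize(Work &w) {
  mat B = w.A.cols(w.basis);
  mat Binv;
  if (!inv(Binv, B)) {
    Binv = pinv(B);
  }
  w.Binv = Binv;
  // recompute basic values from nonbasic ones
  vec rhs = w.b;
  for (int j = 0; j < w.N; ++j) {
    if (w.nb_at[j] != 0 && w.x[j] != 0.0) rhs -= w.A.col(j) * w.x[j];
  }
  vec xb = w.Binv * rhs;
  for (int i = 0; i < w.m; ++i) w.x[w.basis[i]] = xb[i];
}

// Run simplex iterations for the given cost vector. Returns status.
int iterate(Work &w, const vec &cost, int maxit, int phase, int &it_used) {
  bool bland = false;
  int degen_run = 0;
  const int bland_after = 4 * (w.N + w.m);
  int since_refac = 0;

  for (int iter = 0; iter < maxit; ++iter) {
    it_used++;
    if (++since_refac >= 100) { refactorize(w); since_refac = 0; }

    // pricing: y' = cB' Binv
    vec cb(w.m);
    for (int i = 0; i < w.m; ++i) cb[i] = cost[w.basis[i]];
    vec y = w.Binv.t() * cb;

    int enter = -1, enter_dir = 0;
    double best = COST_TOL;
    for (int j = 0; j < w.N; ++j) {
      int st = w.nb_at[j];
      if (st == 0) continue;
      if (w.ub[j] - w.lb[j] < DEG_TOL) continue;  // pinned variable
      double d = cost[j] - dot(y, w.A.col(j));
      double score;
      int dir;
      if (st == 1 && d < -COST_TOL) { score = -d; dir = +1; }
      else if (st == 2 && d > COST_TOL) { score = d; dir = -1; }
      else continue;
      if (bland) { enter = j; enter_dir = dir; break; }
      if (score > best) { best = score; enter = j; enter_dir = dir; }
    }
    if (enter < 0) return OPTIMAL;

    vec wcol = w.Binv * w.A.col(enter);

    // ratio test: x[enter] moves by enter_dir * t, t >= 0
    double tlim = datum::inf;
    int leave = -1;          // index into basis
    int leave_bound = 0;     // 1 -> hits lower, 2 -> hits upper
    bool has_flip = std::isfinite(w.ub[enter]) && std::isfinite(w.lb[enter]);
    if (has_flip) tlim = w.ub[enter] - w.lb[enter];

    for (int i = 0; i < w.m; ++i) {
      double wi = enter_dir * wcol[i];
      unsigned int bi = w.basis[i];
      if (wi > PIV_TOL) {
        double t = (w.x[bi] - w.lb[bi]) / wi;
        if (t < tlim - DEG_TOL ||
            (t < tlim + DEG_TOL && (leave < 0 ||
              (bland ? bi < w.basis[leave] : std::fabs(wcol[i]) > std::fabs(wcol[leave]))))) {
          tlim = t; leave = i; leave_bound = 1;
        }
      } else if (wi < -PIV_TOL) {
        if (!std::isfinite(w.ub[bi])) continue;
        double t = (w.ub[bi] - w.x[bi]) / (-wi);
        if (t < tlim - DEG_TOL ||
            (t < tlim + DEG_TOL && (leave < 0 ||
              (bland ? bi < w.basis[leave] : std::fabs(wcol[i]) > std::fabs(wcol[leave]))))) {
          tlim = t; leave = i; leave_bound = 2;
        }
      }
    }

    if (!std::isfinite(tlim)) {
      return (phase == 1) ? INFEASIBLE : UNBOUNDED;  // phase 1 is always bounded below
    }
    if (tlim < 0) tlim = 0;

    if (tlim < DEG_TOL) { if (++degen_run > bland_after) bland = true; }
    else { degen_run = 0; bland = false; }

    // apply step
    for (int i = 0; i < w.m; ++i) {
      w.x[w.basis[i]] -= enter_dir * wcol[i] * tlim;
    }

    if (leave < 0) {
      // bound flip, no basis change
      w.x[enter] = (enter_dir > 0) ? w.ub[enter] : w.lb[enter];
      w.nb_at[enter] = (enter_dir > 0) ? 2 : 1;
      continue;
    }

    unsigned int lv = w.basis[leave];
    w.x[enter] = (enter_dir > 0) ? (w.lb[enter] + tlim) : (w.ub[enter] - tlim);
    w.x[lv] = (leave_bound == 1) ? w.lb[lv] : w.ub[lv];
    w.nb_at[lv] = leave_bound;
    w.nb_at[enter] = 0;
    w.basis[leave] = enter;

    // eta update of Binv using pre-pivot column wcol
    double piv = wcol[leave];
    if (std::fabs(piv) < PIV_TOL) { refactorize(w); since_refac = 0; continue; }
    rowvec prow = w.Binv.row(leave) / piv;
    for (int i = 0; i < w.m; ++i) {
      if (i == leave) continue;
      if (std::fabs(wcol[i]) > 0) w.Binv.row(i) -= wcol[i] * prow;
    }
    w.Binv.row(leave) = prow;
  }
  return ITLIMIT;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".simplex_lp")]]
Rcpp::List simplex_lp(const arma::mat &A, const arma::vec &b, const arma::vec &c,
                      const arma::vec &lb, const arma::vec &ub,
                      bool maximize = false, int maxit = 50000) {
  int m = A.n_rows, n = A.n_cols;
  if ((int)b.n_elem != m || (int)c.n_elem != n ||
      (int)lb.n_elem != n || (int)ub.n_elem != n)
    Rcpp::stop("simplex_lp: dimension mismatch");

  for (int j = 0; j < n; ++j) {
    if (!std::isfinite(lb[j])) Rcpp::stop("simplex_lp: lower bounds must be finite");
    if (lb[j] > ub[j] + 1e-9) {
      return Rcpp::List::create(Rcpp::Named("status") = (int)INFEASIBLE,
                                Rcpp::Named("objective") = NA_REAL,
                                Rcpp::Named("x") = Rcpp::NumericVector(n),
                                Rcpp::Named("iterations") = 0);
    }
  }

  vec cost = maximize ? vec(-c) : vec(c);

  Work w;
  w.m = m; w.N = n + m;
  w.A.set_size(m, w.N);
  w.A.cols(0, n - 1) = A;
  w.b = b;
  w.lb.set_size(w.N); w.ub.set_size(w.N);
  w.lb.subvec(0, n - 1) = lb; w.ub.subvec(0, n - 1) = ub;
  w.x.zeros(w.N);
  w.nb_at.set_size(w.N);
  w.basis.set_size(m);

  // nonbasic structurals start at the finite bound nearest zero
  for (int j = 0; j < n; ++j) {
    double v;
    if (std::isfinite(w.ub[j]) && std::fabs(w.ub[j]) < std::fabs(w.lb[j])) {
      v = w.ub[j]; w.nb_at[j] = 2;
    } else {
      v = w.lb[j]; w.nb_at[j] = 1;
    }
    if (w.ub[j] - w.lb[j] < DEG_TOL) { v = w.lb[j]; w.nb_at[j] = 1; }
    w.x[j] = v;
  }

  // artificials: column s_i * e_i so that their start value |r_i| >= 0
  vec r = b;
  for (int j = 0; j < n; ++j) if (w.x[j] != 0.0) r -= A.col(j) * w.x[j];
  w.Binv.zeros(m, m);
  for (int i = 0; i < m; ++i) {
    double s = (r[i] >= 0) ? 1.0 : -1.0;
    w.A.col(n + i).zeros();
    w.A(i, n + i) = s;
    w.lb[n + i] = 0.0;
    w.ub[n + i] = datum::inf;
    w.x[n + i] = std::fabs(r[i]);
    w.basis[i] = n + i;
    w.nb_at[n + i] = 0;
    w.Binv(i, i) = s;
  }

  int it_used = 0;

  // phase I: minimize sum of artificials
  bool need_phase1 = false;
  for (int i = 0; i < m; ++i) if (w.x[n + i] > FEAS_TOL) need_phase1 = true;
  if (need_phase1) {
    vec c1 = zeros<vec>(w.N);
    c1.subvec(n, w.N - 1).ones();
    int st = iterate(w, c1, maxit, 1, it_used);
    if (st == ITLIMIT)
      return Rcpp::List::create(Rcpp::Named("status") = (int)ITLIMIT,
                                Rcpp::Named("objective") = NA_REAL,
                                Rcpp::Named("x") = Rcpp::NumericVector(n),
                                Rcpp::Named("iterations") = it_used);
    double art = 0;
    for (int i = 0; i < m; ++i) art += w.x[n + i];
    if (st == INFEASIBLE || art > FEAS_TOL * (1.0 + norm(b, "inf"))) {
      return Rcpp::List::create(Rcpp::Named("status") = (int)INFEASIBLE,
                                Rcpp::Named("objective") = NA_REAL,
                                Rcpp::Named("x") = Rcpp::NumericVector(n),
                                Rcpp::Named("iterations") = it_used);
    }
  }

  // pin artificials at zero for phase II
  for (int i = 0; i < m; ++i) { w.lb[n + i] = 0.0; w.ub[n + i] = 0.0; }
  for (int j = n; j < w.N; ++j) if (w.nb_at[j] != 0) w.x[j] = 0.0;

  vec c2 = zeros<vec>(w.N);
  c2.subvec(0, n - 1) = cost;
  int st = iterate(w, c2, maxit, 2, it_used);

  refactorize(w);  // polish basic values before reporting
  Rcpp::NumericVector xout(n);
  double obj = 0;
  for (int j = 0; j < n; ++j) { xout[j] = w.x[j]; obj += cost[j] * w.x[j]; }
  if (maximize) obj = -obj;

  return Rcpp::List::create(Rcpp::Named("status") = st,
                            Rcpp::Named("objective") = (st == OPTIMAL) ? obj : NA_REAL,
                            Rcpp::Named("x") = xout,
                            Rcpp::Named("iterations") = it_used);
}
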