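// Artificial-centering hit-and-run chain over the flux polytope
// { v : S v = 0, lb <= v <= ub, G v >= h }.
//
// Directions are differences between a random stored warmup point and the
// running center of mass, so every step stays inside the null space of S
// (up to floating-point drift); bound and inequality constraints enter via
// the step-size interval. Uses R's RNG so set.seed() governs the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

//' @noRd
// [[Rcpp::export(name = ".achr_chain")]]
arma::mat achr_chain(const arma::mat &warmup,   // k x n feasible points
                     const arma::vec &lb, const arma::vec &ub,
                     const arma::mat &G, const arma::vec &h,  // G v >= h (0 rows allowed)
                     int n_samples, int thinning) {
  const int k = warmup.n_rows, n = warmup.n_cols;
  const double EPS = 1e-12;
  if (k < 2) Rcpp::stop("achr_chain: need at least two warmup points");

  vec center = mean(warmup, 0).t();
  vec x = center;
  double count = k;
  const bool has_ineq = G.n_rows > 0;

  mat out(n_samples, n);
  int kept = 0, step = 0;
  Rcpp::RNGScope scope;

  // a rejected proposal (degenerate direction or empty step interval)
  // counts as a zero-length step, so chains on degenerate polytopes --
  // down to a single point -- still terminate
  auto tick = [&]() {
    if (++step % thinning == 0) {
      out.row(kept) = x.t();
      ++kept;
    }
  };

  while (kept < n_samples) {
    int idx = (int)std::floor(R::runif(0.0, 1.0) * k);
    if (idx >= k) idx = k - 1;
    vec d = warmup.row(idx).t() - center;
    double nd = norm(d);
    if (nd < 1e-10) { tick(); continue; }
    d /= nd;

    double tlo = -datum::inf, thi = datum::inf;
    for (int j = 0; j < n; ++j) {
      double dj = d[j];
      if (dj > EPS) {
        thi = std::min(thi, (ub[j] - x[j]) / dj);
        tlo = std::max(tlo, (lb[j] - x[j]) / dj);
      } else if (dj < -EPS) {
        thi = std::min(thi, (lb[j] - x[j]) / dj);
        tlo = std::max(tlo, (ub[j] - x[j]) / dj);
      }
    }
    if (has_ineq) {
      vec gd = G * d, gx = G * x;
      for (unsigned int r = 0; r < G.n_rows; ++r) {
        if (gd[r] > EPS)       tlo = std::max(tlo, (h[r] - gx[r]) / gd[r]);
        else if (gd[r] < -EPS) thi = std::min(thi, (h[r] - gx[r]) / gd[r]);
      }
    }
    if (!std::isfinite(tlo) || !std::isfinite(thi) || thi <= tlo) {
      tick();
      continue;
    }

    double t = tlo + R::runif(0.0, 1.0) * (thi - tlo);
    x += t * d;
    // guard against floating-point overshoot of the box
    for (int j = 0; j < n; ++j) {
      if (x[j] < lb[j]) x[j] = lb[j];
      if (x[j] > ub[j]) x[j] = ub[j];
    }
    center = (center * count + x) / (count + 1.0);
    count += 1.0;
    tick();
  }
  return out;
}
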