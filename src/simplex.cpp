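// Dense bounded-variable two-phase primal simplex.
//
// Solves  min c'x  subject to  A x = b,  lb <= x <= ub  (bounds may be
// +/-Inf, encoded as |bound| >= 1e29).  Community FBA/FVA problems are small
// (a few hundred rows/columns) and dense algebra with an explicitly
// maintained basis inverse is both fast and easy to audit.  Inequality rows
// are converted to equalities with slack columns on the R side.
//
// Anti-cycling: Dantzig pricing initially, permanent switch to Bland's rule
// after a fixed number of pivots.  The basis inverse is refreshed by direct
// inversion every REFACTOR_EVERY pivots to bound drift.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BINF = 1e29;       // bounds beyond this are infinite
static const double TOL_DJ = 1e-9;     // reduced-cost optimality tolerance
static const double TOL_PIV = 1e-10;   // minimum pivot magnitude
static const double TOL_FEAS = 1e-8;   // phase-1 residual tolerance
static const int REFACTOR_EVERY = 64;

namespace {

struct Tableau {
  mat A;            // m x n_tot (structural + artificial columns)
  vec b, lb, ub;    // n_tot bounds
  vec cost;         // current-phase costs
  uvec basis;       // m column indices
  ivec where;       // per column: -1 basic, 0 at lb, 1 at ub, 2 free at 0
  vec x;            // all column values
  mat Binv;
  int m, ntot;
  bool bland = false;
  int pivots_since_refactor = 0;

  bool refactor() {
    mat B = A.cols(basis);
    mat inv_;
    if (!inv(inv_, B)) return false;
    Binv = inv_;
    // recompute basic values from nonbasic bound values
    vec r = b;
    for (int j = 0; j < ntot; ++j) {
      if (where[j] != -1 && x[j] != 0.0) r -= A.col(j) * x[j];
    }
    vec xb = Binv * r;
    for (int i = 0; i < m; ++i) x[basis[i]] = xb[i];
    pivots_since_refactor = 0;
    return true;
  }

  // one simplex iteration on the current cost vector
  // returns: 0 pivoted/flipped, 1 optimal, 2 unbounded, 3 numerical failure
  int iterate() {
    vec y = Binv.t() * cost(basis);
    // reduced costs
    int enter = -1, dir = 0;
    double bestviol = TOL_DJ;
    for (int j = 0; j < ntot; ++j) {
      if (where[j] == -1) continue;
      if (ub[j] - lb[j] < 1e-12) continue;         // fixed variable
      double dj = cost[j] - dot(y, A.col(j));
      double viol, jdir;
      if (where[j] == 0) { viol = -dj; jdir = 1; }
      else if (where[j] == 1) { viol = dj; jdir = -1; }
      else { viol = std::abs(dj); jdir = (dj < 0) ? 1 : -1; }  // free
      if (viol > (bland ? TOL_DJ : bestviol)) {
        enter = j;
        dir = (int)jdir;
        if (bland) break;
        bestviol = viol;
      }
    }
    if (enter < 0) return 1;

    vec w = Binv * A.col(enter);
    // ratio test: entering moves by theta >= 0 in direction `dir`;
    // basic i changes by -dir * theta * w[i]
    double range = (ub[enter] >= BINF || lb[enter] <= -BINF)
                       ? datum::inf : (ub[enter] - lb[enter]);
    double theta = range;
    int leave = -1, leave_to = 0;
    double leave_piv = 0.0;
    for (int i = 0; i < m; ++i) {
      double delta = -dir * w[i];
      double cap = datum::inf;
      int to = 0;
      unsigned int bi = basis[i];
      if (delta > TOL_PIV) {
        if (ub[bi] < BINF) cap = (ub[bi] - x[bi]) / delta;
        to = 1;
      } else if (delta < -TOL_PIV) {
        if (lb[bi] > -BINF) cap = (x[bi] - lb[bi]) / (-delta);
        to = 0;
      } else {
        continue;
      }
      if (cap < 0) cap = 0;  // degenerate
      bool better = cap < theta - 1e-12;
      bool tie = std::abs(cap - theta) <= 1e-12;
      if (better ||
          (tie && leave >= 0 &&
           (bland ? (bi < basis[leave]) : (std::abs(w[i]) > std::abs(leave_piv))))) {
        theta = cap;
        leave = i;
        leave_to = to;
        leave_piv = w[i];
      }
    }
    if (!std::isfinite(theta)) return 2;  // unbounded ray

    // apply step
    x[enter] += dir * theta;
    for (int i = 0; i < m; ++i) x[basis[i]] -= dir * theta * w[i];

    if (leave < 0) {               // bound flip, no basis change
      where[enter] = (where[enter] == 0) ? 1 : 0;
      return 0;
    }
    unsigned int lv = basis[leave];
    where[lv] = leave_to;
    x[lv] = (leave_to == 1) ? ub[lv] : lb[lv];  // snap to bound
    basis[leave] = enter;
    where[enter] = -1;
    // product-form update of Binv
    double piv = w[leave];
    if (std::abs(piv) < TOL_PIV) return 3;
    Binv.row(leave) /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      if (w[i] != 0.0) Binv.row(i) -= w[i] * Binv.row(leave);
    }
    if (++pivots_since_refactor >= REFACTOR_EVERY) {
      if (!refactor()) return 3;
    }
    return 0;
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_solve_lp(const arma::mat& A, const arma::vec& b,
                        const arma::vec& c, const arma::vec& lb,
                        const arma::vec& ub) {
  const int m = A.n_rows, n = A.n_cols;
  Tableau T;
  T.m = m;
  T.ntot = n + m;
  T.A.set_size(m, T.ntot);
  T.A.cols(0, n - 1) = A;
  T.b = b;
  T.lb.set_size(T.ntot);
  T.ub.set_size(T.ntot);
  T.lb.head(n) = lb;
  T.ub.head(n) = ub;
  T.x.zeros(T.ntot);
  T.where.set_size(T.ntot);
  T.basis.set_size(m);

  // start nonbasic structurals at the finite bound nearest zero
  for (int j = 0; j < n; ++j) {
    double v;
    int wh;
    if (lb[j] > -BINF && (std::abs(lb[j]) <= std::abs(ub[j]) || ub[j] >= BINF)) {
      v = lb[j]; wh = 0;
    } else if (ub[j] < BINF) {
      v = ub[j]; wh = 1;
    } else {
      v = 0.0; wh = 2;  // free variable resting at 0
    }
    T.x[j] = v;
    T.where[j] = wh;
  }
  // artificial columns absorb the residual
  vec r = b - A * T.x.head(n);
  for (int i = 0; i < m; ++i) {
    int aj = n + i;
    T.A.col(aj).zeros();
    T.A(i, aj) = (r[i] >= 0) ? 1.0 : -1.0;
    T.x[aj] = std::abs(r[i]);
    T.lb[aj] = 0.0;
    T.ub[aj] = BINF * 10;
    T.where[aj] = -1;
    T.basis[i] = aj;
  }
  T.Binv = T.A.cols(T.basis);   // diagonal of +/-1
  T.Binv = inv(T.Binv);

  const int bland_after = 500 + 20 * (m + n);
  const int maxit = 5000 + 200 * (m + n);
  int iter = 0;

  // ---- phase 1 ----
  T.cost.zeros(T.ntot);
  for (int i = 0; i < m; ++i) T.cost[n + i] = 1.0;
  int st = 0;
  while (true) {
    if (iter > bland_after) T.bland = true;
    if (iter++ > maxit) { st = 3; break; }
    int rc = T.iterate();
    if (rc == 1) { st = 0; break; }
    if (rc == 2) { st = 4; break; }   // phase-1 unbounded: numerical trouble
    if (rc == 3) { st = 4; break; }
  }
  if (st == 3 || st == 4)
    return Rcpp::List::create(Rcpp::Named("status") = (st == 3) ? 3 : 4,
                              Rcpp::Named("x") = T.x.head(n),
                              Rcpp::Named("obj") = NA_REAL,
                              Rcpp::Named("iter") = iter);
  // re-derive the basic values from a fresh inverse before judging
  // feasibility: product-form drift must not decide it
  if (!T.refactor())
    return Rcpp::List::create(Rcpp::Named("status") = 4,
                              Rcpp::Named("x") = T.x.head(n),
                              Rcpp::Named("obj") = NA_REAL,
                              Rcpp::Named("iter") = iter);
  double p1 = 0.0;
  for (int i = 0; i < m; ++i) p1 += std::abs(T.x[n + i]);
  // true residual over all columns: immune to an ill-conditioned inverse
  double res = norm(T.b - T.A * T.x, "inf");
  if (!std::isfinite(res) || res > 1e-6 * (1.0 + norm(b, "inf")))
    return Rcpp::List::create(Rcpp::Named("status") = 4,
                              Rcpp::Named("x") = T.x.head(n),
                              Rcpp::Named("obj") = NA_REAL,
                              Rcpp::Named("iter") = iter);
  if (p1 > TOL_FEAS * (1.0 + norm(b, "inf")))
    return Rcpp::List::create(Rcpp::Named("status") = 1,
                              Rcpp::Named("x") = T.x.head(n),
                              Rcpp::Named("obj") = NA_REAL,
                              Rcpp::Named("iter") = iter);

  // drive residual artificials out of the basis where possible
  for (int i = 0; i < m; ++i) {
    if ((int)T.basis[i] < n) continue;
    rowvec ri = T.Binv.row(i) * A;   // row of Binv * A over structurals
    int jbest = -1;
    double best = 1e-7;
    for (int j = 0; j < n; ++j) {
      if (T.where[j] == -1) continue;
      if (std::abs(ri[j]) > best) { best = std::abs(ri[j]); jbest = j; }
    }
    if (jbest < 0) continue;  // redundant row; artificial stays basic at 0
    vec w = T.Binv * T.A.col(jbest);
    unsigned int lv = T.basis[i];
    T.where[lv] = 0;
    T.x[lv] = 0.0;
    T.basis[i] = jbest;
    T.where[jbest] = -1;
    double piv = w[i];
    T.Binv.row(i) /= piv;
    for (int k = 0; k < m; ++k) {
      if (k == i) continue;
      if (w[k] != 0.0) T.Binv.row(k) -= w[k] * T.Binv.row(i);
    }
  }
  // freeze artificials at zero
  for (int i = 0; i < m; ++i) {
    T.lb[n + i] = 0.0;
    T.ub[n + i] = 0.0;
    if (T.where[n + i] != -1) T.x[n + i] = 0.0;
  }

  // ---- phase 2 ----
  T.cost.zeros(T.ntot);
  T.cost.head(n) = c;
  T.bland = false;
  T.refactor();
  int iter0 = iter;
  bool clean = false;  // optimality must survive one refactorization
  while (true) {
    if (iter - iter0 > bland_after) T.bland = true;
    if (iter++ > 2 * maxit) { st = 3; break; }
    int rc = T.iterate();
    if (rc == 1) {
      if (clean) { st = 0; break; }
      if (!T.refactor()) { st = 4; break; }
      clean = true;
      continue;
    }
    clean = false;
    if (rc == 2) { st = 2; break; }
    if (rc == 3) { st = 4; break; }
  }
  if (st == 0) {
    double res2 = norm(T.b - T.A * T.x, "inf");
    if (!std::isfinite(res2) || res2 > 1e-6 * (1.0 + norm(b, "inf"))) st = 4;
  }
  double obj = dot(c, T.x.head(n));
  return Rcpp::List::create(Rcpp::Named("status") = st,
                            Rcpp::Named("x") = T.x.head(n),
                            Rcpp::Named("obj") = (st == 0) ? obj : NA_REAL,
                            Rcpp::Named("iter") = iter);
}
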