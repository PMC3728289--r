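// Dense two-phase primal simplex for the small/medium LPs assembled by
// buildLP(). Solves
//     min c'x  s.t.  A x {<=,=,>=} b,  0 <= x <= ub,
// with finite upper bounds rewritten as extra rows by the caller (solveLP).
// Dantzig pricing with a switch to Bland's rule after a burn-in to rule out
// cycling; tolerances chosen for problems whose coefficients are O(1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double TOL = 1e-9;     // pricing / feasibility tolerance
static const double PIVTOL = 1e-7;  // minimal admissible pivot magnitude

// Pivot the tableau T on (prow, pcol); basis bookkeeping in `basis`.
static void pivot(mat &T, std::vector<int> &basis, uword prow, uword pcol) {
  T.row(prow) /= T(prow, pcol);
  for (uword r = 0; r < T.n_rows; ++r) {
    if (r == prow) continue;
    double f = T(r, pcol);
    if (std::abs(f) > 0.0) T.row(r) -= f * T.row(prow);
  }
  basis[prow] = (int) pcol;
}

// Run simplex iterations on tableau T (last row = objective, last col = rhs)
// allowing columns [0, ncols_eligible) to enter. Returns 0 optimal,
// 1 unbounded, 2 iteration limit.
static int iterate(mat &T, std::vector<int> &basis, uword ncols_eligible,
                   int max_iter) {
  uword m = T.n_rows - 1;
  int iter = 0, bland_after = std::max(200, (int)(10 * m));
  while (true) {
    if (++iter > max_iter) return 2;
    bool bland = iter > bland_after;
    // pricing
    uword pcol = ncols_eligible;  // sentinel
    double best = -TOL;
    for (uword j = 0; j < ncols_eligible; ++j) {
      double rc = T(m, j);
      if (rc < -TOL) {
        if (bland) { pcol = j; break; }
        if (rc < best) { best = rc; pcol = j; }
      }
    }
    if (pcol == ncols_eligible) return 0;  // optimal
    // ratio test (Bland tie-break on basis index)
    uword prow = m;  // sentinel
    double best_ratio = datum::inf;
    for (uword r = 0; r < m; ++r) {
      double a = T(r, pcol);
      if (a > PIVTOL) {
        double ratio = T(r, T.n_cols - 1) / a;
        if (ratio < best_ratio - TOL ||
            (ratio < best_ratio + TOL && prow < m &&
             basis[r] < basis[prow])) {
          best_ratio = ratio;
          prow = r;
        }
      }
    }
    if (prow == m) return 1;  // unbounded
    pivot(T, basis, prow, pcol);
  }
}

// [[Rcpp::export(name = ".simplex_solve")]]
Rcpp::List simplex_solve(arma::vec c, arma::mat A, arma::ivec dir,
                         arma::vec b, int max_iter) {
  uword m = A.n_rows, n = A.n_cols;

  // flip rows to make rhs non-negative
  for (uword r = 0; r < m; ++r) {
    if (b(r) < 0) { A.row(r) *= -1.0; b(r) *= -1.0; dir(r) = -dir(r); }
  }

  // columns: n structural | slacks/surplus | artificials | rhs
  uword n_slack = 0, n_art = 0;
  for (uword r = 0; r < m; ++r) {
    if (dir(r) != 0) ++n_slack;                   // <= or >=
    if (dir(r) == 0 || dir(r) > 0) ++n_art;       // = or >= need artificial
  }
  uword ntot = n + n_slack + n_art;
  mat T(m + 1, ntot + 1, fill::zeros);
  T(span(0, m - 1), span(0, n - 1)) = A;
  T(span(0, m - 1), ntot) = b;

  std::vector<int> basis(m, -1);
  uword js = n, ja = n + n_slack;
  std::vector<uword> art_rows;
  for (uword r = 0; r < m; ++r) {
    if (dir(r) < 0) {            // <=  : slack enters basis
      T(r, js) = 1.0; basis[r] = (int) js; ++js;
    } else if (dir(r) > 0) {     // >=  : surplus + artificial
      T(r, js) = -1.0; ++js;
      T(r, ja) = 1.0; basis[r] = (int) ja; art_rows.push_back(r); ++ja;
    } else {                     // =   : artificial
      T(r, ja) = 1.0; basis[r] = (int) ja; art_rows.push_back(r); ++ja;
    }
  }

  int status;  // 0 optimal, 1 unbounded, 2 maxiter, 3 infeasible
  if (n_art > 0) {
    // phase 1: minimise sum of artificials
    for (uword j = n + n_slack; j < ntot; ++j) T(m, j) = 1.0;
    for (uword r : art_rows) T.row(m) -= T.row(r);  // price out basis
    status = iterate(T, basis, n + n_slack, max_iter);
    if (status == 1) status = 3;  // phase-1 unbounded cannot happen; guard
    if (status != 0)
      return Rcpp::List::create(Rcpp::Named("status") = status);
    if (T(m, ntot) < -10 * TOL || std::abs(T(m, ntot)) > 1e-7)
      return Rcpp::List::create(Rcpp::Named("status") = 3);
    // drive any artificial still basic (at zero) out of the basis,
    // pivoting on the largest admissible entry for stability; a row
    // with no admissible entry is a redundant combination (phase 1
    // left it at level ~0) and is dropped
    for (uword r = 0; r < m; ++r) {
      if (basis[r] >= (int)(n + n_slack)) {
        uword jbest = 0; double abest = 0.0;
        for (uword j = 0; j < n + n_slack; ++j) {
          double a = std::abs(T(r, j));
          if (a > abest) { abest = a; jbest = j; }
        }
        if (abest > PIVTOL) pivot(T, basis, r, jbest);
        else T.row(r).zeros();
      }
    }
  }

  // phase 2 objective
  T.row(m).zeros();
  for (uword j = 0; j < n; ++j) T(m, j) = c(j);
  for (uword r = 0; r < m; ++r) {
    int bj = basis[r];
    if (bj >= 0 && bj < (int) n && std::abs(c(bj)) > 0.0)
      T.row(m) -= c(bj) * T.row(r);
  }
  status = iterate(T, basis, n + n_slack, max_iter);

  vec x(n, fill::zeros);
  if (status == 0) {
    for (uword r = 0; r < m; ++r)
      if (basis[r] >= 0 && basis[r] < (int) n)
        x(basis[r]) = T(r, ntot);
  }
  return Rcpp::List::create(
      Rcpp::Named("status") = status,
      Rcpp::Named("x") = x,
      Rcpp::Named("value") = dot(c, x));
}
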