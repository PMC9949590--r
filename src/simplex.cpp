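#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase primal tableau simplex for
//     min c'x   s.t.  A x (sense) b,   x >= 0
// sense per row: -1 (<=), 0 (=), +1 (>=).
// Degeneracy is endemic in flux-balance LPs, so Dantzig pricing switches to
// Bland's rule after a fixed number of pivots to guarantee termination.
//
// status: 0 optimal, 2 infeasible, 3 unbounded, 4 iteration limit.

static int choose_entering(const std::vector<double> &obj, int ncols,
                           const std::vector<char> &eligible, bool bland,
                           double tol) {
  if (bland) {
    for (int j = 0; j < ncols; ++j)
      if (eligible[j] && obj[j] < -tol) return j;
    return -1;
  }
  int best = -1;
  double most = -tol;
  for (int j = 0; j < ncols; ++j)
    if (eligible[j] && obj[j] < most) { most = obj[j]; best = j; }
  return best;
}

// [[Rcpp::export(name = ".simplex_core")]]
List simplex_core(NumericMatrix A, NumericVector b, NumericVector cobj,
                  IntegerVector sense, double tol = 1e-9,
                  double feas_tol = 1e-7, int max_iter = 50000,
                  int bland_after = 5000) {
  const int m = A.nrow(), n = A.ncol();

  // Count auxiliary columns: slack for <=, surplus+artificial for >=,
  // artificial for =.  Rows are first normalized to b >= 0.
  std::vector<int> rsign(m, 1);
  std::vector<int> sns(m);
  for (int i = 0; i < m; ++i) {
    sns[i] = sense[i];
    if (b[i] < 0) { rsign[i] = -1; sns[i] = -sns[i]; }
  }
  int nslack = 0, nart = 0;
  for (int i = 0; i < m; ++i) {
    if (sns[i] != 0) ++nslack;
    if (sns[i] >= 0) ++nart;
  }
  const int N = n + nslack + nart;

  // Tableau: m rows x (N + 1) columns (last col = rhs), plus objective rows
  // kept as flat vectors.
  std::vector<std::vector<double> > T(m, std::vector<double>(N + 1, 0.0));
  std::vector<int> basis(m, -1);
  std::vector<char> is_art(N, 0);

  int sl = n, ar = n + nslack;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T[i][j] = rsign[i] * A(i, j);
    T[i][N] = rsign[i] * b[i];
    if (sns[i] == -1) {            // <= : slack basic
      T[i][sl] = 1.0; basis[i] = sl; ++sl;
    } else if (sns[i] == 1) {      // >= : surplus + artificial basic
      T[i][sl] = -1.0; ++sl;
      T[i][ar] = 1.0; is_art[ar] = 1; basis[i] = ar; ++ar;
    } else {                       // = : artificial basic
      T[i][ar] = 1.0; is_art[ar] = 1; basis[i] = ar; ++ar;
    }
  }

  std::vector<char> eligible(N, 1);
  std::vector<double> obj(N + 1, 0.0);

  // ---- helpers -------------------------------------------------------
  auto pivot = [&](int pr, int pc) {
    double piv = T[pr][pc];
    std::vector<double> &row = T[pr];
    for (int j = 0; j <= N; ++j) row[j] /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == pr) continue;
      double f = T[i][pc];
      if (std::fabs(f) < tol) { T[i][pc] = 0.0; continue; }
      std::vector<double> &ri = T[i];
      for (int j = 0; j <= N; ++j) ri[j] -= f * row[j];
      ri[pc] = 0.0;
    }
    double f = obj[pc];
    if (std::fabs(f) > 0.0) {
      for (int j = 0; j <= N; ++j) obj[j] -= f * row[j];
      obj[pc] = 0.0;
    }
    basis[pr] = pc;
  };

  auto run_phase = [&](int &iter) -> int {
    // returns 0 done-optimal, 3 unbounded, 4 iter limit
    while (true) {
      if (++iter > max_iter) return 4;
      bool bland = iter > bland_after;
      int pc = choose_entering(obj, N, eligible, bland, tol);
      if (pc < 0) return 0;
      int pr = -1;
      double best = R_PosInf;
      for (int i = 0; i < m; ++i) {
        double a = T[i][pc];
        if (a > tol) {
          double ratio = T[i][N] / a;
          if (ratio < best - 1e-12 ||
              (ratio < best + 1e-12 && (pr < 0 || basis[i] < basis[pr]))) {
            best = ratio; pr = i;
          }
        }
      }
      if (pr < 0) return 3;
      pivot(pr, pc);
      if (iter % 512 == 0) Rcpp::checkUserInterrupt();
    }
  };

  int iter = 0;

  // ---- Phase 1 -------------------------------------------------------
  if (nart > 0) {
    std::fill(obj.begin(), obj.end(), 0.0);
    for (int j = 0; j < N; ++j) if (is_art[j]) obj[j] = 1.0;
    // price out basic artificials
    for (int i = 0; i < m; ++i) {
      if (is_art[basis[i]]) {
        for (int j = 0; j <= N; ++j) obj[j] -= T[i][j];
      }
    }
    int rc = run_phase(iter);
    if (rc == 4) return List::create(_["status"] = 4);
    double p1 = -obj[N];  // phase-1 objective value
    if (p1 > feas_tol * (1.0 + std::fabs(p1)) && p1 > feas_tol)
      return List::create(_["status"] = 2, _["phase1"] = p1);
    // drive artificials out of the basis where possible
    for (int i = 0; i < m; ++i) {
      if (is_art[basis[i]]) {
        int pc = -1;
        for (int j = 0; j < N; ++j)
          if (!is_art[j] && std::fabs(T[i][j]) > 1e-7) { pc = j; break; }
        if (pc >= 0) pivot(i, pc);
        // else: redundant row; artificial stays basic at (numerically) zero
      }
    }
    for (int j = 0; j < N; ++j) if (is_art[j]) eligible[j] = 0;
  }

  // ---- Phase 2 -------------------------------------------------------
  std::fill(obj.begin(), obj.end(), 0.0);
  for (int j = 0; j < n; ++j) obj[j] = cobj[j];
  for (int i = 0; i < m; ++i) {
    int bj = basis[i];
    double cb = (bj < n) ? cobj[bj] : 0.0;
    if (cb != 0.0)
      for (int j = 0; j <= N; ++j) obj[j] -= cb * T[i][j];
  }
  int rc = run_phase(iter);
  if (rc == 3) return List::create(_["status"] = 3);
  if (rc == 4) return List::create(_["status"] = 4);

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) x[basis[i]] = T[i][N];
  double objval = 0.0;
  for (int j = 0; j < n; ++j) objval += cobj[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["obj"] = objval,
                      _["iter"] = iter);
}
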