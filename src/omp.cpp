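// Orthogonal matching pursuit over a fixed dictionary, batched over signal
// columns. Stops at max_atoms or when the residual L2 norm drops below tol.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_omp(NumericMatrix D, NumericMatrix X, int max_atoms,
                      double tol) {
  int d = D.nrow(), K = D.ncol(), N = X.ncol();
  NumericMatrix C(K, N);
  if (max_atoms > K) max_atoms = K;
  std::vector<double> r(d), corr(K);
  std::vector<int> sel;
  std::vector<double> G;      // Cholesky factor (lower), row-major s x s
  std::vector<double> coef;
  for (int j = 0; j < N; ++j) {
    double xn = 0;
    for (int i = 0; i < d; ++i) { r[i] = X(i, j); xn += r[i] * r[i]; }
    if (std::sqrt(xn) <= tol) continue;
    sel.clear();
    for (int it = 0; it < max_atoms; ++it) {
      // most correlated unused atom
      int best = -1; double bv = 0;
      for (int k = 0; k < K; ++k) {
        double c = 0;
        for (int i = 0; i < d; ++i) c += D(i, k) * r[i];
        corr[k] = c;
        double a = std::fabs(c);
        bool used = false;
        for (size_t s = 0; s < sel.size(); ++s) if (sel[s] == k) used = true;
        if (!used && a > bv) { bv = a; best = k; }
      }
      if (best < 0 || bv < 1e-12) break;
      sel.push_back(best);
      int s = sel.size();
      // solve least squares on selected atoms via normal equations
      std::vector<double> A(s * s), b(s);
      for (int p = 0; p < s; ++p) {
        for (int q = 0; q <= p; ++q) {
          double g = 0;
          for (int i = 0; i < d; ++i) g += D(i, sel[p]) * D(i, sel[q]);
          A[p * s + q] = g; A[q * s + p] = g;
        }
        double bb = 0;
        for (int i = 0; i < d; ++i) bb += D(i, sel[p]) * X(i, j);
        b[p] = bb;
      }
      // Cholesky solve with ridge for safety
      for (int p = 0; p < s; ++p) A[p * s + p] += 1e-10;
      G.assign(s * s, 0.0);
      bool ok = true;
      for (int p = 0; p < s && ok; ++p) {
        for (int q = 0; q <= p; ++q) {
          double sum = A[p * s + q];
          for (int m = 0; m < q; ++m) sum -= G[p * s + m] * G[q * s + m];
          if (p == q) {
            if (sum <= 0) { ok = false; break; }
            G[p * s + p] = std::sqrt(sum);
          } else G[p * s + q] = sum / G[q * s + q];
        }
      }
      if (!ok) { sel.pop_back(); break; }
      coef.assign(s, 0.0);
      for (int p = 0; p < s; ++p) {
        double sum = b[p];
        for (int m = 0; m < p; ++m) sum -= G[p * s + m] * coef[m];
        coef[p] = sum / G[p * s + p];
      }
      for (int p = s - 1; p >= 0; --p) {
        double sum = coef[p];
        for (int m = p + 1; m < s; ++m) sum -= G[m * s + p] * coef[m];
        coef[p] = sum / G[p * s + p];
      }
      // residual
      double rn = 0;
      for (int i = 0; i < d; ++i) {
        double v = X(i, j);
        for (int p = 0; p < s; ++p) v -= D(i, sel[p]) * coef[p];
        r[i] = v; rn += v * v;
      }
      if (std::sqrt(rn) <= tol) break;
    }
    for (size_t p = 0; p < sel.size(); ++p) C(sel[p], j) = coef[p];
  }
  return C;
}
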