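#include <Rcpp.h>
using namespace Rcpp;

// Weighted Whittaker smoother with a second-difference penalty:
// solve (W + lambda * D'D) z = W y, where D is the (n-2) x n second
// difference operator and W = diag(w). The system matrix is symmetric
// positive definite and pentadiagonal, so we factor it with a banded
// Cholesky (bandwidth 2) in O(n).
//
// [[Rcpp::export]]
NumericVector whittaker_solve(NumericVector y, NumericVector w, double lambda) {
  const int n = y.size();
  if (w.size() != n) stop("y and w must have the same length");
  if (n < 3) return clone(y);

  // Band storage: d0 = main diagonal, d1 = first sub-diagonal, d2 = second.
  std::vector<double> d0(n), d1(n, 0.0), d2(n, 0.0);

  // Assemble W + lambda * D'D. Row i of D (i = 0..n-3) is
  // [.. 1 -2 1 ..] starting at column i.
  for (int i = 0; i < n; ++i) d0[i] = w[i];
  for (int i = 0; i < n - 2; ++i) {
    d0[i]     += lambda;          // 1*1
    d0[i + 1] += 4.0 * lambda;    // (-2)*(-2)
    d0[i + 2] += lambda;          // 1*1
    d1[i]     += -2.0 * lambda;   // 1*(-2)   -> (i+1, i)
    d1[i + 1] += -2.0 * lambda;   // (-2)*1   -> (i+2, i+1)
    d2[i]     += lambda;          // 1*1      -> (i+2, i)
  }

  // Banded Cholesky: A = L L', L lower-triangular with bandwidth 2.
  // l0 = diag(L), l1 = first sub-diagonal, l2 = second sub-diagonal.
  std::vector<double> l0(n), l1(n, 0.0), l2(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double a10 = (i >= 1) ? l1[i - 1] : 0.0;  // L[i, i-1]
    double a20 = (i >= 2) ? l2[i - 2] : 0.0;  // L[i, i-2]
    double v = d0[i] - a10 * a10 - a20 * a20;
    if (v <= 0.0) stop("whittaker_solve: matrix not positive definite");
    l0[i] = std::sqrt(v);
    if (i + 1 < n) {
      double s = d1[i];
      if (i >= 1) s -= l1[i - 1] * l2[i - 1];  // L[i,i-1] * L[i+1,i-1]
      l1[i] = s / l0[i];                       // L[i+1, i]
    }
    if (i + 2 < n) {
      l2[i] = d2[i] / l0[i];                   // L[i+2, i]
    }
  }

  // Solve L u = W y (forward), then L' z = u (backward).
  NumericVector z(n);
  std::vector<double> u(n);
  for (int i = 0; i < n; ++i) {
    double s = w[i] * y[i];
    if (i >= 1) s -= l1[i - 1] * u[i - 1];
    if (i >= 2) s -= l2[i - 2] * u[i - 2];
    u[i] = s / l0[i];
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = u[i];
    if (i + 1 < n) s -= l1[i] * z[i + 1];
    if (i + 2 < n) s -= l2[i] * z[i + 2];
    z[i] = s / l0[i];
  }
  return z;
}
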