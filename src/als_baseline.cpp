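#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Asymmetric least squares baseline (Eilers-style): iteratively solve
//   (W + smoothness * D2' D2) zhat = W y
// with asymmetric weights w_i = asym if y_i > z_i else 1 - asym.
// D2 is the second-difference operator, so the system matrix is
// pentadiagonal; solved with a banded (bandwidth 2) LDL^T factorization.

static void als_one(const double *y, int m, double lambda, double asym,
                    int iters, double *z) {
  std::vector<double> d0(m), d1(m - 1), d2(m - 2);  // system bands
  std::vector<double> s0(m), s1(m - 1), s2(m - 2);  // D2'D2 bands
  std::vector<double> w(m, 1.0), rhs(m);
  std::vector<double> l1(m - 1), l2(m - 2), diag(m), tmp(m);

  // bands of D2'D2 for the (m-2) x m second-difference matrix
  for (int i = 0; i < m; ++i) s0[i] = 6.0;
  if (m >= 1) s0[0] = 1.0;
  if (m >= 2) { s0[m - 1] = 1.0; }
  if (m >= 2) { s0[1] = 5.0; s0[m - 2] = 5.0; }
  if (m == 3) s0[1] = 4.0;  // middle point of a 3-channel spectrum
  for (int i = 0; i < m - 1; ++i) s1[i] = -4.0;
  if (m >= 2) { s1[0] = -2.0; s1[m - 2] = -2.0; }
  for (int i = 0; i < m - 2; ++i) s2[i] = 1.0;

  for (int iter = 0; iter < iters; ++iter) {
    for (int i = 0; i < m; ++i) {
      d0[i] = w[i] + lambda * s0[i];
      rhs[i] = w[i] * y[i];
    }
    for (int i = 0; i < m - 1; ++i) d1[i] = lambda * s1[i];
    for (int i = 0; i < m - 2; ++i) d2[i] = lambda * s2[i];

    // banded LDL^T factorization (bandwidth 2)
    for (int i = 0; i < m; ++i) {
      double di = d0[i];
      if (i >= 1) di -= l1[i - 1] * l1[i - 1] * diag[i - 1];
      if (i >= 2) di -= l2[i - 2] * l2[i - 2] * diag[i - 2];
      diag[i] = di;
      if (i + 1 < m) {
        double v = d1[i];
        if (i >= 1) v -= l1[i - 1] * l2[i - 1] * diag[i - 1];
        l1[i] = v / diag[i];
      }
      if (i + 2 < m) l2[i] = d2[i] / diag[i];
    }
    // forward solve L t = rhs
    for (int i = 0; i < m; ++i) {
      double v = rhs[i];
      if (i >= 1) v -= l1[i - 1] * tmp[i - 1];
      if (i >= 2) v -= l2[i - 2] * tmp[i - 2];
      tmp[i] = v;
    }
    // diagonal and backward solve L^T z = D^{-1} t
    for (int i = m - 1; i >= 0; --i) {
      double v = tmp[i] / diag[i];
      if (i + 1 < m) v -= l1[i] * z[i + 1];
      if (i + 2 < m) v -= l2[i] * z[i + 2];
      z[i] = v;
    }
    for (int i = 0; i < m; ++i) w[i] = (y[i] > z[i]) ? asym : 1.0 - asym;
  }
}

// [[Rcpp::export(name = ".als_baseline_cpp")]]
NumericMatrix als_baseline_cpp(const NumericMatrix &Yv, double smoothness,
                               double asymmetry, int iters) {
  const int nr = Yv.nrow(), m = Yv.ncol();
  NumericMatrix Z(nr, m);
  std::vector<double> yi(m), zi(m);
  for (int r = 0; r < nr; ++r) {
    for (int j = 0; j < m; ++j) yi[j] = Yv(r, j);
    als_one(yi.data(), m, smoothness, asymmetry, iters, zi.data());
    for (int j = 0; j < m; ++j) Z(r, j) = zi[j];
  }
  return Z;
}
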