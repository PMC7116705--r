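#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Solve the symmetric p x p system A b = rhs by Gaussian elimination with
// partial pivoting. Returns false when (numerically) singular.
static bool solve_sym(int p, std::vector<double> A, std::vector<double> &rhs) {
  for (int col = 0; col < p; ++col) {
    int piv = col;
    double amax = std::fabs(A[col * p + col]);
    for (int r = col + 1; r < p; ++r) {
      double v = std::fabs(A[r * p + col]);
      if (v > amax) { amax = v; piv = r; }
    }
    if (amax < 1e-300) return false;
    if (piv != col) {
      for (int c = 0; c < p; ++c) std::swap(A[col * p + c], A[piv * p + c]);
      std::swap(rhs[col], rhs[piv]);
    }
    double d = A[col * p + col];
    for (int r = col + 1; r < p; ++r) {
      double f = A[r * p + col] / d;
      if (f == 0.0) continue;
      for (int c = col; c < p; ++c) A[r * p + c] -= f * A[col * p + c];
      rhs[r] -= f * rhs[col];
    }
  }
  for (int r = p - 1; r >= 0; --r) {
    double s = rhs[r];
    for (int c = r + 1; c < p; ++c) s -= A[r * p + c] * rhs[c];
    rhs[r] = s / A[r * p + r];
  }
  return true;
}

// Windowed likelihood-ratio scan for a change in AR structure.
//
// For each centre t in [h, T-h] (1-based), fits AR models by conditional
// least squares (the conditional Gaussian MLE, profile variance RSS/n) to the
// left half, right half and full window at a common order selected by BIC on
// the full window, and forms
//   LS_h(t) = (1/h) [ L_left(theta1) + L_right(theta2) - L_full(theta) ].
// The three conditional log-likelihood sums are arranged so that the full
// window decomposes exactly into the two halves at common parameters (the
// right half conditions on the last p observations of the left half), which
// makes LS_h(t) >= 0 an algebraic identity up to round-off.
//
// All lagged cross-moments come from prefix sums of lag-d products, so each
// window costs O(pmax^3) independent of h.
//
// [[Rcpp::export]]
List scan_profile_cpp(NumericVector x, int h, int pmax) {
  const int T = x.size();
  if (2 * h >= T) stop("window radius too large: need 2h < T");
  if (pmax < 0 || pmax >= h) stop("invalid maximum order");

  // P[d][i] = sum_{s=d+1..i} x_s * x_{s-d}  (1-based s), i = 0..T
  std::vector< std::vector<double> > P(pmax + 1, std::vector<double>(T + 1, 0.0));
  for (int d = 0; d <= pmax; ++d) {
    double acc = 0.0;
    for (int s = 1; s <= T; ++s) {
      if (s > d) acc += x[s - 1] * x[s - d - 1];
      P[d][s] = acc;
    }
  }
  // sum over t' in [a, b] of x_{t'-j} x_{t'-k}, 1-based, caller guarantees
  // all indices fall inside 1..T
  auto S = [&](int a, int b, int j, int k) -> double {
    if (j > k) std::swap(j, k);
    const int d = k - j;
    return P[d][b - j] - P[d][a - j - 1];
  };

  // Conditional least-squares fit of order m on evaluation range [a, b];
  // returns RSS (or -1 on numerical failure) and n = b - a + 1.
  auto fit_rss = [&](int a, int b, int m) -> double {
    double s00 = S(a, b, 0, 0);
    if (m == 0) return s00;
    std::vector<double> A(m * m);
    std::vector<double> v(m), rhs(m);
    for (int j = 1; j <= m; ++j) {
      v[j - 1] = S(a, b, 0, j);
      rhs[j - 1] = -v[j - 1];
      for (int k = j; k <= m; ++k) {
        double val = S(a, b, j, k);
        A[(j - 1) * m + (k - 1)] = val;
        A[(k - 1) * m + (j - 1)] = val;
      }
    }
    if (!solve_sym(m, A, rhs)) return -1.0;
    double rss = s00;
    for (int j = 0; j < m; ++j) rss += rhs[j] * v[j];
    return rss;
  };

  auto loglik = [](double rss, int n) -> double {
    if (rss <= 0.0 || n <= 0) return NA_REAL;
    return -0.5 * n * (std::log(2.0 * M_PI * rss / n) + 1.0);
  };

  const int npos = T - 2 * h + 1;
  NumericVector values(npos);
  IntegerVector orders(npos);
  int ndeg = 0;

  for (int i = 0; i < npos; ++i) {
    const int t = h + i;          // centre, 1-based
    const int a0 = t - h + 1;
    const int b0 = t + h;

    // BIC order selection on the full window
    int best = 0;
    double best_bic = R_PosInf;
    for (int m = 0; m <= pmax; ++m) {
      const int n = b0 - (a0 + m) + 1;
      double rss = fit_rss(a0 + m, b0, m);
      if (rss <= 0.0) continue;
      double bic = n * std::log(rss / n) + (m + 1) * std::log((double) n);
      if (bic < best_bic - 1e-12) { best_bic = bic; best = m; }
    }
    const int p = best;

    double rssL = fit_rss(a0 + p, t, p);
    double rssR = fit_rss(t + 1, b0, p);
    double rssF = fit_rss(a0 + p, b0, p);
    double lL = loglik(rssL, t - (a0 + p) + 1);
    double lR = loglik(rssR, b0 - t);
    double lF = loglik(rssF, b0 - (a0 + p) + 1);

    double v;
    if (ISNA(lL) || ISNA(lR) || ISNA(lF)) {
      v = 0.0;
      ++ndeg;
    } else {
      v = (lL + lR - lF) / h;
      if (v < 0.0) v = 0.0;   // round-off only: the ratio is >= 0 exactly
    }
    values[i] = v;
    orders[i] = p;
  }

  return List::create(_["values"] = values,
                      _["orders"] = orders,
                      _["degenerate"] = ndeg);
}
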