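#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Determinant of an n x n matrix (n <= 6) by Gaussian elimination with
// partial pivoting. `a` is row-major and is destroyed.
static double det_small(double* a, int n) {
  double det = 1.0;
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double best = std::fabs(a[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(a[i * n + k]);
      if (v > best) { best = v; piv = i; }
    }
    if (best == 0.0) return 0.0;
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(a[k * n + j], a[piv * n + j]);
      det = -det;
    }
    det *= a[k * n + k];
    for (int i = k + 1; i < n; ++i) {
      double f = a[i * n + k] / a[k * n + k];
      for (int j = k; j < n; ++j) a[i * n + j] -= f * a[k * n + j];
    }
  }
  return det;
}

// Volume of the convex hull of n points in d dimensions (2 <= d <= 6) by
// brute-force facet enumeration: every d-subset whose hyperplane has all
// remaining points strictly on one side is a facet (points in general
// position); the hull volume is the sum of simplex volumes spanned by each
// facet and the centroid.  Complexity O(C(n,d) * (d^4 + n)): adequate for
// the community sizes met here (n up to ~60).
//
// Returns -1 when a point not in the defining subset lies on a candidate
// facet's hyperplane (degenerate configuration); the caller is expected to
// perturb and retry.
// [[Rcpp::export]]
double hull_volume_cpp(NumericMatrix X, double tol = 1e-9) {
  const int n = X.nrow(), d = X.ncol();
  if (d < 2 || d > 6) stop("hull_volume_cpp: dimension must be in 2..6");
  if (n < d + 1) return 0.0;

  // flat row-major copy, centroid, coordinate scale
  std::vector<double> xs((size_t)n * d);
  std::vector<double> m(d, 0.0);
  double scale = 0.0;
  for (int j = 0; j < d; ++j) {
    double lo = X(0, j), hi = X(0, j);
    for (int i = 0; i < n; ++i) {
      double v = X(i, j);
      xs[(size_t)i * d + j] = v;
      m[j] += v;
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    m[j] /= n;
    if (hi - lo > scale) scale = hi - lo;
  }
  if (scale == 0.0) return 0.0;

  double dfact = 1.0;
  for (int k = 2; k <= d; ++k) dfact *= k;
  const double normal_tol = tol * std::pow(scale, d - 1);

  // fixed pseudo-random order for the one-sidedness scan: random subsets
  // see mixed signs almost immediately
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  unsigned long long s = 88172645463325252ULL;
  for (int i = n - 1; i > 0; --i) {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    std::swap(order[i], order[s % (i + 1)]);
  }

  std::vector<int> idx(d);
  for (int k = 0; k < d; ++k) idx[k] = k;
  std::vector<char> in_subset(n, 0);
  for (int k = 0; k < d; ++k) in_subset[idx[k]] = 1;

  std::vector<double> sub((d - 1) * (d - 1)), normal(d), simp(d * d);
  double vol = 0.0;

  while (true) {
    const double* p0 = &xs[(size_t)idx[0] * d];

    // generalized cross product: normal_j = (-1)^j det(diffs minus col j)
    double nnorm2 = 0.0;
    for (int j = 0; j < d; ++j) {
      for (int r = 1; r < d; ++r) {
        const double* pr = &xs[(size_t)idx[r] * d];
        int cc = 0;
        for (int c = 0; c < d; ++c) {
          if (c == j) continue;
          sub[(r - 1) * (d - 1) + cc++] = pr[c] - p0[c];
        }
      }
      double dj = det_small(sub.data(), d - 1);
      normal[j] = ((j % 2) == 0) ? dj : -dj;
      nnorm2 += normal[j] * normal[j];
    }

    if (nnorm2 > normal_tol * normal_tol) {
      double c0 = 0.0;
      for (int j = 0; j < d; ++j) c0 += normal[j] * p0[j];
      const double eps = tol * std::sqrt(nnorm2) * scale;

      bool pos = false, neg = false, on = false;
      for (int oi = 0; oi < n; ++oi) {
        const int i = order[oi];
        if (in_subset[i]) continue;
        const double* pi = &xs[(size_t)i * d];
        double sdot = -c0;
        for (int j = 0; j < d; ++j) sdot += normal[j] * pi[j];
        if (sdot > eps) { pos = true; if (neg) break; }
        else if (sdot < -eps) { neg = true; if (pos) break; }
        else on = true;
      }
      if (!(pos && neg)) {
        if (on) return -1.0;  // degenerate: caller must perturb
        for (int r = 1; r < d; ++r) {
          const double* pr = &xs[(size_t)idx[r] * d];
          for (int j = 0; j < d; ++j)
            simp[(r - 1) * d + j] = pr[j] - p0[j];
        }
        for (int j = 0; j < d; ++j)
          simp[(d - 1) * d + j] = m[j] - p0[j];
        vol += std::fabs(det_small(simp.data(), d)) / dfact;
      }
    }

    // next combination (lexicographic)
    int k = d - 1;
    while (k >= 0 && idx[k] == n - d + k) --k;
    if (k < 0) break;
    for (int t = k; t < d; ++t) in_subset[idx[t]] = 0;
    ++idx[k];
    for (int t = k + 1; t < d; ++t) idx[t] = idx[t - 1] + 1;
    for (int t = k; t < d; ++t) in_subset[idx[t]] = 1;
  }
  return vol;
}
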