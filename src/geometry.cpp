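// Brute-force neighbourhood kernels for 3-D point clouds.
// Sizes here are a few thousand points, where exact brute force beats
// tree structures; ties resolve to the lowest index throughout.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// k nearest neighbours of each query row among ref rows (1-based indices,
// distance-sorted, ties to the lowest index); self matches are kept.
// [[Rcpp::export(name = ".cppKnn")]]
IntegerMatrix cppKnn(NumericMatrix ref, NumericMatrix query, int k) {
  const int n = ref.nrow(), m = query.nrow();
  if (k > n) stop("k exceeds the number of reference points");
  IntegerMatrix out(m, k);
  std::vector<double> rx(n), ry(n), rz(n);
  for (int i = 0; i < n; ++i) {
    rx[i] = ref(i, 0); ry[i] = ref(i, 1); rz[i] = ref(i, 2);
  }
  std::vector<std::pair<double, int> > d(n);
  for (int q = 0; q < m; ++q) {
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    for (int i = 0; i < n; ++i) {
      double dx = rx[i] - qx, dy = ry[i] - qy, dz = rz[i] - qz;
      d[i] = std::make_pair(dx * dx + dy * dy + dz * dz, i);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) out(q, j) = d[j].second + 1;
  }
  return out;
}

// ball query capped at the k nearest: k nearest within radius, shortfall
// padded by repeating the nearest found.
// [[Rcpp::export(name = ".cppBallKnn")]]
IntegerMatrix cppBallKnn(NumericMatrix centers, NumericMatrix points,
                         int k, double radius) {
  const int n = points.nrow(), m = centers.nrow();
  const int kk = std::min(k, n);
  const double r2 = radius * radius;
  IntegerMatrix out(m, k);
  std::vector<std::pair<double, int> > d(n);
  for (int q = 0; q < m; ++q) {
    const double qx = centers(q, 0), qy = centers(q, 1), qz = centers(q, 2);
    for (int i = 0; i < n; ++i) {
      double dx = points(i, 0) - qx, dy = points(i, 1) - qy,
             dz = points(i, 2) - qz;
      d[i] = std::make_pair(dx * dx + dy * dy + dz * dz, i);
    }
    std::partial_sort(d.begin(), d.begin() + kk, d.end());
    int filled = 0;
    for (int j = 0; j < kk && d[j].first <= r2; ++j) {
      out(q, j) = d[j].second + 1;
      ++filled;
    }
    if (filled == 0) { out(q, 0) = d[0].second + 1; filled = 1; }
    for (int j = filled; j < k; ++j) out(q, j) = out(q, 0);
  }
  return out;
}

// greedy max-min farthest point sampling from a given start (1-based)
// [[Rcpp::export(name = ".cppFps")]]
IntegerVector cppFps(NumericMatrix pos, int m, int start) {
  const int n = pos.nrow();
  if (m > n) stop("m exceeds the number of points");
  IntegerVector sel(m);
  std::vector<double> minD(n);
  int cur = start - 1;
  sel[0] = start;
  // column-major access via pointers
  const double* X = &pos(0, 0);
  const double* Y = X + n;
  const double* Z = Y + n;
  for (int i = 0; i < n; ++i) {
    double dx = X[i] - X[cur], dy = Y[i] - Y[cur], dz = Z[i] - Z[cur];
    minD[i] = dx * dx + dy * dy + dz * dz;
  }
  for (int j = 1; j < m; ++j) {
    int best = 0;
    double bd = -1.0;
    for (int i = 0; i < n; ++i) {
      if (minD[i] > bd) { bd = minD[i]; best = i; }
    }
    sel[j] = best + 1;
    for (int i = 0; i < n; ++i) {
      double dx = X[i] - X[best], dy = Y[i] - Y[best], dz = Z[i] - Z[best];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < minD[i]) minD[i] = d;
    }
  }
  return sel;
}
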