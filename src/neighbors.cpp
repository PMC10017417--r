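#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdlib>
#include <algorithm>
using namespace Rcpp;

// Uniform-grid spatial index over 3D points. Cell keys pack the three
// (offset) cell indices into one 64-bit integer; coordinates are in mm and
// clouds span < 2^20 cells per axis by a wide margin.
static inline long long cell_key(long long ix, long long iy, long long iz) {
  const long long B = 1LL << 20;
  return (ix + B) | ((iy + B) << 21) | ((iz + B) << 42);
}

struct Grid {
  double cell;
  double ox, oy, oz;
  std::unordered_map<long long, std::vector<int> > cells;
};

static void grid_build(Grid &g, const NumericMatrix &pts, double cell) {
  int n = pts.nrow();
  g.cell = cell;
  g.ox = g.oy = g.oz = 0.0;
  if (n > 0) {
    g.ox = pts(0, 0); g.oy = pts(0, 1); g.oz = pts(0, 2);
    for (int i = 1; i < n; ++i) {
      if (pts(i, 0) < g.ox) g.ox = pts(i, 0);
      if (pts(i, 1) < g.oy) g.oy = pts(i, 1);
      if (pts(i, 2) < g.oz) g.oz = pts(i, 2);
    }
  }
  g.cells.reserve(n * 2 + 8);
  for (int i = 0; i < n; ++i) {
    long long ix = (long long)std::floor((pts(i, 0) - g.ox) / cell);
    long long iy = (long long)std::floor((pts(i, 1) - g.oy) / cell);
    long long iz = (long long)std::floor((pts(i, 2) - g.oz) / cell);
    g.cells[cell_key(ix, iy, iz)].push_back(i);
  }
}

// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix data, NumericMatrix query, double r) {
  int m = query.nrow();
  List out(m);
  if (data.nrow() == 0 || r <= 0) {
    for (int q = 0; q < m; ++q) out[q] = IntegerVector(0);
    return out;
  }
  Grid g;
  grid_build(g, data, r);
  double r2 = r * r;
  std::vector<int> hits;
  for (int q = 0; q < m; ++q) {
    hits.clear();
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    long long ix = (long long)std::floor((qx - g.ox) / g.cell);
    long long iy = (long long)std::floor((qy - g.oy) / g.cell);
    long long iz = (long long)std::floor((qz - g.oz) / g.cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            g.cells.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == g.cells.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t t = 0; t < v.size(); ++t) {
            int j = v[t];
            double a = data(j, 0) - qx, b = data(j, 1) - qy, c = data(j, 2) - qz;
            if (a * a + b * b + c * c <= r2) hits.push_back(j + 1);
          }
        }
    std::sort(hits.begin(), hits.end());
    out[q] = IntegerVector(hits.begin(), hits.end());
  }
  return out;
}

// k nearest-neighbor distances for each query point, exact, by expanding
// grid shells. exclude_self skips data index == query index (use only when
// query and data are the same matrix in the same order).
// [[Rcpp::export]]
NumericMatrix cpp_knn_dist(NumericMatrix data, NumericMatrix query, int k,
                           bool exclude_self) {
  int n = data.nrow(), m = query.nrow();
  int avail = exclude_self ? n - 1 : n;
  if (k < 1 || avail < k) stop("not enough points for k nearest neighbors");
  // heuristic cell size: expect a handful of points per cell
  double lox = data(0, 0), hix = lox, loy = data(0, 1), hiy = loy,
         loz = data(0, 2), hiz = loz;
  for (int i = 1; i < n; ++i) {
    lox = std::min(lox, data(i, 0)); hix = std::max(hix, data(i, 0));
    loy = std::min(loy, data(i, 1)); hiy = std::max(hiy, data(i, 1));
    loz = std::min(loz, data(i, 2)); hiz = std::max(hiz, data(i, 2));
  }
  double ex = hix - lox, ey = hiy - loy, ez = hiz - loz;
  double vol = std::max(ex, 1e-9) * std::max(ey, 1e-9) * std::max(ez, 1e-9);
  double cell = std::cbrt(vol * std::max(k, 4) / (double)n);
  double maxext = std::max(ex, std::max(ey, ez));
  if (!(cell > 0) || cell > maxext) cell = std::max(maxext, 1e-9);
  // degenerate (planar/collinear) extents make the density heuristic
  // collapse; keep the grid at a sane resolution per axis
  cell = std::max(cell, std::max(maxext, 1e-9) / 64.0);
  Grid g;
  grid_build(g, data, cell);
  // clouds of thin structures fill their bounding box sparsely: shrink the
  // cell until occupied cells hold ~k points each (at most 3 rebuilds)
  for (int pass = 0; pass < 3; ++pass) {
    double occ = (double)n / (double)g.cells.size();
    double target = std::max(k, 4);
    if (occ <= 6.0 * target) break;
    cell *= std::cbrt(target / occ);
    g.cells.clear();
    grid_build(g, data, cell);
  }
  long long maxshell = (long long)std::ceil(maxext / cell) + 1;

  NumericMatrix out(m, k);
  std::vector<double> d2s;
  for (int q = 0; q < m; ++q) {
    d2s.clear();
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    long long ix = (long long)std::floor((qx - g.ox) / cell);
    long long iy = (long long)std::floor((qy - g.oy) / cell);
    long long iz = (long long)std::floor((qz - g.oz) / cell);
    // extend the shell budget when the query lies outside the data box
    long long nx = (long long)std::floor((hix - g.ox) / cell);
    long long ny = (long long)std::floor((hiy - g.oy) / cell);
    long long nz = (long long)std::floor((hiz - g.oz) / cell);
    long long off = 0;
    off = std::max(off, std::max(-ix, ix - nx));
    off = std::max(off, std::max(-iy, iy - ny));
    off = std::max(off, std::max(-iz, iz - nz));
    long long qshell = maxshell + off;
    double kth = R_PosInf;
    for (long long s = 0; s <= qshell; ++s) {
      if ((int)d2s.size() >= k) {
        // cells at Chebyshev distance s have min distance >= (s-1)*cell
        double bound = (double)(s - 1) * cell;
        if (bound > 0 && kth <= bound * bound) break;
      }
      for (long long dx = -s; dx <= s; ++dx)
        for (long long dy = -s; dy <= s; ++dy)
          for (long long dz = -s; dz <= s; ++dz) {
            if (std::max(std::llabs(dx), std::max(std::llabs(dy), std::llabs(dz))) != s)
              continue;
            std::unordered_map<long long, std::vector<int> >::const_iterator it =
              g.cells.find(cell_key(ix + dx, iy + dy, iz + dz));
            if (it == g.cells.end()) continue;
            const std::vector<int> &v = it->second;
            for (size_t t = 0; t < v.size(); ++t) {
              int j = v[t];
              if (exclude_self && j == q) continue;
              double a = data(j, 0) - qx, b = data(j, 1) - qy,
                     c = data(j, 2) - qz;
              d2s.push_back(a * a + b * b + c * c);
            }
          }
      if ((int)d2s.size() >= k) {
        std::nth_element(d2s.begin(), d2s.begin() + (k - 1), d2s.end());
        kth = d2s[k - 1];
      }
    }
    std::partial_sort(d2s.begin(), d2s.begin() + k, d2s.end());
    for (int j = 0; j < k; ++j) out(q, j) = std::sqrt(d2s[j]);
  }
  return out;
}
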