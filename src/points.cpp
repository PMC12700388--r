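#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// uniform-grid spatial hash for fixed-radius neighbor queries
struct CellGrid {
  double cell;
  std::unordered_map<long long, std::vector<int>> cells;
  static long long key(long long cx, long long cy, long long cz) {
    // interleave-free packing; coordinates are bounded in practice
    return ((cx + 1048576) << 42) ^ ((cy + 1048576) << 21) ^ (cz + 1048576);
  }
  void build(const NumericMatrix& pts, double cell_size) {
    cell = cell_size;
    cells.clear();
    for (int i = 0; i < pts.nrow(); ++i) {
      long long cx = (long long)std::floor(pts(i, 0) / cell);
      long long cy = (long long)std::floor(pts(i, 1) / cell);
      long long cz = (long long)std::floor(pts(i, 2) / cell);
      cells[key(cx, cy, cz)].push_back(i);
    }
  }
  template <typename F>
  void visit(double x, double y, double z, F f) const {
    long long cx = (long long)std::floor(x / cell);
    long long cy = (long long)std::floor(y / cell);
    long long cz = (long long)std::floor(z / cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(cx + dx, cy + dy, cz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) f(j);
        }
  }
};

// All unordered point pairs at Euclidean distance strictly below eps.
// Returns 1-based indices i < j and the distances.
// [[Rcpp::export]]
List radius_pairs_cpp(NumericMatrix pts, double eps) {
  CellGrid grid;
  grid.build(pts, eps);
  std::vector<int> ii, jj;
  std::vector<double> dd;
  int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    grid.visit(x, y, z, [&](int j) {
      if (j <= i) return;
      double dx = pts(j, 0) - x, dy = pts(j, 1) - y, dz = pts(j, 2) - z;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < eps * eps) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(std::sqrt(d2));
      }
    });
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["dist"] = wrap(dd));
}

// Pairs (a in A, b in B) at distance strictly below eps; 1-based indices.
// [[Rcpp::export]]
List cross_radius_pairs_cpp(NumericMatrix A, NumericMatrix B, double eps) {
  CellGrid grid;
  grid.build(B, eps);
  std::vector<int> ia, ib;
  std::vector<double> dd;
  for (int i = 0; i < A.nrow(); ++i) {
    double x = A(i, 0), y = A(i, 1), z = A(i, 2);
    grid.visit(x, y, z, [&](int j) {
      double dx = B(j, 0) - x, dy = B(j, 1) - y, dz = B(j, 2) - z;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < eps * eps) {
        ia.push_back(i + 1);
        ib.push_back(j + 1);
        dd.push_back(std::sqrt(d2));
      }
    });
  }
  return List::create(_["i"] = wrap(ia), _["j"] = wrap(ib), _["dist"] = wrap(dd));
}

// Flat-kernel mean shift: every point seeds an iteration of
// x <- mean(points within `bandwidth` of x) (closed ball) until the
// displacement drops below tol or max_iter is reached. Returns the
// converged mode of every seed.
// [[Rcpp::export]]
NumericMatrix mean_shift_modes_cpp(NumericMatrix pts, double bandwidth,
                                   double tol, int max_iter) {
  CellGrid grid;
  grid.build(pts, bandwidth);
  int n = pts.nrow();
  NumericMatrix modes(n, 3);
  double bw2 = bandwidth * bandwidth;
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    for (int it = 0; it < max_iter; ++it) {
      double sx = 0, sy = 0, sz = 0;
      int cnt = 0;
      grid.visit(x, y, z, [&](int j) {
        double dx = pts(j, 0) - x, dy = pts(j, 1) - y, dz = pts(j, 2) - z;
        if (dx * dx + dy * dy + dz * dz <= bw2) {
          sx += pts(j, 0); sy += pts(j, 1); sz += pts(j, 2);
          ++cnt;
        }
      });
      if (cnt == 0) break;
      double nxp = sx / cnt, nyp = sy / cnt, nzp = sz / cnt;
      double dx = nxp - x, dy = nyp - y, dz = nzp - z;
      x = nxp; y = nyp; z = nzp;
      if (std::sqrt(dx * dx + dy * dy + dz * dz) < tol) break;
    }
    modes(i, 0) = x; modes(i, 1) = y; modes(i, 2) = z;
  }
  return modes;
}

// Count of input points within a closed ball of radius `bandwidth` around
// each query (used for mode ranking when merging).
// [[Rcpp::export]]
IntegerVector ball_counts_cpp(NumericMatrix pts, NumericMatrix queries,
                              double bandwidth) {
  CellGrid grid;
  grid.build(pts, bandwidth);
  double bw2 = bandwidth * bandwidth;
  IntegerVector out(queries.nrow());
  for (int i = 0; i < queries.nrow(); ++i) {
    double x = queries(i, 0), y = queries(i, 1), z = queries(i, 2);
    int cnt = 0;
    grid.visit(x, y, z, [&](int j) {
      double dx = pts(j, 0) - x, dy = pts(j, 1) - y, dz = pts(j, 2) - z;
      if (dx * dx + dy * dy + dz * dz <= bw2) ++cnt;
    });
    out[i] = cnt;
  }
  return out;
}

// Mark voxels whose center lies within `radius` of any of the given points
// (0-based continuous coordinates). Used to rasterize balls and tubes.
// [[Rcpp::export]]
IntegerVector paint_balls_cpp(IntegerVector dims, NumericMatrix centers,
                              double radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  double r2 = radius * radius;
  for (int c = 0; c < centers.nrow(); ++c) {
    double cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    int x0 = std::max(0, (int)std::ceil(cx - radius));
    int x1 = std::min(nx - 1, (int)std::floor(cx + radius));
    int y0 = std::max(0, (int)std::ceil(cy - radius));
    int y1 = std::min(ny - 1, (int)std::floor(cy + radius));
    int z0 = std::max(0, (int)std::ceil(cz - radius));
    int z1 = std::min(nz - 1, (int)std::floor(cz + radius));
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double dx = x - cx, dy = y - cy, dz = z - cz;
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = 1;
        }
  }
  return out;
}
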