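#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas), Felzenszwalb &
// Huttenlocher. Samples sit at integer positions `pos`; the envelope is
// queried at positions 0..nq-1.
static void dt1d(const std::vector<double>& f, const std::vector<double>& pos,
                 std::vector<double>& d, int nq) {
  const double INF = std::numeric_limits<double>::infinity();
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      int p = v[k];
      if (f[p] == INF) { // drop unusable parabola
        --k;
        if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; s = -INF; break; }
        continue;
      }
      s = ((f[q] + pos[q] * pos[q]) - (f[p] + pos[p] * pos[p])) /
          (2.0 * pos[q] - 2.0 * pos[p]);
      if (s <= z[k]) { --k; if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; s = -INF; break; } }
      else break;
    }
    if (v[k] != q) {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  int j = 0;
  for (int q = 0; q < nq; ++q) {
    while (z[j + 1] < (double)q) ++j;
    int p = v[j];
    double dx = (double)q - pos[p];
    d[q] = dx * dx + f[p];
  }
}

// Squared Euclidean distance transform of a 3D mask: for every voxel the
// squared distance to the nearest zero voxel, where everything outside the
// volume also counts as background (the transform "grows from the borders"
// when no interior background exists). Array layout: x fastest, index
// x + nx*(y + ny*z).
// [[Rcpp::export]]
NumericVector edt_sq_cpp(IntegerVector mask, IntegerVector dims) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);

  // pass along x, with virtual background samples at x = -1 and x = nx
  {
    int m = nx + 2;
    std::vector<double> f(m), pos(m), d(nx);
    for (int i = 0; i < m; ++i) pos[i] = (double)(i - 1);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        f[0] = 0.0; f[m - 1] = 0.0;
        for (int x = 0; x < nx; ++x)
          f[x + 1] = mask[base + x] ? INF : 0.0;
        dt1d(f, pos, d, nx);
        for (int x = 0; x < nx; ++x) out[base + x] = d[x];
      }
    }
  }
  // pass along y, borders at y = -1 and y = ny
  {
    int m = ny + 2;
    std::vector<double> f(m), pos(m), d(ny);
    for (int i = 0; i < m; ++i) pos[i] = (double)(i - 1);
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) {
        f[0] = 0.0; f[m - 1] = 0.0;
        for (int y = 0; y < ny; ++y)
          f[y + 1] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        dt1d(f, pos, d, ny);
        for (int y = 0; y < ny; ++y)
          out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[y];
      }
    }
  }
  // pass along z, borders at z = -1 and z = nz
  {
    int m = nz + 2;
    std::vector<double> f(m), pos(m), d(nz);
    for (int i = 0; i < m; ++i) pos[i] = (double)(i - 1);
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        f[0] = 0.0; f[m - 1] = 0.0;
        for (int z = 0; z < nz; ++z)
          f[z + 1] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        dt1d(f, pos, d, nz);
        for (int z = 0; z < nz; ++z)
          out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[z];
      }
    }
  }
  return out;
}
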