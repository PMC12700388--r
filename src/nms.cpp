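#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Trilinear interpolation with coordinates clamped to the volume bounds
// (replicate padding beyond the last voxel center).
static inline double trilinear(const NumericVector& S, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  R_xlen_t sY = nx, sZ = (R_xlen_t)nx * ny;
  R_xlen_t b = x0 + sY * y0 + sZ * z0;
  double c000 = S[b],            c100 = S[b + 1];
  double c010 = S[b + sY],       c110 = S[b + 1 + sY];
  double c001 = S[b + sZ],       c101 = S[b + 1 + sZ];
  double c011 = S[b + sY + sZ],  c111 = S[b + 1 + sY + sZ];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
double trilinear_cpp(NumericVector S, IntegerVector dims,
                     double x, double y, double z) {
  return trilinear(S, dims[0], dims[1], dims[2], x, y, z);
}

// Non-maximum suppression along the top (3 - d) Hessian eigenvector
// directions. A voxel with saliency >= threshold joins the dimension-d
// skeleton iff its value strictly exceeds both probes at +/- delta along
// every checked direction. The one-voxel border is excluded. Returns the
// 0-based voxel coordinates of skeleton points, ordered by linear index.
// [[Rcpp::export]]
IntegerMatrix nms_cpp(NumericVector S, IntegerVector dims,
                      NumericMatrix vectors, int d, double delta,
                      double threshold) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ndir = 3 - d;
  std::vector<int> keep;
  for (int z = 1; z < nz - 1; ++z) {
    for (int y = 1; y < ny - 1; ++y) {
      R_xlen_t row = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 1; x < nx - 1; ++x) {
        R_xlen_t i = row + x;
        double si = S[i];
        if (!(si >= threshold)) continue;
        bool ok = true;
        for (int j = 0; j < ndir && ok; ++j) {
          double vx = vectors(i, 3 * j), vy = vectors(i, 3 * j + 1),
                 vz = vectors(i, 3 * j + 2);
          double sm = trilinear(S, nx, ny, nz, x - delta * vx, y - delta * vy,
                                z - delta * vz);
          double sp = trilinear(S, nx, ny, nz, x + delta * vx, y + delta * vy,
                                z + delta * vz);
          ok = (si > sm) && (si > sp);
        }
        if (ok) {
          keep.push_back(x); keep.push_back(y); keep.push_back(z);
        }
      }
    }
  }
  int m = (int)(keep.size() / 3);
  IntegerMatrix pts(m, 3);
  for (int r = 0; r < m; ++r) {
    pts(r, 0) = keep[3 * r];
    pts(r, 1) = keep[3 * r + 1];
    pts(r, 2) = keep[3 * r + 2];
  }
  return pts;
}
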