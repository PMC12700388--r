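#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// mirrored (half-sample symmetric) index: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

static void conv1d_axis(const std::vector<double>& src, std::vector<double>& dst,
                        const std::vector<double>& w, int radius,
                        int nx, int ny, int nz, int axis) {
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  int nax = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  R_xlen_t sax = (axis == 0) ? sx : (axis == 1) ? sy : sz;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int i = (axis == 0) ? x : (axis == 1) ? y : z;
        R_xlen_t base = sx * x + sy * y + sz * z - sax * i;
        double acc = 0.0;
        for (int k = -radius; k <= radius; ++k) {
          int j = reflect_idx(i + k, nax);
          acc += w[k + radius] * src[base + sax * j];
        }
        dst[sx * x + sy * y + sz * z] = acc;
      }
    }
  }
}

// Separable isotropic Gaussian smoothing with mirrored boundaries; kernel
// truncated at 4 sigma and renormalized to unit sum.
// [[Rcpp::export]]
NumericVector gauss3_cpp(NumericVector vol, IntegerVector dims, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int radius = (int)std::ceil(4.0 * sigma);
  std::vector<double> w(2 * radius + 1);
  double s = 0.0;
  for (int k = -radius; k <= radius; ++k) {
    w[k + radius] = std::exp(-0.5 * (double)k * k / (sigma * sigma));
    s += w[k + radius];
  }
  for (double& wi : w) wi /= s;

  std::vector<double> a(n), b(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = vol[i];
  conv1d_axis(a, b, w, radius, nx, ny, nz, 0);
  conv1d_axis(b, a, w, radius, nx, ny, nz, 1);
  conv1d_axis(a, b, w, radius, nx, ny, nz, 2);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = b[i];
  return out;
}
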