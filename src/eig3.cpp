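#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Analytic eigenvalues of a symmetric 3x3 matrix via the trigonometric
// (Cardano) solution of the characteristic cubic. w unsorted.
static void eigvals_cardano(const double A[6], double w[3]) {
  // A = (a11, a22, a33, a12, a13, a23)
  double m = (A[0] + A[1] + A[2]) / 3.0;
  double k00 = A[0] - m, k11 = A[1] - m, k22 = A[2] - m;
  double a12 = A[3], a13 = A[4], a23 = A[5];
  double p = (k00 * k00 + k11 * k11 + k22 * k22) / 6.0 +
             (a12 * a12 + a13 * a13 + a23 * a23) / 3.0;
  double q = 0.5 * (k00 * k11 * k22 + 2.0 * a12 * a13 * a23 -
                    k00 * a23 * a23 - k11 * a13 * a13 - k22 * a12 * a12);
  if (p <= 0.0) { w[0] = w[1] = w[2] = m; return; }
  double sp = std::sqrt(p);
  double arg = q / (sp * sp * sp);
  if (arg > 1.0) arg = 1.0;
  if (arg < -1.0) arg = -1.0;
  double phi = std::acos(arg) / 3.0;
  w[0] = m + 2.0 * sp * std::cos(phi);
  w[1] = m + 2.0 * sp * std::cos(phi - 2.0 * M_PI / 3.0);
  w[2] = m + 2.0 * sp * std::cos(phi + 2.0 * M_PI / 3.0);
}

// Cyclic Jacobi rotations; robust fallback for (near-)degenerate spectra.
// V columns are eigenvectors of the input.
static void eig_jacobi(const double A[6], double w[3], double V[3][3]) {
  double M[3][3] = {{A[0], A[3], A[4]}, {A[3], A[1], A[5]}, {A[4], A[5], A[2]}};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) V[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 64; ++sweep) {
    double off = std::fabs(M[0][1]) + std::fabs(M[0][2]) + std::fabs(M[1][2]);
    if (off == 0.0) break;
    for (int p = 0; p < 2; ++p) {
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(M[p][q]) < 1e-300) continue;
        double theta = (M[q][q] - M[p][p]) / (2.0 * M[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double mkp = M[k][p], mkq = M[k][q];
          M[k][p] = c * mkp - s * mkq;
          M[k][q] = s * mkp + c * mkq;
        }
        for (int k = 0; k < 3; ++k) {
          double mpk = M[p][k], mqk = M[q][k];
          M[p][k] = c * mpk - s * mqk;
          M[q][k] = s * mpk + c * mqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c * vkp - s * vkq;
          V[k][q] = s * vkp + c * vkq;
        }
      }
    }
  }
  for (int i = 0; i < 3; ++i) w[i] = M[i][i];
}

static inline void cross3(const double a[3], const double b[3], double c[3]) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double norm3(const double a[3]) {
  return std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
}

// Eigenvector of (A - w I) as the largest cross product of two of its rows;
// returns the squared norm achieved (tiny => ill-conditioned).
static double eigvec_cross(const double A[6], double w, double v[3]) {
  double r0[3] = {A[0] - w, A[3], A[4]};
  double r1[3] = {A[3], A[1] - w, A[5]};
  double r2[3] = {A[4], A[5], A[2] - w};
  double c01[3], c02[3], c12[3];
  cross3(r0, r1, c01);
  cross3(r0, r2, c02);
  cross3(r1, r2, c12);
  double n01 = c01[0]*c01[0]+c01[1]*c01[1]+c01[2]*c01[2];
  double n02 = c02[0]*c02[0]+c02[1]*c02[1]+c02[2]*c02[2];
  double n12 = c12[0]*c12[0]+c12[1]*c12[1]+c12[2]*c12[2];
  const double* best = c01;
  double nb = n01;
  if (n02 > nb) { best = c02; nb = n02; }
  if (n12 > nb) { best = c12; nb = n12; }
  double nn = std::sqrt(nb);
  if (nn > 0) { v[0] = best[0] / nn; v[1] = best[1] / nn; v[2] = best[2] / nn; }
  else { v[0] = 1.0; v[1] = 0.0; v[2] = 0.0; }
  return nb;
}

// Full decomposition of one matrix; vectors as rows of V[k][*] matching w[k].
// Relative eigenvalue gaps below `degtol` trigger the Jacobi fallback.
static void eig3_one(const double A[6], double w[3], double V[3][3],
                     double degtol) {
  eigvals_cardano(A, w);
  double scale = std::max({std::fabs(w[0]), std::fabs(w[1]), std::fabs(w[2]), 1e-300});
  double gap = std::min({std::fabs(w[0] - w[1]), std::fabs(w[0] - w[2]),
                         std::fabs(w[1] - w[2])});
  bool fallback = gap < degtol * scale;
  if (!fallback) {
    double nb0 = eigvec_cross(A, w[0], V[0]);
    double nb1 = eigvec_cross(A, w[1], V[1]);
    if (nb0 < 1e-24 * scale * scale * scale * scale ||
        nb1 < 1e-24 * scale * scale * scale * scale)
      fallback = true;
    else {
      // re-orthogonalize and complete the right-handed triad
      double d = V[1][0]*V[0][0] + V[1][1]*V[0][1] + V[1][2]*V[0][2];
      for (int k = 0; k < 3; ++k) V[1][k] -= d * V[0][k];
      double n1 = norm3(V[1]);
      if (n1 < 1e-8) fallback = true;
      else {
        for (int k = 0; k < 3; ++k) V[1][k] /= n1;
        cross3(V[0], V[1], V[2]);
      }
    }
  }
  if (fallback) {
    double Vc[3][3];
    eig_jacobi(A, w, Vc);
    for (int k = 0; k < 3; ++k)
      for (int i = 0; i < 3; ++i) V[k][i] = Vc[i][k];
  }
}

// Per-voxel eigen-decomposition of a symmetric tensor field, sorted by
// descending |eigenvalue| (stable for ties). Returns values (n x 3) and
// eigenvectors (n x 9, rows are v1x v1y v1z v2x ... v3z).
// [[Rcpp::export]]
List eig3_field_cpp(NumericVector sxx, NumericVector syy, NumericVector szz,
                    NumericVector sxy, NumericVector sxz, NumericVector syz,
                    double degtol = 1e-6) {
  R_xlen_t n = sxx.size();
  NumericMatrix values(n, 3);
  NumericMatrix vectors(n, 9);
  double A[6], w[3], V[3][3];
  for (R_xlen_t i = 0; i < n; ++i) {
    A[0] = sxx[i]; A[1] = syy[i]; A[2] = szz[i];
    A[3] = sxy[i]; A[4] = sxz[i]; A[5] = syz[i];
    for (int k = 0; k < 6; ++k) {
      if (!std::isfinite(A[k]))
        stop("non-finite tensor component at voxel (linear index) %ld", (long)(i + 1));
    }
    eig3_one(A, w, V, degtol);
    int ord[3] = {0, 1, 2};
    std::stable_sort(ord, ord + 3, [&w](int a, int b) {
      return std::fabs(w[a]) > std::fabs(w[b]);
    });
    for (int k = 0; k < 3; ++k) {
      values(i, k) = w[ord[k]];
      for (int c = 0; c < 3; ++c) vectors(i, 3 * k + c) = V[ord[k]][c];
    }
  }
  return List::create(_["values"] = values, _["vectors"] = vectors);
}
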