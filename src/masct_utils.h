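#ifndef MASCT_UTILS_H
#define MASCT_UTILS_H

#include <Rcpp.h>
#include <cmath>

// Volume geometry: world = origin + D * (index * spacing), indices 0-based,
// D orthonormal (inverse == transpose). Arrays are column-major (nx, ny, nz).
struct Geom {
  int n[3];
  double sp[3];
  double o[3];
  double d[9]; // column-major 3x3
};

inline Geom make_geom(const Rcpp::IntegerVector& dim,
                      const Rcpp::NumericVector& spacing,
                      const Rcpp::NumericVector& origin,
                      const Rcpp::NumericMatrix& dir) {
  Geom g;
  for (int a = 0; a < 3; ++a) {
    g.n[a] = dim[a]; g.sp[a] = spacing[a]; g.o[a] = origin[a];
  }
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) g.d[r + 3 * c] = dir(r, c);
  return g;
}

inline void idx_to_world(const Geom& g, double i, double j, double k, double* p) {
  const double v0 = i * g.sp[0], v1 = j * g.sp[1], v2 = k * g.sp[2];
  p[0] = g.o[0] + g.d[0] * v0 + g.d[3] * v1 + g.d[6] * v2;
  p[1] = g.o[1] + g.d[1] * v0 + g.d[4] * v1 + g.d[7] * v2;
  p[2] = g.o[2] + g.d[2] * v0 + g.d[5] * v1 + g.d[8] * v2;
}

inline void world_to_idx(const Geom& g, const double* p, double* v) {
  const double q0 = p[0] - g.o[0], q1 = p[1] - g.o[1], q2 = p[2] - g.o[2];
  v[0] = (g.d[0] * q0 + g.d[1] * q1 + g.d[2] * q2) / g.sp[0];
  v[1] = (g.d[3] * q0 + g.d[4] * q1 + g.d[5] * q2) / g.sp[1];
  v[2] = (g.d[6] * q0 + g.d[7] * q1 + g.d[8] * q2) / g.sp[2];
}

inline bool in_support(const int* n, double x, double y, double z) {
  const double e = 1e-9;
  return x >= -e && x <= n[0] - 1 + e &&
         y >= -e && y <= n[1] - 1 + e &&
         z >= -e && z <= n[2] - 1 + e;
}

inline double sample_linear(const double* a, const int* n,
                            double x, double y, double z) {
  if (x < 0) x = 0; if (x > n[0] - 1) x = n[0] - 1;
  if (y < 0) y = 0; if (y > n[1] - 1) y = n[1] - 1;
  if (z < 0) z = 0; if (z > n[2] - 1) z = n[2] - 1;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > n[0] - 2) i0 = n[0] >= 2 ? n[0] - 2 : 0;
  if (j0 > n[1] - 2) j0 = n[1] >= 2 ? n[1] - 2 : 0;
  if (k0 > n[2] - 2) k0 = n[2] >= 2 ? n[2] - 2 : 0;
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  const int i1 = n[0] >= 2 ? i0 + 1 : i0;
  const int j1 = n[1] >= 2 ? j0 + 1 : j0;
  const int k1 = n[2] >= 2 ? k0 + 1 : k0;
  const R_xlen_t nx = n[0], nxy = (R_xlen_t)n[0] * n[1];
#define V(I, J, K) a[(I) + nx * (J) + nxy * (K)]
  const double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
  const double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
  const double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
  const double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
#undef V
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

inline double sample_nearest(const double* a, const int* n,
                             double x, double y, double z) {
  int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5),
      k = (int)std::floor(z + 0.5);
  if (i < 0) i = 0; if (i > n[0] - 1) i = n[0] - 1;
  if (j < 0) j = 0; if (j > n[1] - 1) j = n[1] - 1;
  if (k < 0) k = 0; if (k > n[2] - 1) k = n[2] - 1;
  return a[(R_xlen_t)i + (R_xlen_t)n[0] * j + (R_xlen_t)n[0] * n[1] * k];
}

#endif
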