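#include "masct_utils.h"
using namespace Rcpp;

// Cubic B-spline free-form deformation. The control lattice lives in the
// full-resolution fixed image's local millimetre frame q = D_ref^T (p - o_ref)
// so the same coefficients are valid at every pyramid level. Node spacing is
// `delta` mm per axis; coefficients are world-frame displacements in mm.
// Per axis, ncoef = n_intervals + 3 and node l sits at q = (l - 1) * delta.

static inline void bspline_weights(double u, double* b) {
  const double u2 = u * u, u3 = u2 * u;
  b[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  b[1] = (3 * u3 - 6 * u2 + 4) / 6.0;
  b[2] = (-3 * u3 + 3 * u2 + 3 * u + 1) / 6.0;
  b[3] = u3 / 6.0;
}

struct Lattice {
  int nc[3];
  double delta[3];
  Geom ref; // full-res fixed geometry defining the q frame
};

// locate q along one axis: returns base coefficient index, fills 4 weights
static inline int locate(const Lattice& L, int axis, double q, double* w) {
  double t = q / L.delta[axis];
  const int m = L.nc[axis] - 3; // number of intervals
  if (t < 0) t = 0;
  if (t > m - 1e-9) t = m - 1e-9;
  int i = (int)std::floor(t);
  if (i > m - 1) i = m - 1;
  bspline_weights(t - i, w);
  return i; // coefficients i .. i+3
}

static inline void q_of_world(const Geom& ref, const double* p, double* q) {
  const double a = p[0] - ref.o[0], b = p[1] - ref.o[1], c = p[2] - ref.o[2];
  q[0] = ref.d[0] * a + ref.d[1] * b + ref.d[2] * c;
  q[1] = ref.d[3] * a + ref.d[4] * b + ref.d[5] * c;
  q[2] = ref.d[6] * a + ref.d[7] * b + ref.d[8] * c;
}

// MSE cost and analytic gradient of the rigid + B-spline mapping
// phi(x) = R x + t + d(x), moving sampled with trilinear interpolation.
// Out-of-support samples take `fill` with zero gradient. The bending term is
// lambda * sum of squared second differences of the coefficient lattice.
// [[Rcpp::export]]
List cpp_bspline_cost_grad(NumericVector fixed, IntegerVector fdim,
                           NumericVector fspacing, NumericVector forigin,
                           NumericMatrix fdir, NumericVector moving,
                           IntegerVector mdim, NumericVector mspacing,
                           NumericVector morigin, NumericMatrix mdir,
                           NumericVector gx, NumericVector gy, NumericVector gz,
                           NumericMatrix rot, NumericVector trans,
                           NumericVector coef, IntegerVector cdim,
                           NumericVector delta, IntegerVector refdim,
                           NumericVector refspacing, NumericVector reforigin,
                           NumericMatrix refdir, double lambda, double fill,
                           int want_grad) {
  Geom gf = make_geom(fdim, fspacing, forigin, fdir);
  Geom gm = make_geom(mdim, mspacing, morigin, mdir);
  Lattice L;
  L.ref = make_geom(refdim, refspacing, reforigin, refdir);
  for (int a = 0; a < 3; ++a) { L.nc[a] = cdim[a]; L.delta[a] = delta[a]; }
  const R_xlen_t ncoef = (R_xlen_t)L.nc[0] * L.nc[1] * L.nc[2];
  if (coef.size() != 3 * ncoef) stop("coefficient vector size mismatch");
  const double* cf = coef.begin();
  NumericVector grad(want_grad ? 3 * ncoef : 0);
  double* gr = want_grad ? REAL(grad) : NULL;
  double Rm[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) Rm[r + 3 * c] = rot(r, c);
  const double* F = fixed.begin();
  const double* M = moving.begin();
  const double* GX = gx.begin();
  const double* GY = gy.begin();
  const double* GZ = gz.begin();
  const R_xlen_t N = (R_xlen_t)gf.n[0] * gf.n[1] * gf.n[2];
  double sse = 0;
  double p[3], q[3], v[3], phi[3];
  double wx[4], wy[4], wz[4];
  R_xlen_t idx = 0;
  const R_xlen_t cx = 1, cy = L.nc[0], cz = (R_xlen_t)L.nc[0] * L.nc[1];
  for (int k = 0; k < gf.n[2]; ++k)
    for (int j = 0; j < gf.n[1]; ++j)
      for (int i = 0; i < gf.n[0]; ++i, ++idx) {
        idx_to_world(gf, i, j, k, p);
        q_of_world(L.ref, p, q);
        const int bi = locate(L, 0, q[0], wx);
        const int bj = locate(L, 1, q[1], wy);
        const int bk = locate(L, 2, q[2], wz);
        double d0 = 0, d1 = 0, d2 = 0;
        for (int c = 0; c < 4; ++c) {
          const R_xlen_t oc = cz * (bk + c);
          for (int b = 0; b < 4; ++b) {
            const double wyz = wy[b] * wz[c];
            const R_xlen_t ob = oc + cy * (bj + b);
            for (int a = 0; a < 4; ++a) {
              const double w = wx[a] * wyz;
              const R_xlen_t ci = ob + (bi + a);
              d0 += w * cf[ci];
              d1 += w * cf[ci + ncoef];
              d2 += w * cf[ci + 2 * ncoef];
            }
          }
        }
        phi[0] = Rm[0] * p[0] + Rm[3] * p[1] + Rm[6] * p[2] + trans[0] + d0;
        phi[1] = Rm[1] * p[0] + Rm[4] * p[1] + Rm[7] * p[2] + trans[1] + d1;
        phi[2] = Rm[2] * p[0] + Rm[5] * p[1] + Rm[8] * p[2] + trans[2] + d2;
        world_to_idx(gm, phi, v);
        double diff, g0 = 0, g1 = 0, g2 = 0;
        // clamp-to-edge within a 2-voxel margin so the cost stays continuous
        // at the moving-image border (a hard fill cliff breaks line search)
        const double marg = 2.0;
        const bool near = v[0] >= -marg && v[0] <= gm.n[0] - 1 + marg &&
                          v[1] >= -marg && v[1] <= gm.n[1] - 1 + marg &&
                          v[2] >= -marg && v[2] <= gm.n[2] - 1 + marg;
        if (near) {
          const double mv = sample_linear(M, gm.n, v[0], v[1], v[2]);
          diff = mv - F[idx];
          if (want_grad) {
            g0 = sample_linear(GX, gm.n, v[0], v[1], v[2]);
            g1 = sample_linear(GY, gm.n, v[0], v[1], v[2]);
            g2 = sample_linear(GZ, gm.n, v[0], v[1], v[2]);
          }
        } else {
          diff = fill - F[idx];
        }
        sse += diff * diff;
        if (want_grad && (g0 != 0 || g1 != 0 || g2 != 0)) {
          const double f = 2.0 * diff / (double)N;
          const double f0 = f * g0, f1 = f * g1, f2 = f * g2;
          for (int c = 0; c < 4; ++c) {
            const R_xlen_t oc = cz * (bk + c);
            for (int b = 0; b < 4; ++b) {
              const double wyz = wy[b] * wz[c];
              const R_xlen_t ob = oc + cy * (bj + b);
              for (int a = 0; a < 4; ++a) {
                const double w = wx[a] * wyz;
                const R_xlen_t ci = ob + (bi + a);
                gr[ci] += w * f0;
                gr[ci + ncoef] += w * f1;
                gr[ci + 2 * ncoef] += w * f2;
              }
            }
          }
        }
      }
  double cost = sse / (double)N;
  if (lambda > 0) {
    double bend = 0;
    const R_xlen_t stride[3] = {cx, cy, cz};
    for (int comp = 0; comp < 3; ++comp) {
      const double* c0 = cf + comp * ncoef;
      double* g0 = want_grad ? gr + comp * ncoef : NULL;
      for (int axis = 0; axis < 3; ++axis) {
        const R_xlen_t st = stride[axis];
        const int nn[3] = {L.nc[0], L.nc[1], L.nc[2]};
        for (int k = 0; k < nn[2]; ++k)
          for (int j = 0; j < nn[1]; ++j)
            for (int i = 0; i < nn[0]; ++i) {
              const int pos[3] = {i, j, k};
              if (pos[axis] < 1 || pos[axis] > nn[axis] - 2) continue;
              const R_xlen_t ci = i + cy * j + cz * k;
              const double s = c0[ci - st] - 2 * c0[ci] + c0[ci + st];
              bend += s * s;
              if (want_grad) {
                g0[ci - st] += 2 * lambda * s;
                g0[ci] -= 4 * lambda * s;
                g0[ci + st] += 2 * lambda * s;
              }
            }
      }
    }
    cost += lambda * bend;
  }
  if (want_grad)
    return List::create(_["value"] = cost, _["grad"] = grad);
  return List::create(_["value"] = cost);
}

// Dense displacement (B-spline part only, world mm) evaluated on a grid.
// [[Rcpp::export]]
NumericVector cpp_bspline_disp(NumericVector coef, IntegerVector cdim,
                               NumericVector delta, IntegerVector gdim,
                               NumericVector gspacing, NumericVector gorigin,
                               NumericMatrix gdir, IntegerVector refdim,
                               NumericVector refspacing, NumericVector reforigin,
                               NumericMatrix refdir) {
  Geom gg = make_geom(gdim, gspacing, gorigin, gdir);
  Lattice L;
  L.ref = make_geom(refdim, refspacing, reforigin, refdir);
  for (int a = 0; a < 3; ++a) { L.nc[a] = cdim[a]; L.delta[a] = delta[a]; }
  const R_xlen_t ncoef = (R_xlen_t)L.nc[0] * L.nc[1] * L.nc[2];
  const double* cf = coef.begin();
  const R_xlen_t N = (R_xlen_t)gg.n[0] * gg.n[1] * gg.n[2];
  NumericVector out(3 * N);
  double p[3], q[3], wx[4], wy[4], wz[4];
  const R_xlen_t cy = L.nc[0], cz = (R_xlen_t)L.nc[0] * L.nc[1];
  R_xlen_t idx = 0;
  for (int k = 0; k < gg.n[2]; ++k)
    for (int j = 0; j < gg.n[1]; ++j)
      for (int i = 0; i < gg.n[0]; ++i, ++idx) {
        idx_to_world(gg, i, j, k, p);
        q_of_world(L.ref, p, q);
        const int bi = locate(L, 0, q[0], wx);
        const int bj = locate(L, 1, q[1], wy);
        const int bk = locate(L, 2, q[2], wz);
        double d0 = 0, d1 = 0, d2 = 0;
        for (int c = 0; c < 4; ++c) {
          const R_xlen_t oc = cz * (bk + c);
          for (int b = 0; b < 4; ++b) {
            const double wyz = wy[b] * wz[c];
            const R_xlen_t ob = oc + cy * (bj + b);
            for (int a = 0; a < 4; ++a) {
              const double w = wx[a] * wyz;
              const R_xlen_t ci = ob + (bi + a);
              d0 += w * cf[ci];
              d1 += w * cf[ci + ncoef];
              d2 += w * cf[ci + 2 * ncoef];
            }
          }
        }
        out[idx] = d0;
        out[idx + N] = d1;
        out[idx + 2 * N] = d2;
      }
  return out;
}
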