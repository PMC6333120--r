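#include "masct_utils.h"
using namespace Rcpp;

// Resample src onto the destination grid, optionally adding a per-voxel
// displacement (mm, world frame) to the destination voxel's physical point
// before sampling (pull-back warp). interp: 0 = linear, 1 = nearest.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdim,
                           NumericVector sspacing, NumericVector sorigin,
                           NumericMatrix sdir, IntegerVector ddim,
                           NumericVector dspacing, NumericVector dorigin,
                           NumericMatrix ddir, Nullable<NumericVector> disp,
                           int interp, double fill) {
  Geom gs = make_geom(sdim, sspacing, sorigin, sdir);
  Geom gd = make_geom(ddim, dspacing, dorigin, ddir);
  const R_xlen_t N = (R_xlen_t)gd.n[0] * gd.n[1] * gd.n[2];
  NumericVector out(N);
  const double* a = src.begin();
  const double* dsp = NULL;
  if (disp.isNotNull()) {
    NumericVector dv(disp);
    if (dv.size() != 3 * N) stop("displacement field size mismatch");
    dsp = REAL(dv);
  }
  double p[3], v[3];
  R_xlen_t idx = 0;
  for (int k = 0; k < gd.n[2]; ++k)
    for (int j = 0; j < gd.n[1]; ++j)
      for (int i = 0; i < gd.n[0]; ++i, ++idx) {
        idx_to_world(gd, i, j, k, p);
        if (dsp) {
          p[0] += dsp[idx]; p[1] += dsp[idx + N]; p[2] += dsp[idx + 2 * N];
        }
        world_to_idx(gs, p, v);
        // voxel-as-cell support: half a voxel beyond the outer sample
        // centres still samples (clamped to edge); only farther points fill
        const bool outside =
            v[0] < -0.5 || v[0] > gs.n[0] - 0.5 ||
            v[1] < -0.5 || v[1] > gs.n[1] - 0.5 ||
            v[2] < -0.5 || v[2] > gs.n[2] - 0.5;
        if (outside) {
          out[idx] = fill;
        } else if (interp == 1) {
          out[idx] = sample_nearest(a, gs.n, v[0], v[1], v[2]);
        } else {
          out[idx] = sample_linear(a, gs.n, v[0], v[1], v[2]);
        }
      }
  out.attr("dim") = ddim;
  return out;
}

// Central-difference gradient rotated into the world frame; returns three
// arrays (d/dworld_x, d/dworld_y, d/dworld_z) on the source grid.
// [[Rcpp::export]]
List cpp_gradient_world(NumericVector src, IntegerVector dim,
                        NumericVector spacing, NumericMatrix dir) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  NumericVector gx(N), gy(N), gz(N);
  const double* a = src.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double D[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) D[r + 3 * c] = dir(r, c);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double g[3];
        const int lo[3] = {i, j, k};
        const int nn[3] = {nx, ny, nz};
        const R_xlen_t st[3] = {sx, sy, sz};
        for (int axis = 0; axis < 3; ++axis) {
          double num, den;
          if (nn[axis] == 1) { g[axis] = 0; continue; }
          if (lo[axis] == 0) {
            num = a[idx + st[axis]] - a[idx]; den = spacing[axis];
          } else if (lo[axis] == nn[axis] - 1) {
            num = a[idx] - a[idx - st[axis]]; den = spacing[axis];
          } else {
            num = a[idx + st[axis]] - a[idx - st[axis]]; den = 2 * spacing[axis];
          }
          g[axis] = num / den;
        }
        gx[idx] = D[0] * g[0] + D[3] * g[1] + D[6] * g[2];
        gy[idx] = D[1] * g[0] + D[4] * g[1] + D[7] * g[2];
        gz[idx] = D[2] * g[0] + D[5] * g[1] + D[8] * g[2];
      }
  gx.attr("dim") = dim; gy.attr("dim") = dim; gz.attr("dim") = dim;
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

static void smooth_axis(std::vector<double>& buf, const double* in, double* out,
                        int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) {
    std::copy(in, in + (R_xlen_t)nx * ny * nz, out);
    return;
  }
  int r = (int)std::ceil(3 * sigma);
  std::vector<double> w(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) {
    w[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += w[t + r];
  }
  for (double& x : w) x /= s;
  const int nn[3] = {nx, ny, nz};
  const R_xlen_t st[3] = {1, nx, (R_xlen_t)nx * ny};
  const R_xlen_t stride = st[axis];
  const int len = nn[axis];
  // iterate over all lines along `axis`
  R_xlen_t nlines = (R_xlen_t)nx * ny * nz / len;
  (void)nlines;
  for (int k = 0; k < (axis == 2 ? 1 : nz); ++k)
    for (int j = 0; j < (axis == 1 ? 1 : ny); ++j)
      for (int i = 0; i < (axis == 0 ? 1 : nx); ++i) {
        R_xlen_t base = i + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k;
        for (int t = 0; t < len; ++t) buf[t] = in[base + stride * t];
        for (int t = 0; t < len; ++t) {
          double acc = 0, wsum = 0;
          int a0 = std::max(0, t - r), a1 = std::min(len - 1, t + r);
          for (int u = a0; u <= a1; ++u) {
            acc += w[u - t + r] * buf[u];
            wsum += w[u - t + r];
          }
          out[base + stride * t] = acc / wsum;
        }
      }
}

// Separable Gaussian smoothing; sigma per axis in voxel units, kernel
// renormalized at borders.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector src, IntegerVector dim,
                                  NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  NumericVector out(N);
  std::vector<double> tmp(N), buf(std::max(nx, std::max(ny, nz)));
  smooth_axis(buf, src.begin(), tmp.data(), nx, ny, nz, 0, sigma[0]);
  std::vector<double> tmp2(N);
  smooth_axis(buf, tmp.data(), tmp2.data(), nx, ny, nz, 1, sigma[1]);
  smooth_axis(buf, tmp2.data(), REAL(out), nx, ny, nz, 2, sigma[2]);
  out.attr("dim") = dim;
  return out;
}

// Largest 6-connected component of the nonzero voxels.
// [[Rcpp::export]]
IntegerVector cpp_largest_component(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<int> lab(N, 0);
  const int* m = mask.begin();
  int cur = 0;
  R_xlen_t best_size = 0;
  int best_lab = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!m[s] || lab[s]) continue;
    ++cur;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      const int di[6] = {1, -1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, 1, -1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, 1, -1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t u = ii + (R_xlen_t)nx * jj + (R_xlen_t)nx * ny * kk;
        if (m[u] && !lab[u]) {
          lab[u] = cur;
          stack.push_back(u);
        }
      }
    }
    if (size > best_size) { best_size = size; best_lab = cur; }
  }
  IntegerVector out(N);
  for (R_xlen_t s = 0; s < N; ++s) out[s] = (lab[s] == best_lab && best_lab) ? 1 : 0;
  out.attr("dim") = dim;
  return out;
}

// Binary dilation (op = 1) / erosion (op = 0) with an ellipsoidal
// structuring element of per-axis voxel radii.
// [[Rcpp::export]]
IntegerVector cpp_binary_morph(IntegerVector mask, IntegerVector dim,
                               IntegerVector radius, int op) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const int rx = radius[0], ry = radius[1], rz = radius[2];
  std::vector<std::array<int, 3>> se;
  for (int dk = -rz; dk <= rz; ++dk)
    for (int dj = -ry; dj <= ry; ++dj)
      for (int di = -rx; di <= rx; ++di) {
        double t = 0;
        if (rx) t += (double)di * di / ((double)rx * rx);
        else if (di) continue;
        if (ry) t += (double)dj * dj / ((double)ry * ry);
        else if (dj) continue;
        if (rz) t += (double)dk * dk / ((double)rz * rz);
        else if (dk) continue;
        if (t <= 1.0 + 1e-9) se.push_back({di, dj, dk});
      }
  IntegerVector out(N);
  const int* m = mask.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int hit = op ? 0 : 1;
        for (size_t t = 0; t < se.size(); ++t) {
          int ii = i + se[t][0], jj = j + se[t][1], kk = k + se[t][2];
          int val;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            // dilation treats outside as background, erosion as foreground,
            // so a closing never eats objects touching the grid border
            val = op ? 0 : 1;
          else
            val = m[ii + (R_xlen_t)nx * jj + (R_xlen_t)nx * ny * kk] ? 1 : 0;
          if (op) { if (val) { hit = 1; break; } }
          else    { if (!val) { hit = 0; break; } }
        }
        out[idx] = hit;
      }
  out.attr("dim") = dim;
  return out;
}
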