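#include "masct_utils.h"
using namespace Rcpp;

// Patch statistics of a difference vector: squared mean, population variance,
// Shannon entropy (bits) over `bins` equal-width bins spanning [min, max].
static void diff_stats(const double* d, int n, int bins, double* m2,
                       double* var, double* ent, std::vector<int>& cnt) {
  double s = 0, s2 = 0, lo = d[0], hi = d[0];
  for (int i = 0; i < n; ++i) {
    s += d[i];
    s2 += d[i] * d[i];
    if (d[i] < lo) lo = d[i];
    if (d[i] > hi) hi = d[i];
  }
  const double mean = s / n;
  *m2 = mean * mean;
  double v = s2 / n - mean * mean;
  if (v < 0) v = 0;
  *var = v;
  if (hi - lo < 1e-300) {
    *ent = 0;
    return;
  }
  std::fill(cnt.begin(), cnt.begin() + bins, 0);
  const double w = (hi - lo) / bins;
  for (int i = 0; i < n; ++i) {
    int b = (int)((d[i] - lo) / w);
    if (b >= bins) b = bins - 1;
    if (b < 0) b = 0;
    ++cnt[b];
  }
  double e = 0;
  for (int b = 0; b < bins; ++b) {
    if (!cnt[b]) continue;
    const double p = (double)cnt[b] / n;
    e -= p * std::log2(p);
  }
  *ent = e;
}

// GRE between target and one atlas MR at patch centre (i, j, k) with the
// atlas patch shifted by (di, dj). In-plane (axial) patch of half-width r;
// patch voxels are kept when both target and shifted-atlas samples are in
// bounds. Returns a negative value when the clipped patch is empty.
static double gre_one(const double* tgt, const double* atl, const int* n,
                      int i, int j, int k, int di, int dj, int r, int bins,
                      double eps, std::vector<double>& buf,
                      std::vector<int>& cnt) {
  const R_xlen_t nx = n[0], nxy = (R_xlen_t)n[0] * n[1];
  const R_xlen_t zoff = nxy * k;
  int m = 0;
  for (int q = j - r; q <= j + r; ++q) {
    if (q < 0 || q >= n[1]) continue;
    const int qa = q + dj;
    if (qa < 0 || qa >= n[1]) continue;
    for (int p = i - r; p <= i + r; ++p) {
      if (p < 0 || p >= n[0]) continue;
      const int pa = p + di;
      if (pa < 0 || pa >= n[0]) continue;
      buf[m++] = tgt[p + nx * q + zoff] - atl[pa + nx * qa + zoff];
    }
  }
  if (m == 0) return -1.0;
  double m2, var, ent;
  diff_stats(buf.data(), m, bins, &m2, &var, &ent, cnt);
  return std::cbrt((m2 + eps) * (var + eps) * (ent + eps));
}

// Full fusion: per voxel inside `mask`, per atlas, minimize GRE over the
// candidate in-plane offsets (pre-sorted by magnitude then lexicographic;
// first strict minimum wins, implementing the tie-break), then average the
// offset-corrected atlas CT values with weights 1 / gre_min. Outside the
// mask the synthetic CT takes `fill`.
// [[Rcpp::export]]
List cpp_fuse(NumericVector target, IntegerVector dim, IntegerVector mask,
              List atlas_mr, List atlas_ct, IntegerMatrix offsets,
              int patch_radius, int entropy_bins, double eps, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n[3] = {nx, ny, nz};
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const int na = atlas_mr.size();
  const int noff = offsets.nrow();
  if (na < 1) stop("empty atlas list");
  std::vector<const double*> mrs(na), cts(na);
  std::vector<NumericVector> keep_mr(na), keep_ct(na);
  for (int a = 0; a < na; ++a) {
    keep_mr[a] = as<NumericVector>(atlas_mr[a]);
    keep_ct[a] = as<NumericVector>(atlas_ct[a]);
    if (keep_mr[a].size() != N || keep_ct[a].size() != N)
      stop("atlas volume size mismatch");
    mrs[a] = keep_mr[a].begin();
    cts[a] = keep_ct[a].begin();
  }
  std::vector<int> offi(noff), offj(noff);
  for (int t = 0; t < noff; ++t) { offi[t] = offsets(t, 0); offj[t] = offsets(t, 1); }
  NumericVector sct(N);
  List gre_out(na), boi_out(na), boj_out(na);
  std::vector<double*> greP(na);
  std::vector<int*> boiP(na), bojP(na);
  for (int a = 0; a < na; ++a) {
    NumericVector g(N);
    IntegerVector bi(N), bj(N);
    g.attr("dim") = dim; bi.attr("dim") = dim; bj.attr("dim") = dim;
    gre_out[a] = g; boi_out[a] = bi; boj_out[a] = bj;
    greP[a] = REAL(g);
    boiP[a] = INTEGER(bi);
    bojP[a] = INTEGER(bj);
  }
  const double* tgt = target.begin();
  const int* msk = mask.begin();
  const int side = 2 * patch_radius + 1;
  std::vector<double> buf(side * side);
  std::vector<int> cnt(entropy_bins);
  std::vector<double> w(na), ctv(na);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (!msk[idx]) {
          sct[idx] = fill;
          for (int a = 0; a < na; ++a) {
            greP[a][idx] = NA_REAL;
            boiP[a][idx] = 0;
            bojP[a][idx] = 0;
          }
          continue;
        }
        double wsum = 0, vsum = 0;
        for (int a = 0; a < na; ++a) {
          double best = -1;
          int bdi = 0, bdj = 0;
          for (int t = 0; t < noff; ++t) {
            const double g = gre_one(tgt, mrs[a], n, i, j, k, offi[t], offj[t],
                                     patch_radius, entropy_bins, eps, buf, cnt);
            if (g < 0) continue;
            if (best < 0 || g < best) { best = g; bdi = offi[t]; bdj = offj[t]; }
          }
          if (best < 0) { best = eps; bdi = 0; bdj = 0; } // fully clipped corner
          greP[a][idx] = best;
          boiP[a][idx] = bdi;
          bojP[a][idx] = bdj;
          int ia = i + bdi, ja = j + bdj;
          if (ia < 0) ia = 0; if (ia >= nx) ia = nx - 1;
          if (ja < 0) ja = 0; if (ja >= ny) ja = ny - 1;
          const double wt = 1.0 / best;
          wsum += wt;
          vsum += wt * cts[a][ia + (R_xlen_t)nx * ja + (R_xlen_t)nx * ny * k];
        }
        sct[idx] = vsum / wsum;
      }
  sct.attr("dim") = dim;
  return List::create(_["sct"] = sct, _["gre"] = gre_out,
                      _["best_i"] = boi_out, _["best_j"] = boj_out);
}
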