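#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double DM_INF = 1e20;

// 1-D squared distance transform, lower envelope of parabolas
// (Felzenszwalb & Huttenlocher). f: input squared costs, d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DM_INF;
  z[1] = DM_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DM_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact 3-D squared Euclidean distance transform: for every voxel the
// squared distance (voxel units) to the nearest zero voxel of `fg`.
// [[Rcpp::export]]
NumericVector cpp_edt3d_sq(IntegerVector fg, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? DM_INF : 0.0;
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along dim 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, n1, v, z);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  // along dim 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f, d, n2, v, z);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  // along dim 3
  R_xlen_t stride = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      for (int k = 0; k < n3; ++k) f[k] = out[base + stride * k];
      dt1d(f, d, n3, v, z);
      for (int k = 0; k < n3; ++k) out[base + stride * k] = d[k];
    }
  return out;
}

// Hildebrand-style local thickness: EDT -> distance ridge -> maximal-sphere
// painting. Returns the per-voxel thickness map in voxel units (diameter of
// the largest inscribed sphere covering each voxel, with the usual 2d-1
// half-voxel boundary correction); zero on background.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(IntegerVector mask, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  R_xlen_t nfg = 0, nbg = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) ++nfg; else ++nbg;
  }
  if (nfg == 0) stop("empty mask: local thickness undefined");
  if (nbg == 0) stop("mask fills the volume: no background to measure against");
  NumericVector d2 = cpp_edt3d_sq(mask, dims);
  std::vector<double> r(n, 0.0);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) r[i] = std::sqrt(d2[i]);
  R_xlen_t s2 = (R_xlen_t)n1 * n2;
  std::vector<double> th(n, 0.0);
  // ridge: foreground voxels whose EDT is a (weak) local maximum over the
  // 26-neighbourhood
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)n1 * j + s2 * k;
        if (!mask[idx]) continue;
        double ri = r[idx];
        bool ridge = true;
        for (int dk = -1; dk <= 1 && ridge; ++dk)
          for (int dj = -1; dj <= 1 && ridge; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                  kk < 0 || kk >= n3) continue;
              if (r[ii + (R_xlen_t)n1 * jj + s2 * kk] > ri) { ridge = false; break; }
            }
        if (!ridge) continue;
        // paint the maximal sphere of this ridge voxel (radius = EDT value,
        // so the covering reaches the structure surface)
        double val = 2.0 * ri - 1.0;
        double rad = ri;
        int R = (int)std::floor(rad + 1e-9);
        double rad2 = rad * rad + 1e-9;
        for (int dk = -R; dk <= R; ++dk) {
          int kk = k + dk;
          if (kk < 0 || kk >= n3) continue;
          for (int dj = -R; dj <= R; ++dj) {
            int jj = j + dj;
            if (jj < 0 || jj >= n2) continue;
            for (int di = -R; di <= R; ++di) {
              int ii = i + di;
              if (ii < 0 || ii >= n1) continue;
              if ((double)di * di + (double)dj * dj + (double)dk * dk > rad2)
                continue;
              R_xlen_t t = ii + (R_xlen_t)n1 * jj + s2 * kk;
              if (th[t] < val) th[t] = val;
            }
          }
        }
      }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) { out[i] = 0.0; continue; }
    double v = th[i];
    if (v <= 0.0) v = 2.0 * r[i] - 1.0; // uncovered voxel: its own sphere
    out[i] = v;
  }
  return out;
}

// Seeded region growing, 6-connectivity, FIFO order. A voxel is annexed when
// |intensity - running region mean| <= tol. Rejected voxels may be revisited
// from other neighbours as the region statistic evolves.
// [[Rcpp::export]]
List cpp_srg(NumericVector vol, IntegerVector dims, IntegerVector seeds,
             double tol, double max_frac) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  R_xlen_t s2 = (R_xlen_t)n1 * n2;
  LogicalVector mask(n, false);
  std::queue<R_xlen_t> q;
  double sum = 0.0;
  R_xlen_t cnt = 0;
  R_xlen_t limit = (R_xlen_t)std::floor(max_frac * (double)n);
  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    R_xlen_t idx = (R_xlen_t)seeds[s];
    if (idx < 0 || idx >= n) stop("seed index outside the volume");
    if (!mask[idx]) {
      mask[idx] = true;
      sum += vol[idx];
      ++cnt;
      q.push(idx);
    }
  }
  bool overflow = false;
  const int d1[6] = {-1, 1, 0, 0, 0, 0};
  const int d2v[6] = {0, 0, -1, 1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, -1, 1};
  while (!q.empty()) {
    R_xlen_t idx = q.front();
    q.pop();
    int k = (int)(idx / s2);
    R_xlen_t rem = idx - (R_xlen_t)k * s2;
    int j = (int)(rem / n1);
    int i = (int)(rem - (R_xlen_t)j * n1);
    double mean = sum / (double)cnt;
    for (int m = 0; m < 6; ++m) {
      int ii = i + d1[m], jj = j + d2v[m], kk = k + d3[m];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      R_xlen_t t = ii + (R_xlen_t)n1 * jj + s2 * kk;
      if (mask[t]) continue;
      if (std::fabs(vol[t] - mean) <= tol) {
        mask[t] = true;
        sum += vol[t];
        ++cnt;
        if (cnt > limit) { overflow = true; break; }
        q.push(t);
      }
    }
    if (overflow) break;
  }
  return List::create(_["mask"] = mask, _["overflow"] = overflow,
                      _["n_voxels"] = (double)cnt);
}

// Connected-component labelling of a binary matrix, 4- or 8-connectivity.
// Labels are assigned in column-major scan order of first encounter.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nn = (connectivity == 8) ? 8 : 4;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int m = 0; m < nn; ++m) {
          int ii = p.first + dr[m], jj = p.second + dc[m];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  return lab;
}

static inline int nb(const IntegerMatrix& m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen thinning to a 1-px skeleton (8-connected skeleton retained).
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);
  bool changed = true;
  std::vector<std::pair<int, int> > del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!img(i, j)) continue;
          int p2 = nb(img, i - 1, j), p3 = nb(img, i - 1, j + 1);
          int p4 = nb(img, i, j + 1), p5 = nb(img, i + 1, j + 1);
          int p6 = nb(img, i + 1, j), p7 = nb(img, i + 1, j - 1);
          int p8 = nb(img, i, j - 1), p9 = nb(img, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      if (!del.empty()) {
        changed = true;
        for (size_t m = 0; m < del.size(); ++m)
          img(del[m].first, del[m].second) = 0;
      }
    }
  }
  return img;
}
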