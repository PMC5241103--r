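#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1D lower-envelope-of-parabolas pass (Felzenszwalb & Huttenlocher).
// f: input squared distances at n sites with physical step `w` between
// adjacent sites; d: output min_p ( (q-p)*w )^2 + f[p].
static void edt_1d(const double *f, double *d, int n, double w,
                   std::vector<int> &v, std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    int p = v[k];
    double s = ((f[q] - f[p]) / w2 + (double)q * q - (double)p * p) /
               (2.0 * (q - p));
    while (s <= z[k]) {
      --k;
      p = v[k];
      s = ((f[q] - f[p]) / w2 + (double)q * q - (double)p * p) /
          (2.0 * (q - p));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < (double)q) ++kk;
    int p = v[kk];
    double dq = (double)(q - p) * w;
    d[q] = dq * dq + f[p];
  }
}

// Exact squared Euclidean distance transform of a 3D logical array with
// anisotropic voxel spacing. Distance is measured between voxel centers,
// to the nearest TRUE voxel. Returns +Inf if the mask is empty.
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dims,
                              NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      edt_1d(f.data(), d.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = out[base + (R_xlen_t)nx * j]; if (f[j] < INF) any = true; }
      if (!any) continue;
      edt_1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = out[base + nxy * k]; if (f[k] < INF) any = true; }
      if (!any) continue;
      edt_1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) out[base + nxy * k] = d[k];
    }
  out.attr("dim") = dims;
  return out;
}

// 6-connected component labelling of a 3D logical array (BFS).
// Labels are 1..n_components in first-encounter order; background is 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t c = q.front(); q.pop();
      int k = (int)(c / nxy);
      int rem = (int)(c % nxy);
      int j = rem / nx;
      int i = rem % nx;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t idx = ii + (R_xlen_t)nx * jj + nxy * kk;
        if (mask[idx] && lab[idx] == 0) { lab[idx] = next; q.push(idx); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
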