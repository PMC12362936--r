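#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform, one axis at a time
// (lower-envelope-of-parabolas algorithm), in physical units so that
// anisotropic voxel spacing is respected.

static const double BIG = 1e15; // stands in for +Inf; differences stay exact

static void dt1d(const std::vector<double>& f, double h, int n,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double xq = q * h;
    double s;
    while (true) {
      double xp = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * h;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared_cpp")]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dim,
                              NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, spacing[0], nx, d, v, z);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, spacing[1], ny, d, v, z);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(f, spacing[2], nz, d, v, z);
      for (int k = 0; k < nz; k++) out[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  return out;
}

// 6-connectivity labeling of a binary 3D array (breadth-first search).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t p = q.front();
      q.pop();
      int k = (int)(p / sz);
      int j = (int)((p - (R_xlen_t)k * sz) / sy);
      int i = (int)(p - (R_xlen_t)k * sz - (R_xlen_t)j * sy);
      R_xlen_t nb[6];
      int m = 0;
      if (i > 0) nb[m++] = p - sx;
      if (i < nx - 1) nb[m++] = p + sx;
      if (j > 0) nb[m++] = p - sy;
      if (j < ny - 1) nb[m++] = p + sy;
      if (k > 0) nb[m++] = p - sz;
      if (k < nz - 1) nb[m++] = p + sz;
      for (int t = 0; t < m; t++) {
        R_xlen_t u = nb[t];
        if (mask[u] && lab[u] == 0) {
          lab[u] = next;
          q.push(u);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
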