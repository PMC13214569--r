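#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Trilinear interpolation of a 3D volume at fractional 0-based voxel
// coordinates. Samples falling outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector interp3_cpp(NumericVector vol, IntegerVector dim,
                          NumericVector x, NumericVector y, NumericVector z,
                          double fill) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = x.size();
  NumericVector out(n);
  const double *v = vol.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    if (!(xi > -1.0 && yi > -1.0 && zi > -1.0 &&
          xi < (double)n1 && yi < (double)n2 && zi < (double)n3) ||
        ISNAN(xi) || ISNAN(yi) || ISNAN(zi)) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi), z0 = (int)std::floor(zi);
    double fx = xi - x0, fy = yi - y0, fz = zi - z0;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      int zz = z0 + dz;
      double wz = dz ? fz : (1.0 - fz);
      if (zz < 0 || zz >= n3 || wz == 0.0) { if (zz < 0 || zz >= n3) acc += 0.0; continue; }
      for (int dy = 0; dy <= 1; ++dy) {
        int yy = y0 + dy;
        double wy = dy ? fy : (1.0 - fy);
        if (yy < 0 || yy >= n2 || wy == 0.0) continue;
        for (int dx = 0; dx <= 1; ++dx) {
          int xx = x0 + dx;
          double wx = dx ? fx : (1.0 - fx);
          if (xx < 0 || xx >= n1 || wx == 0.0) continue;
          acc += wz * wy * wx * v[(R_xlen_t)xx + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * zz)];
        }
      }
    }
    out[i] = acc;
  }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), in place on
// a line of length n; f holds squared distances (INF where no site yet).
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &vtx, std::vector<double> &zz, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  vtx[0] = q0;
  zz[0] = -INF;
  zz[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    int p = vtx[k];
    double s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * q - 2.0 * p);
    while (s <= zz[k]) {
      --k;
      p = vtx[k];
      s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * q - 2.0 * p);
    }
    ++k;
    vtx[k] = q;
    zz[k] = s;
    zz[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < q) ++k;
    int p = vtx[k];
    d[q] = (q - (double)p) * (q - (double)p) + f[p];
  }
}

// Exact 3D squared Euclidean distance transform (voxel units) to the set of
// TRUE voxels in `sites`. Returns +Inf where sites is empty.
// [[Rcpp::export]]
NumericVector edt3_cpp(LogicalVector sites, IntegerVector dim) {
  const double INF = std::numeric_limits<double>::infinity();
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  double *o = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) o[i] = sites[i] ? 0.0 : INF;
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), zz(nmax + 1);
  std::vector<int> vtx(nmax);
  // pass along x
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y) {
      R_xlen_t base = (R_xlen_t)n1 * (y + (R_xlen_t)n2 * z);
      for (int x = 0; x < n1; ++x) f[x] = o[base + x];
      dt1d(f, d, vtx, zz, n1);
      for (int x = 0; x < n1; ++x) o[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < n3; ++z)
    for (int x = 0; x < n1; ++x) {
      R_xlen_t base = (R_xlen_t)x + (R_xlen_t)n1 * n2 * z;
      for (int y = 0; y < n2; ++y) f[y] = o[base + (R_xlen_t)n1 * y];
      dt1d(f, d, vtx, zz, n2);
      for (int y = 0; y < n2; ++y) o[base + (R_xlen_t)n1 * y] = d[y];
    }
  // pass along z
  for (int y = 0; y < n2; ++y)
    for (int x = 0; x < n1; ++x) {
      R_xlen_t base = (R_xlen_t)x + (R_xlen_t)n1 * y;
      R_xlen_t stride = (R_xlen_t)n1 * n2;
      for (int z = 0; z < n3; ++z) f[z] = o[base + stride * z];
      dt1d(f, d, vtx, zz, n3);
      for (int z = 0; z < n3; ++z) o[base + stride * z] = d[z];
    }
  return out;
}
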