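#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher.  f holds squared distances on input,
// w is the (physical) sample spacing along the line.
static void dt1d(std::vector<double>& f, double w) {
  const int n = (int)f.size();
  if (n == 0) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * w, vv;
    double s = 0.0;
    while (true) {
      vv = (double)v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * w;
    while (z[k + 1] < qq) ++k;
    double vv = (double)v[k] * w;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact Euclidean distance transform of a 3D occupancy grid.
// Returns, per voxel, the distance (physical units set by `spacing`)
// to the nearest foreground voxel centre; 0 on foreground.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector occ, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel instead of infinity: infinite parabola
  // intercepts break the lower-envelope recursion
  const double INF = 1e30;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = occ[i] ? 0.0 : INF;

  std::vector<double> line;
  // pass along x
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      bool any = false;
      for (int x = 0; x < nx; ++x) { line[x] = out[base + x]; if (line[x] < INF) any = true; }
      if (!any) continue;
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = line[x];
    }
  // pass along y
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) line[y] = out[base + (R_xlen_t)nx * y];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = line[y];
    }
  // pass along z
  line.resize(nz);
  const R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int z = 0; z < nz; ++z) line[z] = out[base + stride * z];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + stride * z] = line[z];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] >= 1e29) ? R_PosInf : std::sqrt(out[i]);
  return out;
}

// Local thickness by sphere propagation (Hildebrand & Ruegsegger):
// every foreground voxel c carries an inscribed-sphere radius r(c)
// (its EDT value = distance to the nearest background voxel centre);
// each foreground voxel p covered by some sphere (|p - c| < r(c)) is
// assigned diameter max(2 r(c) - 1): the -1 measures to the digital
// surface half a voxel inside the background centres, so an isolated
// voxel has thickness 1.  Grid must be isotropic (unit voxel units).
// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(LogicalVector occ, NumericVector r,
                                  IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n);
  // order foreground voxels by decreasing radius so early painting wins
  std::vector<R_xlen_t> idx;
  idx.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; ++i)
    if (occ[i]) idx.push_back(i);
  std::sort(idx.begin(), idx.end(),
            [&](R_xlen_t a, R_xlen_t b) { return r[a] > r[b]; });
  for (R_xlen_t ii = 0; ii < (R_xlen_t)idx.size(); ++ii) {
    const R_xlen_t c = idx[ii];
    const double rc = r[c];
    const double d2 = 2.0 * rc - 1.0;
    const int cz = (int)(c / ((R_xlen_t)nx * ny));
    const int cy = (int)((c / nx) % ny);
    const int cx = (int)(c % nx);
    const int R = (int)std::ceil(rc);
    const double rc2 = rc * rc;
    for (int dz = -R; dz <= R; ++dz) {
      int z = cz + dz;
      if (z < 0 || z >= nz) continue;
      for (int dy = -R; dy <= R; ++dy) {
        int y = cy + dy;
        if (y < 0 || y >= ny) continue;
        double dzy = (double)dz * dz + (double)dy * dy;
        if (dzy >= rc2) continue;
        R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int dx = -R; dx <= R; ++dx) {
          int x = cx + dx;
          if (x < 0 || x >= nx) continue;
          if (dzy + (double)dx * dx >= rc2) continue;
          R_xlen_t p = base + x;
          if (occ[p] && th[p] < d2) th[p] = d2;
        }
      }
    }
  }
  // isolated voxels (EDT radius <= 1) still have unit diameter
  for (R_xlen_t i = 0; i < n; ++i)
    if (occ[i] && th[i] <= 0.0) th[i] = 1.0;
  return th;
}
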