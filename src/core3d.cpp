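#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Voxel grids are R arrays dim = c(nz, ny, nx); linear index (0-based)
// i = z + nz * (y + ny * x), i.e. column-major with z fastest.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export(name = ".cc_label_3d26")]]
IntegerVector cc_label_3d26(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++next;
    lab[seed] = next;
    stack.clear();
    stack.push_back((int)seed);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int x = cur / (nz * ny);
      int rem = cur - x * nz * ny;
      int y = rem / nz;
      int z = rem - y * nz;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            int nb = lin(zz, yy, xx, nz, ny);
            if (mask[nb] && !lab[nb]) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
    }
  }
  return lab;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher) on a line of
// samples spaced h apart. f holds squared distances; overwritten in place.
static void dt1d(std::vector<double>& f, double h, std::vector<int>& v,
                 std::vector<double>& zbnd, std::vector<double>& out) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zbnd[0] = -INF;
  zbnd[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      double qq = q * h, vv = v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= zbnd[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbnd[k] = s;
    zbnd[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * h;
    while (zbnd[k + 1] < qq) ++k;
    double d = qq - v[k] * h;
    out[q] = d * d + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = out[q];
}

// Squared Euclidean distance (um^2) from each foreground voxel to the
// nearest background voxel; background voxels get 0. Voxels outside the
// grid count as background (the border is at half a voxel beyond the
// first/last sample, approximated as one full spacing step).
// [[Rcpp::export(name = ".edt_sq_3d")]]
NumericVector edt_sq_3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), out(nmax), zbnd(nmax + 1);
  std::vector<int> v(nmax);
  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      f.assign(nz, 0.0);
      for (int z = 0; z < nz; ++z) f[z] = g[lin(z, y, x, nz, ny)];
      dt1d(f, spacing[0], v, zbnd, out);
      for (int z = 0; z < nz; ++z) g[lin(z, y, x, nz, ny)] = f[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      f.assign(ny, 0.0);
      for (int y = 0; y < ny; ++y) f[y] = g[lin(z, y, x, nz, ny)];
      dt1d(f, spacing[1], v, zbnd, out);
      for (int y = 0; y < ny; ++y) g[lin(z, y, x, nz, ny)] = f[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      f.assign(nx, 0.0);
      for (int x = 0; x < nx; ++x) f[x] = g[lin(z, y, x, nz, ny)];
      dt1d(f, spacing[2], v, zbnd, out);
      for (int x = 0; x < nx; ++x) g[lin(z, y, x, nz, ny)] = f[x];
    }
  return g;
}

// 1-based linear indices of strict-ish 3D local maxima: voxel value above
// thresh and >= all 26 neighbours (neighbours outside the grid ignored).
// [[Rcpp::export(name = ".local_max_3d26")]]
IntegerVector local_max_3d26(NumericVector img, IntegerVector dim,
                             double thresh) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double val = img[lin(z, y, x, nz, ny)];
        if (!(val > thresh)) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1 && ismax; ++dx) {
              if (!dz && !dy && !dx) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                continue;
              if (img[lin(zz, yy, xx, nz, ny)] > val) ismax = false;
            }
        if (ismax) hits.push_back(lin(z, y, x, nz, ny) + 1);
      }
  return wrap(hits);
}

// Fill holes slice-by-slice (constant z): background 4-connected regions in
// the y-x plane not reachable from the slice border become foreground.
// [[Rcpp::export(name = ".fill_holes_slices")]]
LogicalVector fill_holes_slices(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out = clone(mask);
  std::vector<char> open((size_t)ny * nx);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    std::fill(open.begin(), open.end(), 0);
    stack.clear();
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool border = (y == 0 || y == ny - 1 || x == 0 || x == nx - 1);
        if (border && !mask[lin(z, y, x, nz, ny)]) {
          int p = y + ny * x;
          if (!open[p]) { open[p] = 1; stack.push_back(p); }
        }
      }
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int x = p / ny, y = p - x * ny;
      const int dy4[4] = {1, -1, 0, 0}, dx4[4] = {0, 0, 1, -1};
      for (int k = 0; k < 4; ++k) {
        int yy = y + dy4[k], xx = x + dx4[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int q = yy + ny * xx;
        if (!open[q] && !mask[lin(z, yy, xx, nz, ny)]) {
          open[q] = 1;
          stack.push_back(q);
        }
      }
    }
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (!mask[lin(z, y, x, nz, ny)] && !open[y + ny * x])
          out[lin(z, y, x, nz, ny)] = true;
  }
  return out;
}
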