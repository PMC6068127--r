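// Low-level 3D image primitives used by the segmentation and region modules:
// connected-component labelling, border flood fill (for hole filling), an
// exact squared Euclidean distance transform, separable Gaussian smoothing,
// and batched trilinear sampling. Arrays are R column-major logical/double
// vectors with dim = c(nx, ny, nz).
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
}

// Neighbour offsets for 6- or 26-connectivity.
static void neighbour_offsets(int conn, std::vector<std::array<int,3> > &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (conn == 6 && nz != 1) continue;
        off.push_back({dx, dy, dz});
      }
}

// [[Rcpp::export(name = ".cc_label3")]]
IntegerVector cc_label3(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3> > off;
  neighbour_offsets(connectivity, off);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t w = idx3(xx, yy, zz, nx, ny);
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Voxels of `open` reachable from the array border through `open` (6-conn).
// Complement of the result within `open` = enclosed cavities.
// [[Rcpp::export(name = ".flood_border3")]]
LogicalVector flood_border3(LogicalVector open, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, FALSE);
  std::vector<std::array<int,3> > off;
  neighbour_offsets(6, off);
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && y != 0 && z != 0 && x != nx - 1 && y != ny - 1 && z != nz - 1)
          continue;
        R_xlen_t v = idx3(x, y, z, nx, ny);
        if (open[v] && !out[v]) { out[v] = TRUE; stack.push_back(v); }
      }
  while (!stack.empty()) {
    R_xlen_t v = stack.back(); stack.pop_back();
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    for (size_t k = 0; k < off.size(); ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      R_xlen_t w = idx3(xx, yy, zz, nx, ny);
      if (open[w] && !out[w]) { out[w] = TRUE; stack.push_back(w); }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
static void edt1d(const double *f, double *d, int n, double step2,
                  int *v, double *zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -DBL_MAX;
  zbuf[1] = DBL_MAX;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + step2 * q * q) - (f[v[k]] + step2 * v[k] * v[k])) /
          (2.0 * step2 * (q - v[k]));
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = DBL_MAX;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = step2 * dq * dq + f[v[k]];
  }
}

// Exact squared EDT: distance from each TRUE voxel to the nearest FALSE voxel,
// in world units given anisotropic spacing. FALSE voxels get 0.
// [[Rcpp::export(name = ".edt3_sq")]]
NumericVector edt3_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  double s2 = spacing[0] * spacing[0];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = out[idx3(x, y, z, nx, ny)];
      edt1d(f.data(), d.data(), nx, s2, v.data(), zbuf.data());
      for (int x = 0; x < nx; ++x) out[idx3(x, y, z, nx, ny)] = d[x];
    }
  // pass along y
  s2 = spacing[1] * spacing[1];
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[idx3(x, y, z, nx, ny)];
      edt1d(f.data(), d.data(), ny, s2, v.data(), zbuf.data());
      for (int y = 0; y < ny; ++y) out[idx3(x, y, z, nx, ny)] = d[y];
    }
  // pass along z
  s2 = spacing[2] * spacing[2];
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[idx3(x, y, z, nx, ny)];
      edt1d(f.data(), d.data(), nz, s2, v.data(), zbuf.data());
      for (int z = 0; z < nz; ++z) out[idx3(x, y, z, nx, ny)] = d[z];
    }
  out.attr("dim") = dim;
  return out;
}

static void conv1(std::vector<double> &line, const std::vector<double> &ker) {
  int n = (int)line.size(), r = (int)(ker.size() - 1) / 2;
  std::vector<double> tmp(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0, wsum = 0.0;
    for (int k = -r; k <= r; ++k) {
      int j = i + k;
      if (j < 0 || j >= n) continue;
      acc += ker[k + r] * line[j];
      wsum += ker[k + r];
    }
    tmp[i] = acc / wsum;
  }
  line.swap(tmp);
}

// Separable Gaussian blur, sigma in voxels per axis (renormalised at borders).
// [[Rcpp::export(name = ".gauss_blur3")]]
NumericVector gauss_blur3(NumericVector img, IntegerVector dim, NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(img);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    for (int k = -r; k <= r; ++k) ker[k + r] = std::exp(-0.5 * k * k / (s * s));
    int nline = axis == 0 ? nx : (axis == 1 ? ny : nz);
    std::vector<double> line(nline);
    if (axis == 0) {
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          for (int x = 0; x < nx; ++x) line[x] = out[idx3(x, y, z, nx, ny)];
          conv1(line, ker);
          for (int x = 0; x < nx; ++x) out[idx3(x, y, z, nx, ny)] = line[x];
        }
    } else if (axis == 1) {
      for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
          for (int y = 0; y < ny; ++y) line[y] = out[idx3(x, y, z, nx, ny)];
          conv1(line, ker);
          for (int y = 0; y < ny; ++y) out[idx3(x, y, z, nx, ny)] = line[y];
        }
    } else {
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          for (int z = 0; z < nz; ++z) line[z] = out[idx3(x, y, z, nx, ny)];
          conv1(line, ker);
          for (int z = 0; z < nz; ++z) out[idx3(x, y, z, nx, ny)] = line[z];
        }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Trilinear sampling at continuous 0-based voxel coordinates (n x 3 matrix).
// Points outside the grid return `fill`.
// [[Rcpp::export(name = ".trilinear3")]]
NumericVector trilinear3(NumericVector img, IntegerVector dim,
                         NumericMatrix pts, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t np = pts.nrow();
  NumericVector out(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double c000 = img[idx3(x0, y0, z0, nx, ny)], c100 = img[idx3(x1, y0, z0, nx, ny)];
    double c010 = img[idx3(x0, y1, z0, nx, ny)], c110 = img[idx3(x1, y1, z0, nx, ny)];
    double c001 = img[idx3(x0, y0, z1, nx, ny)], c101 = img[idx3(x1, y0, z1, nx, ny)];
    double c011 = img[idx3(x0, y1, z1, nx, ny)], c111 = img[idx3(x1, y1, z1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling for label volumes.
// [[Rcpp::export(name = ".nearest3")]]
NumericVector nearest3(NumericVector img, IntegerVector dim,
                       NumericMatrix pts, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t np = pts.nrow();
  NumericVector out(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    int x = (int)std::lround(pts(i, 0));
    int y = (int)std::lround(pts(i, 1));
    int z = (int)std::lround(pts(i, 2));
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) out[i] = fill;
    else out[i] = img[idx3(x, y, z, nx, ny)];
  }
  return out;
}
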