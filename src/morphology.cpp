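// 3D binary image kernels: connected-component labelling, background
// reachability from the grid boundary, and dilation by an ellipsoidal
// structuring element. Grids are column-major (R array layout), 0-based
// internally.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<int> off_dx, off_dy, off_dz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        off_dx.push_back(dx); off_dy.push_back(dy); off_dz.push_back(dz);
      }
  const int noff = (int)off_dx.size();

  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next_label = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.clear();
    stack.push_back((int)start);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (nx * ny);
      int rem = cur - z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (int k = 0; k < noff; ++k) {
        int xx = x + off_dx[k], yy = y + off_dy[k], zz = z + off_dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int ni = idx3(xx, yy, zz, nx, ny);
        if (mask[ni] && labels[ni] == 0) {
          labels[ni] = next_label;
          stack.push_back(ni);
        }
      }
    }
  }
  return labels;
}

// Background voxels (mask == FALSE) 6-connected to the grid boundary.
// Complementing the result over the background gives the internal cavities.
// [[Rcpp::export]]
LogicalVector bg_reachable_from_boundary(LogicalVector mask, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  LogicalVector reach(n, false);
  std::vector<int> stack;
  // seed with all boundary background voxels
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x > 0 && x < nx - 1 && y > 0 && y < ny - 1 && z > 0 && z < nz - 1)
          continue;
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i] && !reach[i]) {
          reach[i] = true;
          stack.push_back(i);
        }
      }
  const int ddx[6] = {1, -1, 0, 0, 0, 0};
  const int ddy[6] = {0, 0, 1, -1, 0, 0};
  const int ddz[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    int cur = stack.back(); stack.pop_back();
    int z = cur / (nx * ny);
    int rem = cur - z * nx * ny;
    int y = rem / nx;
    int x = rem - y * nx;
    for (int k = 0; k < 6; ++k) {
      int xx = x + ddx[k], yy = y + ddy[k], zz = z + ddz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int ni = idx3(xx, yy, zz, nx, ny);
      if (!mask[ni] && !reach[ni]) {
        reach[ni] = true;
        stack.push_back(ni);
      }
    }
  }
  return reach;
}

// Binary dilation by an ellipsoidal structuring element with voxel radii
// (rx, ry, rz) (in voxels; anisotropic spacing is handled by the caller).
// Voxels outside the grid are treated as background.
// [[Rcpp::export]]
LogicalVector dilate_ellipsoid_3d(LogicalVector mask, IntegerVector dim,
                                  NumericVector radii_vox) {
  if (dim.size() != 3 || radii_vox.size() != 3) stop("bad dim/radii");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  const double rx = radii_vox[0], ry = radii_vox[1], rz = radii_vox[2];
  const int ix = (int)std::floor(rx), iy = (int)std::floor(ry),
            iz = (int)std::floor(rz);

  std::vector<int> off_dx, off_dy, off_dz;
  for (int dz = -iz; dz <= iz; ++dz)
    for (int dy = -iy; dy <= iy; ++dy)
      for (int dx = -ix; dx <= ix; ++dx) {
        double q = 0.0;
        if (rx > 0) q += (double)dx * dx / (rx * rx); else if (dx) continue;
        if (ry > 0) q += (double)dy * dy / (ry * ry); else if (dy) continue;
        if (rz > 0) q += (double)dz * dz / (rz * rz); else if (dz) continue;
        if (q <= 1.0 + 1e-12) {
          off_dx.push_back(dx); off_dy.push_back(dy); off_dz.push_back(dz);
        }
      }
  const int noff = (int)off_dx.size();

  LogicalVector out(n, false);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int z = (int)(i / ((R_xlen_t)nx * ny));
    int rem = (int)(i - (R_xlen_t)z * nx * ny);
    int y = rem / nx;
    int x = rem - y * nx;
    for (int k = 0; k < noff; ++k) {
      int xx = x + off_dx[k], yy = y + off_dy[k], zz = z + off_dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      out[idx3(xx, yy, zz, nx, ny)] = true;
    }
  }
  return out;
}
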