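#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 26-connected component labelling by iterative flood fill.
// Returns an integer array (same length as mask) of component ids, 0 = background.
// [[Rcpp::export]]
IntegerVector cc_label_26_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int cur = 0;
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    const int i0 = idx3(x, y, z, nx, ny);
    if (!mask[i0] || lab[i0]) continue;
    ++cur;
    lab[i0] = cur;
    stack.clear();
    stack.push_back(i0);
    while (!stack.empty()) {
      const int j = stack.back(); stack.pop_back();
      const int jx = j % nx, jy = (j / nx) % ny, jz = j / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        const int qx = jx + dx, qy = jy + dy, qz = jz + dz;
        if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
        const int q = idx3(qx, qy, qz, nx, ny);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Slice-wise 2-D hole filling: per axial (z) slice, flood the background from the
// slice border with 4-connectivity; unreached background voxels are holes.
// [[Rcpp::export]]
LogicalVector fill_holes_slices_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(clone(mask));
  std::vector<char> visited((size_t)nx * ny);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    std::fill(visited.begin(), visited.end(), 0);
    stack.clear();
    // seed from slice border
    for (int x = 0; x < nx; ++x) {
      for (int y : {0, ny - 1}) {
        const int i = idx3(x, y, z, nx, ny);
        if (!mask[i] && !visited[x + nx * y]) { visited[x + nx * y] = 1; stack.push_back(x + nx * y); }
      }
    }
    for (int y = 0; y < ny; ++y) {
      for (int x : {0, nx - 1}) {
        const int i = idx3(x, y, z, nx, ny);
        if (!mask[i] && !visited[x + nx * y]) { visited[x + nx * y] = 1; stack.push_back(x + nx * y); }
      }
    }
    while (!stack.empty()) {
      const int j = stack.back(); stack.pop_back();
      const int jx = j % nx, jy = j / nx;
      const int dx4[4] = {1, -1, 0, 0}, dy4[4] = {0, 0, 1, -1};
      for (int k = 0; k < 4; ++k) {
        const int qx = jx + dx4[k], qy = jy + dy4[k];
        if (qx < 0 || qy < 0 || qx >= nx || qy >= ny) continue;
        const int q2 = qx + nx * qy;
        if (!visited[q2] && !mask[idx3(qx, qy, z, nx, ny)]) { visited[q2] = 1; stack.push_back(q2); }
      }
    }
    for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
      const int i = idx3(x, y, z, nx, ny);
      if (!mask[i] && !visited[x + nx * y]) out[i] = true;
    }
  }
  return out;
}

// 3-D hole filling: background flooded from the volume border with 26-connectivity.
// [[Rcpp::export]]
LogicalVector fill_holes_3d_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<char> visited(n, 0);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    if (x != 0 && y != 0 && z != 0 && x != nx - 1 && y != ny - 1 && z != nz - 1) continue;
    const int i = idx3(x, y, z, nx, ny);
    if (!mask[i] && !visited[i]) { visited[i] = 1; stack.push_back(i); }
  }
  while (!stack.empty()) {
    const int j = stack.back(); stack.pop_back();
    const int jx = j % nx, jy = (j / nx) % ny, jz = j / (nx * ny);
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      const int qx = jx + dx, qy = jy + dy, qz = jz + dz;
      if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
      const int q = idx3(qx, qy, qz, nx, ny);
      if (!mask[q] && !visited[q]) { visited[q] = 1; stack.push_back(q); }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mask[i] || !visited[i];
  return out;
}

static std::vector<std::array<int, 3>> ball_offsets(double r) {
  std::vector<std::array<int, 3>> off;
  const int ri = (int)std::floor(r);
  for (int dz = -ri; dz <= ri; ++dz) for (int dy = -ri; dy <= ri; ++dy) for (int dx = -ri; dx <= ri; ++dx)
    if ((double)(dx * dx + dy * dy + dz * dz) <= r * r + 1e-9)
      off.push_back({dx, dy, dz});
  return off;
}

// [[Rcpp::export]]
LogicalVector dilate_ball_cpp(LogicalVector mask, IntegerVector dim, double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto off = ball_offsets(radius);
  LogicalVector out(mask.size(), false);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    if (!mask[idx3(x, y, z, nx, ny)]) continue;
    for (auto &o : off) {
      const int qx = x + o[0], qy = y + o[1], qz = z + o[2];
      if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
      out[idx3(qx, qy, qz, nx, ny)] = true;
    }
  }
  return out;
}

// Erosion; voxels outside the grid are treated as foreground so that the volume
// border does not erode structures that extend through it.
// [[Rcpp::export]]
LogicalVector erode_ball_cpp(LogicalVector mask, IntegerVector dim, double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto off = ball_offsets(radius);
  LogicalVector out(mask.size(), false);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    const int i = idx3(x, y, z, nx, ny);
    if (!mask[i]) continue;
    bool keep = true;
    for (auto &o : off) {
      const int qx = x + o[0], qy = y + o[1], qz = z + o[2];
      if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
      if (!mask[idx3(qx, qy, qz, nx, ny)]) { keep = false; break; }
    }
    out[i] = keep;
  }
  return out;
}

// TRUE for mask voxels 26-adjacent to a voxel where other==TRUE.
// [[Rcpp::export]]
LogicalVector touches_cpp(LogicalVector mask, LogicalVector other, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    const int i = idx3(x, y, z, nx, ny);
    if (!mask[i]) continue;
    bool hit = false;
    for (int dz = -1; dz <= 1 && !hit; ++dz) for (int dy = -1; dy <= 1 && !hit; ++dy) for (int dx = -1; dx <= 1 && !hit; ++dx) {
      if (!dx && !dy && !dz) continue;
      const int qx = x + dx, qy = y + dy, qz = z + dz;
      if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
      if (other[idx3(qx, qy, qz, nx, ny)]) hit = true;
    }
    out[i] = hit;
  }
  return out;
}
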