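#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Uniform cubic B-spline kernel, support |t| < 2 (t in control-grid units).
static inline double bspl(double t) {
  t = std::fabs(t);
  if (t < 1.0) return (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
  if (t < 2.0) { const double u = 2.0 - t; return u * u * u / 6.0; }
  return 0.0;
}

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Expand a control grid of displacements into a dense per-voxel field.
// disp: (ncx, ncy, ncz, 3) control-point displacement array (voxel units);
// control k (0-based) sits at voxel coordinate (k - 1) * spacing.
// Returns (nx, ny, nz, 3) dense field.
// [[Rcpp::export]]
NumericVector ffd_expand_cpp(NumericVector disp, IntegerVector ncdim,
                             IntegerVector shape, NumericVector spacing) {
  const int ncx = ncdim[0], ncy = ncdim[1], ncz = ncdim[2];
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const int nvox = nx * ny * nz, nctl = ncx * ncy * ncz;
  NumericVector out((R_xlen_t)nvox * 3);
  for (int z = 0; z < nz; ++z) {
    const int jz = (int)std::floor(z / sz);
    double wz[4]; int kz[4];
    for (int l = 0; l < 4; ++l) { kz[l] = jz - 1 + l + 1; wz[l] = bspl(z / sz - (kz[l] - 1)); }
    for (int y = 0; y < ny; ++y) {
      const int jy = (int)std::floor(y / sy);
      double wy[4]; int ky[4];
      for (int l = 0; l < 4; ++l) { ky[l] = jy - 1 + l + 1; wy[l] = bspl(y / sy - (ky[l] - 1)); }
      for (int x = 0; x < nx; ++x) {
        const int jx = (int)std::floor(x / sx);
        double wx[4]; int kx[4];
        for (int l = 0; l < 4; ++l) { kx[l] = jx - 1 + l + 1; wx[l] = bspl(x / sx - (kx[l] - 1)); }
        double acc[3] = {0.0, 0.0, 0.0};
        for (int lz = 0; lz < 4; ++lz) {
          if (kz[lz] < 0 || kz[lz] >= ncz) continue;
          for (int ly = 0; ly < 4; ++ly) {
            if (ky[ly] < 0 || ky[ly] >= ncy) continue;
            const double wzy = wz[lz] * wy[ly];
            for (int lx = 0; lx < 4; ++lx) {
              if (kx[lx] < 0 || kx[lx] >= ncx) continue;
              const double w = wzy * wx[lx];
              if (w == 0.0) continue;
              const int c = kx[lx] + ncx * (ky[ly] + ncy * kz[lz]);
              for (int d = 0; d < 3; ++d) acc[d] += w * disp[c + (R_xlen_t)nctl * d];
            }
          }
        }
        const int v = idx3(x, y, z, nx, ny);
        for (int d = 0; d < 3; ++d) out[v + (R_xlen_t)nvox * d] = acc[d];
      }
    }
  }
  return out;
}

static inline double sample_trilinear(const double *src, int nx, int ny, int nz,
                                      double px, double py, double pz, double fill) {
  if (px < 0 || py < 0 || pz < 0 || px > nx - 1 || py > ny - 1 || pz > nz - 1) return fill;
  const int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
  const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
  const double fx = px - x0, fy = py - y0, fz = pz - z0;
  double v = 0.0;
  for (int cz = 0; cz <= 1; ++cz) for (int cy = 0; cy <= 1; ++cy) for (int cx = 0; cx <= 1; ++cx) {
    const double w = (cx ? fx : 1 - fx) * (cy ? fy : 1 - fy) * (cz ? fz : 1 - fz);
    if (w == 0.0) continue;
    v += w * src[idx3(cx ? x1 : x0, cy ? y1 : y0, cz ? z1 : z0, nx, ny)];
  }
  return v;
}

// Pull-back warp of a gray volume: out(x) = src(x + field(x)), trilinear.
// [[Rcpp::export]]
NumericVector warp_trilinear_cpp(NumericVector src, IntegerVector dim,
                                 NumericVector field, double fill,
                                 bool clamp = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  const double *s = REAL(src);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    const int i = idx3(x, y, z, nx, ny);
    double px = x + field[i], py = y + field[i + (R_xlen_t)n];
    double pz = z + field[i + 2 * (R_xlen_t)n];
    if (clamp) {
      px = std::min(std::max(px, 0.0), (double)(nx - 1));
      py = std::min(std::max(py, 0.0), (double)(ny - 1));
      pz = std::min(std::max(pz, 0.0), (double)(nz - 1));
    }
    out[i] = sample_trilinear(s, nx, ny, nz, px, py, pz, fill);
  }
  return out;
}

// Pull-back warp of a label map: nearest-neighbour transport.
// [[Rcpp::export]]
IntegerVector warp_nearest_cpp(IntegerVector src, IntegerVector dim,
                               NumericVector field, int fill,
                               bool clamp = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector out(n);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    const int i = idx3(x, y, z, nx, ny);
    const double px = x + field[i], py = y + field[i + (R_xlen_t)n], pz = z + field[i + 2 * (R_xlen_t)n];
    int qx = (int)std::lround(px), qy = (int)std::lround(py), qz = (int)std::lround(pz);
    if (clamp) {
      qx = std::min(std::max(qx, 0), nx - 1);
      qy = std::min(std::max(qy, 0), ny - 1);
      qz = std::min(std::max(qz, 0), nz - 1);
    }
    out[i] = (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
               ? fill : src[idx3(qx, qy, qz, nx, ny)];
  }
  return out;
}

// One deterministic ICM pass over all control points.
// For each control point in raster order, candidate displacements
// current + step * {-1,0,1}^3 are scored by the B-spline-support-weighted local
// sum of absolute differences plus a first-order smoothness penalty
// lambda * sum_{grid neighbours} ||d - d_nb||; strict improvement is required.
// The dense field is updated incrementally after each accepted move.
// Returns list(disp, changes).
// [[Rcpp::export]]
List ffd_icm_pass_cpp(NumericVector target, NumericVector source, IntegerVector dim,
                      NumericVector disp, IntegerVector ncdim, NumericVector spacing,
                      double step, double lambda, int stride, double max_disp,
                      double fill, double support_half) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ncx = ncdim[0], ncy = ncdim[1], ncz = ncdim[2];
  const int nvox = nx * ny * nz, nctl = ncx * ncy * ncz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector d(clone(disp));
  NumericVector field = ffd_expand_cpp(d, ncdim, dim, spacing);
  const double *tg = REAL(target);
  const double *sr = REAL(source);
  int changes = 0;

  for (int cz = 0; cz < ncz; ++cz) for (int cy = 0; cy < ncy; ++cy) for (int cx = 0; cx < ncx; ++cx) {
    const int c = cx + ncx * (cy + ncy * cz);
    // control position in voxel coordinates
    const double pcx = (cx - 1) * sx, pcy = (cy - 1) * sy, pcz = (cz - 1) * sz;
    const int x0 = std::max(0, (int)std::ceil(pcx - 2 * sx + 1e-9));
    const int x1 = std::min(nx - 1, (int)std::floor(pcx + 2 * sx - 1e-9));
    const int y0 = std::max(0, (int)std::ceil(pcy - 2 * sy + 1e-9));
    const int y1 = std::min(ny - 1, (int)std::floor(pcy + 2 * sy - 1e-9));
    const int z0 = std::max(0, (int)std::ceil(pcz - 2 * sz + 1e-9));
    const int z1 = std::min(nz - 1, (int)std::floor(pcz + 2 * sz - 1e-9));
    if (x0 > x1 || y0 > y1 || z0 > z1) continue;

    // energy evaluation restricted to the inner support (weights beyond
    // support_half cells contribute little); dense updates use full support
    const int ex0 = std::max(0, (int)std::ceil(pcx - support_half * sx));
    const int ex1 = std::min(nx - 1, (int)std::floor(pcx + support_half * sx));
    const int ey0 = std::max(0, (int)std::ceil(pcy - support_half * sy));
    const int ey1 = std::min(ny - 1, (int)std::floor(pcy + support_half * sy));
    const int ez0 = std::max(0, (int)std::ceil(pcz - support_half * sz));
    const int ez1 = std::min(nz - 1, (int)std::floor(pcz + support_half * sz));
    if (ex0 > ex1 || ey0 > ey1 || ez0 > ez1) continue;

    const double cur0 = d[c], cur1 = d[c + (R_xlen_t)nctl], cur2 = d[c + 2 * (R_xlen_t)nctl];

    // smoothness: 6-neighbour control points
    double nb[6][3]; int nnb = 0;
    const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int k = 0; k < 6; ++k) {
      const int qx = cx + off[k][0], qy = cy + off[k][1], qz = cz + off[k][2];
      if (qx < 0 || qy < 0 || qz < 0 || qx >= ncx || qy >= ncy || qz >= ncz) continue;
      const int q = qx + ncx * (qy + ncy * qz);
      nb[nnb][0] = d[q]; nb[nnb][1] = d[q + (R_xlen_t)nctl]; nb[nnb][2] = d[q + 2 * (R_xlen_t)nctl];
      ++nnb;
    }

    double best_e = R_PosInf;
    double best[3] = {cur0, cur1, cur2};
    bool have_cur = false;
    double cur_e = R_PosInf;

    for (int az = -1; az <= 1; ++az) for (int ay = -1; ay <= 1; ++ay) for (int ax = -1; ax <= 1; ++ax) {
      const double cd0 = cur0 + step * ax, cd1 = cur1 + step * ay, cd2 = cur2 + step * az;
      if (std::fabs(cd0) > max_disp || std::fabs(cd1) > max_disp || std::fabs(cd2) > max_disp) continue;
      // local data energy over the support, stride-subsampled, B-spline weighted
      double e = 0.0;
      for (int z = ez0; z <= ez1; z += stride) {
        const double wz = bspl((z - pcz) / sz);
        if (wz == 0.0) continue;
        for (int y = ey0; y <= ey1; y += stride) {
          const double wzy = wz * bspl((y - pcy) / sy);
          if (wzy == 0.0) continue;
          for (int x = ex0; x <= ex1; x += stride) {
            const double w = wzy * bspl((x - pcx) / sx);
            if (w == 0.0) continue;
            const int i = idx3(x, y, z, nx, ny);
            const double w3 = w;
            const double px = x + field[i] + (cd0 - cur0) * w3;
            const double py = y + field[i + (R_xlen_t)nvox] + (cd1 - cur1) * w3;
            const double pz = z + field[i + 2 * (R_xlen_t)nvox] + (cd2 - cur2) * w3;
            e += w3 * std::fabs(tg[i] - sample_trilinear(sr, nx, ny, nz, px, py, pz, fill));
          }
        }
      }
      // smoothness energy
      double es = 0.0;
      for (int k = 0; k < nnb; ++k) {
        const double d0 = cd0 - nb[k][0], d1 = cd1 - nb[k][1], d2 = cd2 - nb[k][2];
        es += std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
      }
      e += lambda * es;
      const bool is_cur = (ax == 0 && ay == 0 && az == 0);
      if (is_cur) { cur_e = e; have_cur = true; }
      if (e < best_e - 1e-12) { best_e = e; best[0] = cd0; best[1] = cd1; best[2] = cd2; }
    }

    if (have_cur && best_e < cur_e - 1e-9 &&
        (best[0] != cur0 || best[1] != cur1 || best[2] != cur2)) {
      // incremental dense-field update over the full support
      const double dd0 = best[0] - cur0, dd1 = best[1] - cur1, dd2 = best[2] - cur2;
      for (int z = z0; z <= z1; ++z) {
        const double wz = bspl((z - pcz) / sz);
        if (wz == 0.0) continue;
        for (int y = y0; y <= y1; ++y) {
          const double wzy = wz * bspl((y - pcy) / sy);
          if (wzy == 0.0) continue;
          for (int x = x0; x <= x1; ++x) {
            const double w = wzy * bspl((x - pcx) / sx);
            if (w == 0.0) continue;
            const int i = idx3(x, y, z, nx, ny);
            field[i] += dd0 * w;
            field[i + (R_xlen_t)nvox] += dd1 * w;
            field[i + 2 * (R_xlen_t)nvox] += dd2 * w;
          }
        }
      }
      d[c] = best[0]; d[c + (R_xlen_t)nctl] = best[1]; d[c + 2 * (R_xlen_t)nctl] = best[2];
      ++changes;
    }
  }
  return List::create(Named("disp") = d, Named("changes") = changes);
}
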