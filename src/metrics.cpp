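#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Surface voxels: positive voxels with at least one 6-connected neighbour
// negative or lying on the grid edge.
// [[Rcpp::export]]
LogicalVector boundary_6_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    const int i = idx3(x, y, z, nx, ny);
    if (!mask[i]) continue;
    bool b = false;
    for (int k = 0; k < 6 && !b; ++k) {
      const int qx = x + off[k][0], qy = y + off[k][1], qz = z + off[k][2];
      if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) { b = true; break; }
      if (!mask[idx3(qx, qy, qz, nx, ny)]) b = true;
    }
    out[i] = b;
  }
  return out;
}

// Symmetric Hausdorff distance between two point sets (rows = points, columns
// = physical coordinates in mm). Exact all-pairs max-min in both directions.
// [[Rcpp::export]]
double hausdorff_points_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  double h = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    const NumericMatrix &X = pass == 0 ? a : b;
    const NumericMatrix &Y = pass == 0 ? b : a;
    const int nX = pass == 0 ? na : nb, nY = pass == 0 ? nb : na;
    for (int i = 0; i < nX; ++i) {
      double mn = R_PosInf;
      const double x0 = X(i, 0), x1 = X(i, 1), x2 = X(i, 2);
      for (int j = 0; j < nY; ++j) {
        const double d0 = x0 - Y(j, 0), d1 = x1 - Y(j, 1), d2 = x2 - Y(j, 2);
        const double d = d0 * d0 + d1 * d1 + d2 * d2;
        if (d < mn) {
          mn = d;
          if (mn <= h * h) break;  // cannot raise the running max
        }
      }
      if (mn > h * h && R_finite(mn)) h = std::sqrt(mn);
    }
  }
  return h;
}
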