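#include <Rcpp.h>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// One ICM sweep in fixed raster order over mask voxels.
// labels: current map in 0..L-1 (background = 0, frozen outside mask);
// logprior: nvox x L; logint: L x Q (per-label log intensity density);
// g: voxel gray levels 0..Q-1; veq: Potts potential.
// Conditional score of label l at voxel v:
//   logprior(v,l) + logint(l, g_v) + veq * (2 * #eq_neighbours(l) - #valid).
// Ties go to the lowest label id. Returns list(labels, changes).
// [[Rcpp::export]]
List icm_sweep_cpp(IntegerVector labels, IntegerVector dim, LogicalVector mask,
                   NumericMatrix logprior, NumericMatrix logint,
                   IntegerVector g, double veq) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int L = logprior.ncol();
  IntegerVector lab(clone(labels));
  int changes = 0;
  std::vector<int> cnt(L);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    const int i = idx3(x, y, z, nx, ny);
    if (!mask[i]) continue;
    std::fill(cnt.begin(), cnt.end(), 0);
    int nvalid = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      const int qx = x + dx, qy = y + dy, qz = z + dz;
      if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
      const int q = idx3(qx, qy, qz, nx, ny);
      if (!mask[q]) continue;  // domain-restricted MGRF, matching the estimator
      ++nvalid;
      ++cnt[lab[q]];
    }
    int best = 0;
    double best_s = R_NegInf;
    for (int l = 0; l < L; ++l) {
      const double s = logprior(i, l) + logint(l, g[i]) + veq * (2.0 * cnt[l] - nvalid);
      if (s > best_s + 1e-12) { best_s = s; best = l; }
    }
    if (best != lab[i]) { lab[i] = best; ++changes; }
  }
  return List::create(Named("labels") = lab, Named("changes") = changes);
}

// Joint MGRF objective of a map under fixed models:
//   sum_{v in mask} [logprior(v, m_v) + logint(m_v, g_v)]
//   + veq * sum_{unordered 26-pairs, both in bounds, >=1 endpoint in mask}
//       (+1 if equal else -1).
// Single-site moves to the conditional argmax never decrease this.
// [[Rcpp::export]]
double map_objective_cpp(IntegerVector labels, IntegerVector dim, LogicalVector mask,
                         NumericMatrix logprior, NumericMatrix logint,
                         IntegerVector g, double veq) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  static const int POS13[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
  };
  double obj = 0.0;
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    const int i = idx3(x, y, z, nx, ny);
    if (mask[i]) obj += logprior(i, labels[i]) + logint(labels[i], g[i]);
    for (int k = 0; k < 13; ++k) {
      const int qx = x + POS13[k][0], qy = y + POS13[k][1], qz = z + POS13[k][2];
      if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
      const int q = idx3(qx, qy, qz, nx, ny);
      if (!mask[i] || !mask[q]) continue;  // pairs wholly inside the domain
      obj += veq * (labels[i] == labels[q] ? 1.0 : -1.0);
    }
  }
  return obj;
}
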