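#include <Rcpp.h>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// The 13 positive-direction offsets of the 26-neighbourhood; iterating these
// once per voxel visits every unordered neighbour pair exactly once.
static const int POS13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
  {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// Count equal-label and total unordered 26-neighbour pairs. Pairs crossing the
// volume boundary are dropped; if use_mask, both endpoints must lie in mask.
// [[Rcpp::export]]
NumericVector pair_stats_26_cpp(IntegerVector labels, IntegerVector dim,
                                LogicalVector mask, bool use_mask) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double neq = 0.0, ntot = 0.0;
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    const int i = idx3(x, y, z, nx, ny);
    if (use_mask && !mask[i]) continue;
    for (int k = 0; k < 13; ++k) {
      const int qx = x + POS13[k][0], qy = y + POS13[k][1], qz = z + POS13[k][2];
      if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
      const int q = idx3(qx, qy, qz, nx, ny);
      if (use_mask && !mask[q]) continue;
      ntot += 1.0;
      if (labels[i] == labels[q]) neq += 1.0;
    }
  }
  return NumericVector::create(neq, ntot);
}

// Voxel-wise Potts conditionals: p(l) propto exp(sum_nb V(l, m_nb)) with
// V = v_eq for equal labels and -v_eq otherwise, over in-bounds 26-neighbours.
// labels must be in 0..L-1. Returns an (nvox x L) matrix of probabilities.
// [[Rcpp::export]]
NumericMatrix spatial_probs_cpp(IntegerVector labels, IntegerVector dim,
                                int L, double veq) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericMatrix out(n, L);
  std::vector<int> cnt(L);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    const int i = idx3(x, y, z, nx, ny);
    std::fill(cnt.begin(), cnt.end(), 0);
    int nvalid = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      const int qx = x + dx, qy = y + dy, qz = z + dz;
      if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
      ++nvalid;
      ++cnt[labels[idx3(qx, qy, qz, nx, ny)]];
    }
    // score_l = veq*cnt_l + (-veq)*(nvalid-cnt_l) = veq*(2*cnt_l - nvalid)
    double mx = R_NegInf;
    for (int l = 0; l < L; ++l) {
      const double s = veq * (2.0 * cnt[l] - nvalid);
      out(i, l) = s;
      if (s > mx) mx = s;
    }
    double tot = 0.0;
    for (int l = 0; l < L; ++l) { out(i, l) = std::exp(out(i, l) - mx); tot += out(i, l); }
    for (int l = 0; l < L; ++l) out(i, l) /= tot;
  }
  return out;
}
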