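// Threshold-free cluster enhancement and the sign-flip permutation null.
//
// TFCE(v) = sum over thresholds h (dh to max in n_steps equal increments) of
//   extent(h, v)^E * h^H * dh,
// where extent(h, v) is the voxel count of the connected component
// containing v in the supra-threshold set {stat >= h} under 6/18/26
// connectivity. Computed by a single sweep from the highest threshold down,
// growing components with a union-find as voxels cross each threshold.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Neigh {
  std::vector<int> dx, dy, dz;
};

Neigh neighbour_offsets(int connectivity) {
  Neigh n;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        bool keep = (connectivity == 26) ? true
          : (connectivity == 18) ? (manh <= 2)
          : (manh == 1);  // 6-connectivity
        if (keep) { n.dx.push_back(dx); n.dy.push_back(dy); n.dz.push_back(dz); }
      }
  return n;
}

class UnionFind {
public:
  explicit UnionFind(int n) : parent_(n, -1), size_(n, 0) {}
  void reset() { std::fill(parent_.begin(), parent_.end(), -1); }
  bool active(int v) const { return parent_[v] >= 0; }
  void add(int v) { parent_[v] = v; size_[v] = 1; }
  int find(int v) {
    int r = v;
    while (parent_[r] != r) r = parent_[r];
    while (parent_[v] != r) { int nxt = parent_[v]; parent_[v] = r; v = nxt; }
    return r;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size_[a] < size_[b]) std::swap(a, b);
    parent_[b] = a;
    size_[a] += size_[b];
  }
  int size_of_root(int r) const { return size_[r]; }
private:
  std::vector<int> parent_, size_;
};

// One TFCE evaluation over the full grid. `stat` has length nx*ny*nz;
// only voxels with in_mask and stat > 0 contribute. Adds into `out`
// (caller zeroes it). Returns the maximum TFCE value over the grid.
double tfce_core(const double* stat, const std::vector<char>& in_mask,
                 int nx, int ny, int nz, double H, double E, int n_steps,
                 const Neigh& nb, UnionFind& uf, double* out) {
  const int nvox = nx * ny * nz;
  std::vector<int> active;
  active.reserve(1024);
  double hmax = 0.0;
  for (int v = 0; v < nvox; ++v)
    if (in_mask[v] && stat[v] > 0.0) {
      active.push_back(v);
      if (stat[v] > hmax) hmax = stat[v];
    }
  if (active.empty() || hmax <= 0.0) return 0.0;

  std::sort(active.begin(), active.end(),
            [stat](int a, int b) { return stat[a] > stat[b]; });
  uf.reset();
  const double dh = hmax / n_steps;
  const bool fast_pow = (E == 0.5 && H == 2.0);
  const int nxy = nx * ny;
  std::size_t ptr = 0;
  std::vector<int> added;
  added.reserve(active.size());
  double out_max = 0.0;

  for (int k = n_steps; k >= 1; --k) {
    // h = hmax at k = n_steps exactly, so the peak voxel always enters at
    // the top threshold (keeps the c^(H+1) homogeneity exact under scaling)
    const double h = hmax * ((double)k / n_steps);
    while (ptr < active.size() && stat[active[ptr]] >= h) {
      const int v = active[ptr++];
      uf.add(v);
      added.push_back(v);
      const int x = v % nx, y = (v / nx) % ny, z = v / nxy;
      for (std::size_t j = 0; j < nb.dx.size(); ++j) {
        const int X = x + nb.dx[j], Y = y + nb.dy[j], Z = z + nb.dz[j];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        const int w = X + Y * nx + Z * nxy;
        if (uf.active(w)) uf.unite(v, w);
      }
    }
    const double hpow = fast_pow ? h * h : std::pow(h, H);
    const double inc_base = hpow * dh;
    for (std::size_t i = 0; i < added.size(); ++i) {
      const int v = added[i];
      const double sz = (double)uf.size_of_root(uf.find(v));
      const double inc = (fast_pow ? std::sqrt(sz) : std::pow(sz, E)) * inc_base;
      out[v] += inc;
      if (out[v] > out_max) out_max = out[v];
    }
  }
  return out_max;
}

std::vector<char> mask_to_char(const LogicalVector& mask) {
  std::vector<char> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = (mask[i] == TRUE);
  return m;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector stat, LogicalVector mask,
                       IntegerVector dims, double h_power, double e_power,
                       int n_steps, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  if (stat.size() != nvox || mask.size() != nvox)
    stop("stat/mask size does not match dims");
  NumericVector out(nvox, 0.0);
  Neigh nb = neighbour_offsets(connectivity);
  UnionFind uf(nvox);
  std::vector<char> m = mask_to_char(mask);
  tfce_core(REAL(stat), m, nx, ny, nz, h_power, e_power, n_steps, nb, uf,
            REAL(out));
  return out;
}

// Sign-flip permutation null of the maximum TFCE statistic, both
// directions. diffs: n_mask x n_subj per-subject difference values on the
// mask; signs: n_subj x n_perm matrix of +/-1, first column the observed
// labeling; mask_idx: 0-based indices of mask voxels in the full grid.
// Returns the n_perm x 2 null maxima (pos, neg) plus the TFCE maps of the
// first (observed) permutation, so observed maps and null share identical
// arithmetic.
// [[Rcpp::export]]
List cpp_perm_null_max(NumericMatrix diffs, IntegerMatrix signs,
                       IntegerVector dims, IntegerVector mask_idx,
                       double h_power, double e_power, int n_steps,
                       int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  const int n_mask = diffs.nrow(), n_sub = diffs.ncol();
  const int n_perm = signs.ncol();
  if (signs.nrow() != n_sub) stop("signs/diffs subject mismatch");
  if (mask_idx.size() != n_mask) stop("mask_idx/diffs mismatch");

  std::vector<char> in_mask(nvox, 0);
  for (int v = 0; v < n_mask; ++v) in_mask[mask_idx[v]] = 1;

  Neigh nb = neighbour_offsets(connectivity);
  UnionFind uf(nvox);
  std::vector<double> stat(nvox, 0.0), tf(nvox, 0.0);
  NumericMatrix out(n_perm, 2);
  NumericVector obs_t(nvox), obs_pos(nvox), obs_neg(nvox);
  const double n = (double)n_sub;

  for (int p = 0; p < n_perm; ++p) {
    for (int v = 0; v < n_mask; ++v) {
      // two-pass (centered) variance, summed in subject order: identical
      // floating-point arithmetic to the R paired t-map, so the identity
      // permutation reproduces the observed TFCE maximum exactly
      double m = 0.0;
      for (int s = 0; s < n_sub; ++s) m += signs(s, p) * diffs(v, s);
      m /= n;
      double ss = 0.0;
      for (int s = 0; s < n_sub; ++s) {
        const double d = signs(s, p) * diffs(v, s) - m;
        ss += d * d;
      }
      double var = ss / (n - 1.0);
      // relative guard against cancellation when all differences are equal
      bool zero = var <= 1e-24 + 1e-20 * m * m;
      stat[mask_idx[v]] = zero ? 0.0 : m / std::sqrt(var / n);
    }
    std::fill(tf.begin(), tf.end(), 0.0);
    out(p, 0) = tfce_core(stat.data(), in_mask, nx, ny, nz, h_power, e_power,
                          n_steps, nb, uf, tf.data());
    if (p == 0) {
      std::copy(stat.begin(), stat.end(), obs_t.begin());
      std::copy(tf.begin(), tf.end(), obs_pos.begin());
    }
    for (int v = 0; v < n_mask; ++v) stat[mask_idx[v]] = -stat[mask_idx[v]];
    std::fill(tf.begin(), tf.end(), 0.0);
    out(p, 1) = tfce_core(stat.data(), in_mask, nx, ny, nz, h_power, e_power,
                          n_steps, nb, uf, tf.data());
    if (p == 0) std::copy(tf.begin(), tf.end(), obs_neg.begin());
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(Named("max") = out, Named("t_obs") = obs_t,
                      Named("tfce_pos") = obs_pos,
                      Named("tfce_neg") = obs_neg);
}
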