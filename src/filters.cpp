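// Spatial filters: separable 3-D convolution (zero-padded boundaries) and
// a masked cubic median filter.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// Convolve along one axis with zero boundary. src and dst are nx*ny*nz.
void conv_axis(const double* src, double* dst, int nx, int ny, int nz,
               const double* kern, int r, int axis) {
  const int nxy = nx * ny;
  const int stride = (axis == 0) ? 1 : (axis == 1) ? nx : nxy;
  const int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const int n_outer = nx * ny * nz / len;
  for (int o = 0; o < n_outer; ++o) {
    // decompose outer index into the two non-axis coordinates
    int base;
    if (axis == 0) { int y = o % ny, z = o / ny; base = y * nx + z * nxy; }
    else if (axis == 1) { int x = o % nx, z = o / nx; base = x + z * nxy; }
    else { int x = o % nx, y = o / nx; base = x + y * nx; }
    for (int i = 0; i < len; ++i) {
      double acc = 0.0;
      const int j0 = std::max(0, i - r), j1 = std::min(len - 1, i + r);
      for (int j = j0; j <= j1; ++j)
        acc += src[base + j * stride] * kern[r + (i - j)];
      dst[base + i * stride] = acc;
    }
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_separable_conv3(NumericVector arr, IntegerVector dims,
                                  NumericVector kernel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  if (arr.size() != nvox) stop("array/dims mismatch");
  if (kernel.size() % 2 == 0) stop("kernel length must be odd");
  const int r = (kernel.size() - 1) / 2;
  std::vector<double> buf(nvox);
  NumericVector out(nvox);
  conv_axis(REAL(arr), buf.data(), nx, ny, nz, REAL(kernel), r, 0);
  conv_axis(buf.data(), REAL(out), nx, ny, nz, REAL(kernel), r, 1);
  std::copy(REAL(out), REAL(out) + nvox, buf.data());
  conv_axis(buf.data(), REAL(out), nx, ny, nz, REAL(kernel), r, 2);
  return out;
}

// Median over a (2r+1)^3 window, restricted to `valid` voxels; voxels
// outside `valid` are passed through unchanged. Window entries outside the
// grid or outside `valid` are ignored.
// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector arr, LogicalVector valid,
                                 IntegerVector dims, int radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  if (arr.size() != nvox || valid.size() != nvox) stop("array/dims mismatch");
  NumericVector out(clone(arr));
  std::vector<double> window;
  window.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  const int nxy = nx * ny;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int v = x + y * nx + z * nxy;
        if (valid[v] != TRUE) continue;
        window.clear();
        for (int dz = -radius; dz <= radius; ++dz) {
          const int Z = z + dz; if (Z < 0 || Z >= nz) continue;
          for (int dy = -radius; dy <= radius; ++dy) {
            const int Y = y + dy; if (Y < 0 || Y >= ny) continue;
            for (int dx = -radius; dx <= radius; ++dx) {
              const int X = x + dx; if (X < 0 || X >= nx) continue;
              const int w = X + Y * nx + Z * nxy;
              if (valid[w] == TRUE) window.push_back(arr[w]);
            }
          }
        }
        if (window.empty()) continue;
        const std::size_t mid = window.size() / 2;
        std::nth_element(window.begin(), window.begin() + mid, window.end());
        double med = window[mid];
        if (window.size() % 2 == 0) {
          double lo = *std::max_element(window.begin(), window.begin() + mid);
          med = 0.5 * (med + lo);
        }
        out[v] = med;
      }
  return out;
}
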