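#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Separable box erosion/dilation on a 3D logical grid.
// Offsets [lo[a], hi[a]] per axis; out-of-grid voxels count as background
// (false) for both operations, so erosion eats the border and dilation
// never wraps. A cube structuring element of edge d uses lo = -floor((d-1)/2),
// hi = ceil((d-1)/2); its reflection swaps lo/hi.
static void pass1d(std::vector<int>& in, std::vector<int>& out,
                   const int* dims, int axis, int lo, int hi, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long strides[3] = {1L, (long)nx, (long)nx * ny};
  const long stride = strides[axis];
  const int len = dims[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long idx = i + (long)nx * (j + (long)ny * k);
        int pos = (axis == 0) ? i : (axis == 1 ? j : k);
        int acc = dilate ? 0 : 1;
        for (int o = lo; o <= hi; ++o) {
          int p = pos + o;
          int v = (p < 0 || p >= len) ? 0 : in[idx + (long)o * stride];
          if (dilate) { if (v) { acc = 1; break; } }
          else        { if (!v) { acc = 0; break; } }
        }
        out[idx] = acc;
      }
}

// [[Rcpp::export]]
LogicalVector cpp_box_morph(LogicalVector mask, IntegerVector dims,
                            IntegerVector lo, IntegerVector hi, bool dilate) {
  const long n = (long)dims[0] * dims[1] * dims[2];
  std::vector<int> a(n), b(n);
  for (long i = 0; i < n; ++i) a[i] = mask[i] == TRUE;
  int d[3] = {dims[0], dims[1], dims[2]};
  for (int axis = 0; axis < 3; ++axis) {
    pass1d(a, b, d, axis, lo[axis], hi[axis], dilate);
    std::swap(a, b);
  }
  LogicalVector out(n);
  for (long i = 0; i < n; ++i) out[i] = a[i] ? TRUE : FALSE;
  out.attr("dim") = dims;
  return out;
}

// 3D median filter, cubic (2r+1)^3 neighbourhood, borders handled by
// nearest-value replication (index clamping).
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dims, int radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(vol.size());
  const int w = 2 * radius + 1;
  std::vector<double> buf(w * w * w);
  const double* v = vol.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int m = 0;
        for (int dz = -radius; dz <= radius; ++dz) {
          int kk = std::min(std::max(k + dz, 0), nz - 1);
          for (int dy = -radius; dy <= radius; ++dy) {
            int jj = std::min(std::max(j + dy, 0), ny - 1);
            for (int dx = -radius; dx <= radius; ++dx) {
              int ii = std::min(std::max(i + dx, 0), nx - 1);
              buf[m++] = v[ii + (long)nx * (jj + (long)ny * kk)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[i + (long)nx * (j + (long)ny * k)] = buf[m / 2];
      }
  out.attr("dim") = dims;
  return out;
}

// Separable Gaussian smoothing, zero-padded borders (background outside the
// grid). Used to band-limit binary masks ahead of isosurface extraction.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dims,
                          double sigma, bool renormalize = false) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0;
  for (int o = -r; o <= r; ++o) {
    kern[o + r] = std::exp(-0.5 * o * o / (sigma * sigma));
    s += kern[o + r];
  }
  for (double& kv : kern) kv /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const long strides[3] = {1L, (long)nx, (long)nx * ny};
  const int lens[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    const long stride = strides[axis];
    const int len = lens[axis];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long idx = i + (long)nx * (j + (long)ny * k);
          int pos = (axis == 0) ? i : (axis == 1 ? j : k);
          double acc = 0, wsum = 0;
          for (int o = -r; o <= r; ++o) {
            int p = pos + o;
            if (p >= 0 && p < len) {
              acc += kern[o + r] * a[idx + (long)o * stride];
              wsum += kern[o + r];
            }
          }
          // zero-padded by default; renormalize for replicate-like borders
          b[idx] = renormalize ? acc / wsum : acc;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
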