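// Low-level voxel kernels: separable 1D convolution along any axis of
// a (z, y, x)-indexed 3D array stored column-major as dim = c(nz, ny,
// nx), and the 26-neighbourhood maximum used by the regional-maxima
// detector. Borders use symmetric (edge-included) reflection for the
// convolution and treat out-of-image voxels as -Inf for the maximum.

#include <Rcpp.h>
using namespace Rcpp;

static inline int reflect_index(int p, int n) {
  if (p < 0) p = -p - 1;
  if (p >= n) p = 2 * n - 1 - p;
  if (p < 0) p = 0;          // kernels wider than the axis: clamp
  if (p >= n) p = n - 1;
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector a, IntegerVector dims,
                            NumericVector k, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int nk = k.size();
  const int r = (nk - 1) / 2;
  NumericVector out(a.size());
  const double* pa = REAL(a);
  double* po = REAL(out);
  std::vector<double> kk(k.begin(), k.end());
  int n, stride, n_outer, n_inner, outer_stride, inner_stride;
  if (axis == 1) {          // z: stride 1
    n = nz; stride = 1;
    n_inner = ny; inner_stride = nz;
    n_outer = nx; outer_stride = nz * ny;
  } else if (axis == 2) {   // y: stride nz
    n = ny; stride = nz;
    n_inner = nz; inner_stride = 1;
    n_outer = nx; outer_stride = nz * ny;
  } else {                  // x: stride nz*ny
    n = nx; stride = nz * ny;
    n_inner = nz; inner_stride = 1;
    n_outer = ny; outer_stride = nz;
  }
  std::vector<double> line(n + 2 * r);
  for (int o = 0; o < n_outer; ++o) {
    for (int i = 0; i < n_inner; ++i) {
      const R_xlen_t base = (R_xlen_t)o * outer_stride + (R_xlen_t)i * inner_stride;
      for (int p = -r; p < n + r; ++p) {
        line[p + r] = pa[base + (R_xlen_t)reflect_index(p, n) * stride];
      }
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        const double* lj = &line[j];
        for (int t = 0; t < nk; ++t) acc += kk[t] * lj[t];
        po[base + (R_xlen_t)j * stride] = acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_neighborhood_max(NumericVector a, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const bool three_d = nz > 1;
  NumericVector out(a.size());
  const double* pa = REAL(a);
  double* po = REAL(out);
  const int zlo = three_d ? -1 : 0, zhi = three_d ? 1 : 0;
  for (int x = 0; x < nx; ++x) {
    const int x0 = std::max(0, x - 1), x1 = std::min(nx - 1, x + 1);
    for (int y = 0; y < ny; ++y) {
      const int y0 = std::max(0, y - 1), y1 = std::min(ny - 1, y + 1);
      for (int z = 0; z < nz; ++z) {
        const int z0 = std::max(0, z + zlo), z1 = std::min(nz - 1, z + zhi);
        double m = R_NegInf;
        for (int xx = x0; xx <= x1; ++xx) {
          for (int yy = y0; yy <= y1; ++yy) {
            const double* col = pa + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            for (int zz = z0; zz <= z1; ++zz) {
              if (xx == x && yy == y && zz == z) continue;
              const double v = col[zz];
              if (v > m) m = v;
            }
          }
        }
        po[z + nz * (y + (R_xlen_t)ny * x)] = m;
      }
    }
  }
  return out;
}
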