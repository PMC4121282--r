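#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared Euclidean distance transform (lower envelope of parabolas)
// with physical sample spacing w: out[q] = min_p f[p] + w^2 (q - p)^2.
static void dt1d(const double* f, double* out, int n, double w2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    out[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance (in mm, anisotropic spacing) from every voxel
// to the nearest foreground (non-zero) voxel. Felzenszwalb-Huttenlocher
// separable transform, exact.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite sentinel instead of Inf: keeps the envelope intersection
  // formula NaN-free on rows with no foreground
  const double INF = 1e15;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = fg[i] ? 0.0 : INF;

  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  std::vector<double> res(buf.size());

  // axis x
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) buf[i] = d[base + i];
      dt1d(buf.data(), res.data(), nx, w2);
      for (int i = 0; i < nx; ++i) d[base + i] = res[i];
    }
  // axis y
  w2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; ++j) buf[j] = d[base + (R_xlen_t)nx * j];
      dt1d(buf.data(), res.data(), ny, w2);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)nx * j] = res[j];
    }
  // axis z
  w2 = spacing[2] * spacing[2];
  const R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) buf[k] = d[base + stride * k];
      dt1d(buf.data(), res.data(), nz, w2);
      for (int k = 0; k < nz; ++k) d[base + stride * k] = res[k];
    }
  return d;
}
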