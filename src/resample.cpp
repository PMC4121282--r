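#include <Rcpp.h>
using namespace Rcpp;

// Pull-back resampling of a 3D scalar grid.
//
// For every voxel (i,j,k) of the output grid (0-based indices), the source
// voxel coordinate is C * [i,j,k,1]^T and the source array is sampled there
// with trilinear (mode = 0) or nearest-neighbour (mode = 1) interpolation.
// Samples falling outside the source grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector srcdim,
                           NumericMatrix C, IntegerVector outdim,
                           int mode, double fill = 0.0) {
  const int sx = srcdim[0], sy = srcdim[1], sz = srcdim[2];
  const int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);

  const double c00 = C(0,0), c01 = C(0,1), c02 = C(0,2), c03 = C(0,3);
  const double c10 = C(1,0), c11 = C(1,1), c12 = C(1,2), c13 = C(1,3);
  const double c20 = C(2,0), c21 = C(2,1), c22 = C(2,2), c23 = C(2,3);

  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      // start of the row: x = 0
      double px = c01 * j + c02 * k + c03;
      double py = c11 * j + c12 * k + c13;
      double pz = c21 * j + c22 * k + c23;
      for (int i = 0; i < ox; ++i, ++idx, px += c00, py += c10, pz += c20) {
        if (mode == 1) {
          int xi = (int)std::lround(px);
          int yi = (int)std::lround(py);
          int zi = (int)std::lround(pz);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= sx || yi >= sy || zi >= sz) {
            out[idx] = fill;
          } else {
            out[idx] = src[(R_xlen_t)xi + (R_xlen_t)sx * (yi + (R_xlen_t)sy * zi)];
          }
        } else {
          if (px < 0.0 || py < 0.0 || pz < 0.0 ||
              px > sx - 1.0 || py > sy - 1.0 || pz > sz - 1.0) {
            out[idx] = fill;
            continue;
          }
          int x0 = (int)std::floor(px); if (x0 == sx - 1) x0--;
          int y0 = (int)std::floor(py); if (y0 == sy - 1) y0--;
          int z0 = (int)std::floor(pz); if (z0 == sz - 1) z0--;
          if (sx == 1) x0 = 0;
          if (sy == 1) y0 = 0;
          if (sz == 1) z0 = 0;
          double fx = px - x0, fy = py - y0, fz = pz - z0;
          int x1 = (sx == 1) ? x0 : x0 + 1;
          int y1 = (sy == 1) ? y0 : y0 + 1;
          int z1 = (sz == 1) ? z0 : z0 + 1;
          if (sx == 1) fx = 0.0;
          if (sy == 1) fy = 0.0;
          if (sz == 1) fz = 0.0;
          #define SRC(a,b,c) src[(R_xlen_t)(a) + (R_xlen_t)sx * ((b) + (R_xlen_t)sy * (c))]
          double v000 = SRC(x0,y0,z0), v100 = SRC(x1,y0,z0);
          double v010 = SRC(x0,y1,z0), v110 = SRC(x1,y1,z0);
          double v001 = SRC(x0,y0,z1), v101 = SRC(x1,y0,z1);
          double v011 = SRC(x0,y1,z1), v111 = SRC(x1,y1,z1);
          #undef SRC
          double v00 = v000 + fx * (v100 - v000);
          double v10 = v010 + fx * (v110 - v010);
          double v01 = v001 + fx * (v101 - v001);
          double v11 = v011 + fx * (v111 - v011);
          double v0 = v00 + fy * (v10 - v00);
          double v1 = v01 + fy * (v11 - v01);
          out[idx] = v0 + fz * (v1 - v0);
        }
      }
    }
  }
  return out;
}
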