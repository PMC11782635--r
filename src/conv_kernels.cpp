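// im2col / col2im kernels for the 3x3 same-padding convolutions of the
// surrogate classifier. Arrays are column-major (N, H, W, C); the patch
// matrix is (N*H*W, 9*C) with column blocks ordered k = 3*dx + dy (dy
// fastest), matching the R-level weight layout.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int N, int H, int W, int Ci) {
  NumericMatrix cols(N * H * W, 9 * Ci);
  const double* xp = x.begin();
  double* out = cols.begin();
  const R_xlen_t rows = (R_xlen_t)N * H * W;
  for (int ci = 0; ci < Ci; ++ci) {
    const double* plane = xp + (R_xlen_t)ci * N * H * W;
    for (int k = 0; k < 9; ++k) {
      int dx = k / 3, dy = k % 3;
      double* col = out + ((R_xlen_t)k * Ci + ci) * rows;
      for (int w = 0; w < W; ++w) {
        int xx = w + dx - 1;
        for (int h = 0; h < H; ++h) {
          int yy = h + dy - 1;
          double* dst = col + ((R_xlen_t)w * H + h) * N;
          if (xx < 0 || xx >= W || yy < 0 || yy >= H) {
            for (int n = 0; n < N; ++n) dst[n] = 0.0;
          } else {
            const double* src = plane + ((R_xlen_t)xx * H + yy) * N;
            for (int n = 0; n < N; ++n) dst[n] = src[n];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcols, int N, int H, int W, int Ci) {
  NumericVector dx_(( R_xlen_t)N * H * W * Ci);
  double* acc = dx_.begin();
  const double* dc = dcols.begin();
  const R_xlen_t rows = (R_xlen_t)N * H * W;
  for (int ci = 0; ci < Ci; ++ci) {
    double* plane = acc + (R_xlen_t)ci * N * H * W;
    for (int k = 0; k < 9; ++k) {
      int dxo = k / 3, dyo = k % 3;
      const double* col = dc + ((R_xlen_t)k * Ci + ci) * rows;
      for (int w = 0; w < W; ++w) {
        int xx = w + dxo - 1;
        if (xx < 0 || xx >= W) continue;
        for (int h = 0; h < H; ++h) {
          int yy = h + dyo - 1;
          if (yy < 0 || yy >= H) continue;
          double* dst = plane + ((R_xlen_t)xx * H + yy) * N;
          const double* src = col + ((R_xlen_t)w * H + h) * N;
          for (int n = 0; n < N; ++n) dst[n] += src[n];
        }
      }
    }
  }
  dx_.attr("dim") = IntegerVector::create(N, H, W, Ci);
  return dx_;
}
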