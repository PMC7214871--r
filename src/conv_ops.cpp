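#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Unroll a (B, H, W, C) activation array into the im2col matrix
// (B*H*W, k*k*C) for a stride-1, zero-padded k x k convolution.
// Column order is offset-major, channel-minor: column (o*C + c), where
// offset o enumerates (dy, dx) with dy varying fastest (dy, dx in -r..r).
// Rows are (b, i, j) in column-major order, matching R's array layout.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector X, IntegerVector dims, int k) {
  const int B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int r = (k - 1) / 2;
  const R_xlen_t nrow = (R_xlen_t)B * H * W;
  NumericMatrix M(nrow, (R_xlen_t)k * k * C);
  const double *xp = REAL(X);
  double *mp = REAL(M);
  const R_xlen_t planeBH = (R_xlen_t)B * H;
  const R_xlen_t planeBHW = planeBH * W;
  for (int o = 0; o < k * k; ++o) {
    const int dy = (o % k) - r;
    const int dx = (o / k) - r;
    for (int c = 0; c < C; ++c) {
      double *col = mp + ((R_xlen_t)o * C + c) * nrow;
      const double *src = xp + (R_xlen_t)c * planeBHW;
      for (int j = 0; j < W; ++j) {
        const int sx = j + dx;
        if (sx < 0 || sx >= W) continue;
        for (int i = 0; i < H; ++i) {
          const int sy = i + dy;
          if (sy < 0 || sy >= H) continue;
          std::memcpy(col + (R_xlen_t)i * B + (R_xlen_t)j * planeBH,
                      src + (R_xlen_t)sy * B + (R_xlen_t)sx * planeBH,
                      B * sizeof(double));
        }
      }
    }
  }
  return M;
}
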