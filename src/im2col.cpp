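#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Unfold a (N, H, W, C) column-major array into the (N*H*W, k*k*C) patch
// matrix of a same-padding, stride-1, dilated k x k convolution. Column
// order matches the column-major flattening of a (k, k, C, C_out) kernel,
// so the convolution itself is a single GEMM on the result.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, IntegerVector dims, int k,
                         int dilation) {
  const int N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int p = dilation * (k - 1) / 2;
  const R_xlen_t plane = (R_xlen_t)N * H * W;
  NumericMatrix out((R_xlen_t)N * H * W, (R_xlen_t)k * k * C);
  const double *xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int oj = 0; oj < k; ++oj) {
      for (int oi = 0; oi < k; ++oi) {
        const int col = oi + k * oj + k * k * c;
        double *dst = &out(0, col);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dilation * oj - p;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dilation * oi - p;
            const R_xlen_t di = (R_xlen_t)N * (h + (R_xlen_t)H * w);
            if (sw < 0 || sw >= W || sh < 0 || sh >= H) {
              std::memset(dst + di, 0, sizeof(double) * N);
            } else {
              const double *src =
                  xp + (R_xlen_t)N * (sh + (R_xlen_t)H * sw) + plane * c;
              std::memcpy(dst + di, src, sizeof(double) * N);
            }
          }
        }
      }
    }
  }
  return out;
}
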