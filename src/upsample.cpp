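#include <Rcpp.h>
using namespace Rcpp;

// Gradient of nearest-neighbor upsampling: sum each output-plane gradient
// cell into its source cell. ridx/cidx are the 1-based source row/col of
// each output row/col; arrays are column-major (N, H, W, C).
// [[Rcpp::export]]
NumericVector upsample_backward_cpp(NumericVector dout, IntegerVector odims,
                                    IntegerVector ridx, IntegerVector cidx,
                                    IntegerVector idims) {
  const int N = odims[0], Ho = odims[1], Wo = odims[2], C = odims[3];
  const int Hi = idims[1], Wi = idims[2];
  NumericVector dx((R_xlen_t)N * Hi * Wi * C);
  const double *dp = dout.begin();
  double *xp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const R_xlen_t ooff = (R_xlen_t)N * Ho * Wo * c;
    const R_xlen_t ioff = (R_xlen_t)N * Hi * Wi * c;
    for (int w = 0; w < Wo; ++w) {
      const int sw = cidx[w] - 1;
      for (int h = 0; h < Ho; ++h) {
        const int sh = ridx[h] - 1;
        const double *src = dp + ooff + (R_xlen_t)N * (h + (R_xlen_t)Ho * w);
        double *dst = xp + ioff + (R_xlen_t)N * (sh + (R_xlen_t)Hi * sw);
        for (int n = 0; n < N; ++n) dst[n] += src[n];
      }
    }
  }
  return dx;
}
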