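#include <Rcpp.h>
using namespace Rcpp;

// Non-overlapping w x w max pooling with stride w on a column-major
// (N, H, W, C) array; floor rule on the output plane. Returns the pooled
// values and the 1-based flat input index of each window's first maximum.
// [[Rcpp::export]]
List maxpool_cpp(NumericVector x, IntegerVector dims, int w) {
  const int N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Ho = H / w, Wo = W / w;
  NumericVector out((R_xlen_t)N * Ho * Wo * C);
  NumericVector argflat((R_xlen_t)N * Ho * Wo * C);
  const double *xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const R_xlen_t xoff = (R_xlen_t)N * H * W * c;
    const R_xlen_t ooff = (R_xlen_t)N * Ho * Wo * c;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t obase = ooff + (R_xlen_t)N * (ho + (R_xlen_t)Ho * wo);
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          R_xlen_t besti = 0;
          for (int oj = 0; oj < w; ++oj) {
            for (int oi = 0; oi < w; ++oi) {
              const int h = ho * w + oi, ww = wo * w + oj;
              const R_xlen_t xi =
                  xoff + n + (R_xlen_t)N * (h + (R_xlen_t)H * ww);
              if (xp[xi] > best) {
                best = xp[xi];
                besti = xi;
              }
            }
          }
          out[obase + n] = best;
          argflat[obase + n] = (double)(besti + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argflat"] = argflat);
}
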