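#include <Rcpp.h>
using namespace Rcpp;

// im2col for a 3x3 'same' zero-padded correlation on a tensor laid out
// (h, w, B, C). Output: (h*w*B) x (9*C), columns grouped offset-major
// (di fastest, then dj) with channels fastest inside each offset block,
// matching the row layout of the conv weight matrices.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector X, int h, int w, int B, int C) {
  const int rows = h * w * B;
  NumericMatrix out(no_init(rows, 9 * C));
  const double *x = X.begin();
  const R_xlen_t planeB = (R_xlen_t)h * w;       // one image
  const R_xlen_t planeC = planeB * B;            // one channel block
  for (int t = 0; t < 9; ++t) {
    const int di = t % 3 - 1;                    // row offset -1..1
    const int dj = t / 3 - 1;                    // col offset -1..1
    for (int c = 0; c < C; ++c) {
      double *col = &out(0, t * C + c);
      const double *xc = x + planeC * c;
      R_xlen_t r = 0;
      for (int b = 0; b < B; ++b) {
        const double *xb = xc + planeB * b;
        for (int j = 0; j < w; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= w) {
            for (int i = 0; i < h; ++i) col[r++] = 0.0;
            continue;
          }
          const double *xcol = xb + (R_xlen_t)js * h;
          int i = 0;
          if (di < 0) col[r++] = 0.0, i = 1;
          const int imax = (di > 0) ? h - 1 : h;
          for (; i < imax; ++i) col[r++] = xcol[i + di];
          if (di > 0) col[r++] = 0.0;
        }
      }
    }
  }
  return out;
}
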