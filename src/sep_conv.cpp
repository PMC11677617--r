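#include <Rcpp.h>
using namespace Rcpp;

// Separable 2-D convolution with an odd symmetric kernel and replicate-edge
// padding; used for Gaussian smoothing ahead of global thresholding.
// [[Rcpp::export(name = ".sepConvolve2D")]]
NumericMatrix sepConvolve2D(NumericMatrix m, NumericVector k) {
  const int nr = m.nrow(), nc = m.ncol();
  const int kl = k.size();
  const int r = kl / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass (along rows within each column)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        acc += m(ii, j) * k[t + r];
      }
      tmp(i, j) = acc;
    }
  }
  // horizontal pass (along columns within each row)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        acc += tmp(i, jj) * k[t + r];
      }
      out(i, j) = acc;
    }
  }
  return out;
}
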