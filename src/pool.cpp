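#include <Rcpp.h>
using namespace Rcpp;

// Strided max pool over positions for a batch conv output Z of shape
// (n*P) x F, rows ordered batch-fastest (row = b + n*p). Positions are
// split into nbins = floor(P / pool_w) consecutive bins of pool_w rows
// (global pooling when pool_w >= P; a trailing remainder shorter than
// pool_w is dropped). Output columns are bin-major: col = k*F + f.
// Returns the raw per-(example, bin, filter) maximum and its 0-based
// absolute position index; bias and ReLU commute with the max and are
// applied afterwards by the caller.
// [[Rcpp::export]]
List pool_max_raw(NumericMatrix Z, int n, int P, int pool_w) {
  const int F = Z.ncol();
  if (pool_w > P) pool_w = P;
  const int nbins = P / pool_w;
  NumericMatrix pooled(n, F * nbins);
  IntegerMatrix idx(n, F * nbins);
  for (int f = 0; f < F; ++f) {
    const double* col = &Z(0, f);
    for (int k = 0; k < nbins; ++k) {
      const int out_c = k * F + f;
      const int p0 = k * pool_w;
      const double* row0 = col + (size_t)n * p0;
      for (int b = 0; b < n; ++b) {
        pooled(b, out_c) = row0[b];
        idx(b, out_c) = p0;
      }
      for (int p = p0 + 1; p < p0 + pool_w; ++p) {
        const double* row = col + (size_t)n * p;
        for (int b = 0; b < n; ++b) {
          if (row[b] > pooled(b, out_c)) {
            pooled(b, out_c) = row[b];
            idx(b, out_c) = p;
          }
        }
      }
    }
  }
  return List::create(_["pooled"] = pooled, _["idx"] = idx,
                      _["nbins"] = nbins);
}

// Gradient of the filter weights through the max pool: only the argmax row
// of each (example, bin, filter) carries gradient, so
// dW(j, f) = sum_{b,k} M(b + n*idx(b, k*F+f), j) * d(b, k*F+f).
// M is the im2col matrix ((n*P) x J), d the post-activation pooled
// gradient (n x F*nbins).
// [[Rcpp::export]]
NumericMatrix pool_conv_grad(NumericMatrix M, NumericMatrix d,
                             IntegerMatrix idx, int n, int F) {
  const int J = M.ncol(), C = d.ncol();
  NumericMatrix dW(J, F);
  for (int c = 0; c < C; ++c) {
    const int f = c % F;
    for (int b = 0; b < n; ++b) {
      const double g = d(b, c);
      if (g == 0.0) continue;
      const size_t row = (size_t)b + (size_t)n * idx(b, c);
      for (int j = 0; j < J; ++j) dW(j, f) += M(row, j) * g;
    }
  }
  return dW;
}
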