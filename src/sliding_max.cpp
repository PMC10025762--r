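#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Sliding-window maximum over each column of x, window of `width` rows.
// Monotonic-deque algorithm, O(n) per column. Used by the genome scanner:
// global max pooling of a stride-1 window scan is a sliding max over one
// full-contig convolution track.
// [[Rcpp::export]]
NumericMatrix sliding_col_max(NumericMatrix x, int width) {
  const int n = x.nrow(), k = x.ncol();
  if (width < 1 || width > n) stop("sliding_col_max: bad width");
  const int m = n - width + 1;
  NumericMatrix out(m, k);
  for (int j = 0; j < k; ++j) {
    std::deque<int> dq;
    for (int i = 0; i < n; ++i) {
      while (!dq.empty() && x(dq.back(), j) <= x(i, j)) dq.pop_back();
      dq.push_back(i);
      if (dq.front() <= i - width) dq.pop_front();
      if (i >= width - 1) out(i - width + 1, j) = x(dq.front(), j);
    }
  }
  return out;
}
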