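#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Moving percentile with a centred window truncated at the boundaries.
// The percentile within each window follows R's default quantile
// definition (type 7): linear interpolation of order statistics at
// h = (m - 1) * p, so results agree exactly with a per-window
// stats::quantile() oracle.
// [[Rcpp::export(name = ".moving_percentile_cpp")]]
NumericVector moving_percentile_cpp(NumericVector x, int width, double p) {
  const int n = x.size();
  if (width < 2) stop("window must cover at least 2 samples");
  const int left = (width - 1) / 2;
  const int right = width - 1 - left;
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(width);
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - left);
    const int hi = std::min(n - 1, i + right);
    const int m = hi - lo + 1;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    const double h = (m - 1) * p;
    const int j = static_cast<int>(h);
    const double g = h - j;
    std::nth_element(buf.begin(), buf.begin() + j, buf.end());
    const double qj = buf[j];
    double q = qj;
    if (g > 0.0 && j + 1 < m) {
      std::nth_element(buf.begin() + j + 1, buf.begin() + j + 1, buf.end());
      q = qj + g * (buf[j + 1] - qj);
    }
    out[i] = q;
  }
  return out;
}
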