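#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// linear-interpolation percentile (R quantile type 7) of a sorted vector
static double interp_percentile(const std::vector<double>& s, double p) {
  const int m = (int)s.size();
  if (m == 1) return s[0];
  double h = (m - 1) * p / 100.0;
  int lo = (int)std::floor(h);
  if (lo >= m - 1) return s[m - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// Rolling percentile over a centered window of `window` samples, the
// window clamped (shrinking) at the trace edges. The centered window for
// sample t (0-based) is [t - floor((w-1)/2), t + ceil((w-1)/2)].
// A sorted sliding window is maintained with binary insert/erase.
// [[Rcpp::export(name = ".roll_percentile_cpp")]]
NumericVector roll_percentile_cpp(NumericVector x, int window, double p) {
  const int n = x.size();
  NumericVector out(n);
  const int back = (window - 1) / 2;
  const int fwd = window - 1 - back;
  std::vector<double> s;
  s.reserve(std::min(window, n) + 1);
  int lo = 0, hi = -1;  // current inclusive index range held in s
  for (int t = 0; t < n; ++t) {
    const int wlo = std::max(0, t - back);
    const int whi = std::min(n - 1, t + fwd);
    while (hi < whi) {
      ++hi;
      s.insert(std::lower_bound(s.begin(), s.end(), x[hi]), x[hi]);
    }
    while (lo < wlo) {
      s.erase(std::lower_bound(s.begin(), s.end(), x[lo]));
      ++lo;
    }
    out[t] = interp_percentile(s, p);
  }
  return out;
}
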