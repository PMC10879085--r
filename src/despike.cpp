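#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Running-median / running-MAD despiking of one column. Edge windows shrink
// symmetrically; a point is replaced by its window median when it deviates
// from it by more than thresh * 1.4826 * MAD (and deviates at all).

static double med_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// [[Rcpp::export]]
NumericMatrix cpp_despike(const NumericMatrix& X, const int window,
                          const double thresh) {
  const int T = X.nrow(), C = X.ncol();
  const int hmax = (window - 1) / 2;
  NumericMatrix out(clone(X));
  std::vector<double> seg, dev;
  for (int j = 0; j < C; ++j) {
    for (int t = 0; t < T; ++t) {
      const int h = std::min(std::min(t, T - 1 - t), hmax);
      seg.assign(&X(t - h, j), &X(t - h, j) + 2 * h + 1);
      std::vector<double> tmp(seg);
      const double med = med_inplace(tmp);
      dev.resize(seg.size());
      for (size_t u = 0; u < seg.size(); ++u) dev[u] = std::abs(seg[u] - med);
      const double mad = med_inplace(dev);
      const double d = std::abs(X(t, j) - med);
      if (d > thresh * 1.4826 * mad && d > 0) out(t, j) = med;
    }
  }
  return out;
}
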