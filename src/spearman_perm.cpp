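#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Exact two-sided permutation p-value for the Spearman correlation of two
// small paired samples (ranks supplied). Enumerates all n! orderings of ry.

// [[Rcpp::export]]
double cpp_spearman_perm_p(const NumericVector& rx, const NumericVector& ry) {
  const int n = rx.size();
  const double mx = mean(rx), my = mean(ry);
  double sxx = 0.0, syy = 0.0;
  for (int i = 0; i < n; ++i) {
    sxx += (rx[i] - mx) * (rx[i] - mx);
    syy += (ry[i] - my) * (ry[i] - my);
  }
  const double denom = std::sqrt(sxx * syy);
  double sxy = 0.0;
  for (int i = 0; i < n; ++i) sxy += (rx[i] - mx) * (ry[i] - my);
  const double obs = std::abs(sxy / denom);

  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  long long count = 0, total = 0;
  const double eps = 1e-12;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += (rx[i] - mx) * (ry[idx[i]] - my);
    if (std::abs(s / denom) >= obs - eps) ++count;
    ++total;
  } while (std::next_permutation(idx.begin(), idx.end()));
  return static_cast<double>(count) / static_cast<double>(total);
}
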