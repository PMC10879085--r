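#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// City-block (L1) k-means core. Centroid updates are element-wise medians,
// which minimise the within-cluster L1 distance exactly. The caller supplies
// the initial centroids (k-means++ seeding lives in R so all randomness flows
// through R's RNG); the Lloyd iterations here are fully deterministic,
// including the empty-cluster rule (re-seed at the point farthest from its
// current centroid, first index on ties).

static double median_of(std::vector<double>& v) {
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
NumericVector cpp_l1_dist_to_point(const NumericMatrix& X, const NumericVector& v) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector out(n);
  for (int j = 0; j < p; ++j) {
    const double vj = v[j];
    for (int i = 0; i < n; ++i) out[i] += std::abs(X(i, j) - vj);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_l1_assign(const NumericMatrix& X, const NumericMatrix& centroids) {
  const int n = X.nrow(), p = X.ncol(), k = centroids.nrow();
  IntegerVector lab(n);
  NumericVector best(n, R_PosInf);
  std::vector<double> d(n);
  for (int c = 0; c < k; ++c) {
    std::fill(d.begin(), d.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      const double cj = centroids(c, j);
      for (int i = 0; i < n; ++i) d[i] += std::abs(X(i, j) - cj);
    }
    for (int i = 0; i < n; ++i) {
      if (d[i] < best[i]) { best[i] = d[i]; lab[i] = c + 1; }
    }
  }
  return List::create(_["labels"] = lab, _["dist"] = best);
}

// [[Rcpp::export]]
List cpp_kmeans_l1(const NumericMatrix& X, NumericMatrix centroids,
                   const int max_iter, const int tol_changes = 0) {
  const int n = X.nrow(), p = X.ncol(), k = centroids.nrow();
  IntegerVector lab(n);
  NumericVector best(n);
  int iter = 0;
  bool changed = true;
  std::vector<double> d(n), col;
  while (changed && iter < max_iter) {
    ++iter;
    // assignment step
    std::fill(best.begin(), best.end(), R_PosInf);
    IntegerVector newlab(n);
    for (int c = 0; c < k; ++c) {
      std::fill(d.begin(), d.end(), 0.0);
      for (int j = 0; j < p; ++j) {
        const double cj = centroids(c, j);
        for (int i = 0; i < n; ++i) d[i] += std::abs(X(i, j) - cj);
      }
      for (int i = 0; i < n; ++i) {
        if (d[i] < best[i]) { best[i] = d[i]; newlab[i] = c + 1; }
      }
    }
    // empty-cluster repair: re-seed at the farthest point from its centroid
    std::vector<int> counts(k, 0);
    for (int i = 0; i < n; ++i) counts[newlab[i] - 1]++;
    for (int c = 0; c < k; ++c) {
      if (counts[c] == 0) {
        int far = 0; double fd = -1.0;
        for (int i = 0; i < n; ++i)
          if (best[i] > fd && counts[newlab[i] - 1] > 1) { fd = best[i]; far = i; }
        counts[newlab[far] - 1]--;
        newlab[far] = c + 1;
        counts[c] = 1;
        for (int j = 0; j < p; ++j) centroids(c, j) = X(far, j);
        best[far] = 0.0;
      }
    }
    int n_changed = 0;
    for (int i = 0; i < n; ++i) if (newlab[i] != lab[i]) ++n_changed;
    changed = n_changed > tol_changes;
    lab = newlab;
    if (!changed) break;
    // update step: element-wise medians
    for (int c = 0; c < k; ++c) {
      for (int j = 0; j < p; ++j) {
        col.clear();
        for (int i = 0; i < n; ++i)
          if (lab[i] == c + 1) col.push_back(X(i, j));
        if (!col.empty()) centroids(c, j) = median_of(col);
      }
    }
  }
  // final within-cluster distance at the returned labels/centroids
  double tot = 0.0;
  std::fill(best.begin(), best.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    const int c = lab[i] - 1;
    double di = 0.0;
    for (int j = 0; j < p; ++j) di += std::abs(X(i, j) - centroids(c, j));
    best[i] = di;
    tot += di;
  }
  return List::create(_["labels"] = lab, _["centroids"] = centroids,
                      _["tot_within"] = tot, _["point_dist"] = best,
                      _["iterations"] = iter);
}
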