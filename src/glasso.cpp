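#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Graphical lasso by block coordinate descent (Friedman-style): cycle over
// columns of the working covariance W, solving each column's lasso problem
//   min_b  0.5 b' W11 b - s12' b + lambda ||b||_1
// by coordinate descent, then W12 <- W11 b. On convergence the precision
// matrix follows from theta22 = 1/(w22 - w12'b), theta12 = -b * theta22.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
List cpp_glasso(const NumericMatrix& S, const double lambda,
                const int max_iter = 200, const double tol = 1e-5,
                const int inner_max = 200, const double inner_tol = 1e-7) {
  const int p = S.nrow();
  NumericMatrix W(clone(S));
  for (int j = 0; j < p; ++j) W(j, j) += lambda;
  NumericMatrix B(p, p);  // column j holds b for block j (entry j unused)

  double offsum0 = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) if (i != j) offsum0 += std::abs(S(i, j));
  const double thr = tol * std::max(offsum0 / (p * (p - 1.0)), 1e-12);

  int it; bool converged = false;
  for (it = 0; it < max_iter && !converged; ++it) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      // coordinate descent on b (indices != j)
      for (int in = 0; in < inner_max; ++in) {
        double del = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double g = S(k, j);
          for (int m = 0; m < p; ++m) {
            if (m == j || m == k) continue;
            g -= W(k, m) * B(m, j);
          }
          const double bnew = soft(g, lambda) / W(k, k);
          del = std::max(del, std::abs(bnew - B(k, j)));
          B(k, j) = bnew;
        }
        if (del < inner_tol) break;
      }
      // W12 <- W11 b
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int m = 0; m < p; ++m) {
          if (m == j) continue;
          w += W(k, m) * B(m, j);
        }
        max_change = std::max(max_change, std::abs(W(k, j) - w));
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (max_change < thr) converged = true;
  }

  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double q = W(j, j);
    for (int k = 0; k < p; ++k) if (k != j) q -= W(k, j) * B(k, j);
    const double t22 = 1.0 / q;
    Theta(j, j) = t22;
    for (int k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * t22;
  }
  // symmetrise (numerical asymmetry only)
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      const double a = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = a; Theta(j, i) = a;
    }
  return List::create(_["w"] = W, _["theta"] = Theta,
                      _["iterations"] = it, _["converged"] = converged);
}
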