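#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive all-subsets OLS scan over precomputed normal-equation
// cross-products. Column 0 of G is the intercept; candidate predictors are
// columns 1..p. For every subset S of {1..p} with |S| <= max_k the system
// G[{0}+S, {0}+S] beta = g[{0}+S] is solved by Cholesky and scored with
// AIC = n*log(RSS/n) + 2*(|S|+1). Ties (within 1e-10) break toward fewer
// predictors, then lexicographically on the sorted index list.
//
// G    : (p+1)x(p+1) = t(Z) %*% Z with Z = [1, X]
// g    : (p+1)       = t(Z) %*% y
// yty  : sum(y^2)
// n    : number of observations
// max_k: largest admissible subset size (typically n - 2)
//
// Returns list(selected = 1-based candidate indices, aic, rss,
//              n_evaluated = number of admissible subsets scored).
// [[Rcpp::export]]
List exhaustive_aic_cpp(NumericMatrix G, NumericVector g, double yty,
                        int n, int max_k) {
  const int p = G.ncol() - 1;
  if (p < 1 || p > 25) stop("candidate count must be in 1..25");
  const uint64_t nmask = (uint64_t)1 << p;
  const int dim = p + 1;

  double A[26 * 26], L[26 * 26], b[26], z[26];
  int cols[26];

  double best_aic = R_PosInf, best_rss = NA_REAL;
  uint64_t best_mask = 0;
  int best_k = p + 1;
  long long n_eval = 0;

  for (uint64_t mask = 0; mask < nmask; ++mask) {
    int k = 0;
    cols[k++] = 0;
    for (int j = 0; j < p; ++j)
      if (mask & ((uint64_t)1 << j)) cols[k++] = j + 1;
    const int m = k;               // system size = predictors + intercept
    if (m - 1 > max_k) continue;

    // gather the subset system
    for (int i = 0; i < m; ++i) {
      b[i] = g[cols[i]];
      const double* Gc = &G[(size_t)cols[i] * dim];
      for (int j = 0; j <= i; ++j) A[i * m + j] = Gc[cols[j]];
    }

    // Cholesky A = L L^T (lower), skip singular subsets
    bool ok = true;
    for (int i = 0; i < m && ok; ++i) {
      double d = A[i * m + i];
      for (int q = 0; q < i; ++q) d -= L[i * m + q] * L[i * m + q];
      if (d <= 1e-12 * (std::abs(A[i * m + i]) + 1e-300)) { ok = false; break; }
      const double Lii = std::sqrt(d);
      L[i * m + i] = Lii;
      for (int r = i + 1; r < m; ++r) {
        double s = A[r * m + i];
        for (int q = 0; q < i; ++q) s -= L[r * m + q] * L[i * m + q];
        L[r * m + i] = s / Lii;
      }
    }
    if (!ok) continue;

    // forward/back substitution: beta = A^{-1} b
    for (int i = 0; i < m; ++i) {
      double s = b[i];
      for (int q = 0; q < i; ++q) s -= L[i * m + q] * z[q];
      z[i] = s / L[i * m + i];
    }
    // RSS = yty - b' A^{-1} b = yty - ||z||^2
    double fit = 0.0;
    for (int i = 0; i < m; ++i) fit += z[i] * z[i];
    double rss = yty - fit;
    if (rss < 1e-12) rss = 1e-12;  // guard exact interpolation
    const int kpred = m - 1;
    const double aic = n * std::log(rss / n) + 2.0 * (kpred + 1);
    ++n_eval;

    bool take = false;
    if (aic < best_aic - 1e-10) {
      take = true;
    } else if (aic <= best_aic + 1e-10) {
      if (kpred < best_k) {
        take = true;
      } else if (kpred == best_k) {
        // lexicographic on sorted index lists: lowest differing bit decides
        uint64_t diff = mask ^ best_mask;
        if (diff) {
          uint64_t low = diff & (~diff + 1);
          if (mask & low) take = true;  // mask has the smaller leading index
        }
      }
    }
    if (take) {
      best_aic = aic; best_mask = mask; best_k = kpred; best_rss = rss;
    }
    if ((mask & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector sel(best_k);
  for (int j = 0, q = 0; j < p; ++j)
    if (best_mask & ((uint64_t)1 << j)) sel[q++] = j + 1;
  return List::create(_["selected"] = sel, _["aic"] = best_aic,
                      _["rss"] = best_rss, _["n_evaluated"] = (double)n_eval);
}
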