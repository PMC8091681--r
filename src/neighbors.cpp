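#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix pairwise_sq_dists_cpp(const NumericMatrix& X) {
  const int n = X.nrow(), d = X.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        const double diff = X(i, m) - X(j, m);
        s += diff * diff;
      }
      D(i, j) = s;
      D(j, i) = s;
    }
  }
  return D;
}

// Exact k nearest neighbours (Euclidean), self excluded.
// Ties at equal distance resolve to the lower index (std::pair ordering).
// [[Rcpp::export]]
List knn_exact_cpp(const NumericMatrix& X, const int k) {
  const int n = X.nrow(), d = X.ncol();
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector< std::pair<double, int> > cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        const double diff = X(i, m) - X(j, m);
        s += diff * diff;
      }
      cand[c++] = std::make_pair(s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = cand[j].second + 1;  // 1-based for R
      dist(i, j) = std::sqrt(cand[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
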