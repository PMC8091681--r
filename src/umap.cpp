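#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic xorshift32 RNG so SGD runs are bit-reproducible across
// platforms, independent of R's RNG state.
static inline uint32_t xorshift32(uint32_t& s) {
  s ^= s << 13;
  s ^= s >> 17;
  s ^= s << 5;
  return s;
}

static inline double clip4(const double v) {
  if (v > 4.0) return 4.0;
  if (v < -4.0) return -4.0;
  return v;
}

// Edge-sampling stochastic gradient descent on the fuzzy graph layout
// objective (umap-style forces). head/tail are 1-based endpoints of each
// undirected edge (listed once); both endpoints move on attraction, only the
// head on negative samples. epochs_per_sample controls how often each edge is
// updated: stronger edges are sampled more often.
// [[Rcpp::export]]
NumericMatrix umap_sgd_cpp(const NumericMatrix& Y0, const IntegerVector& head,
                           const IntegerVector& tail,
                           const NumericVector& epochs_per_sample,
                           const double a, const double b, const double gamma,
                           const double initial_alpha, const int n_epochs,
                           const double negative_sample_rate, const int seed) {
  const int n = Y0.nrow(), d = Y0.ncol();
  const int n_edges = head.size();
  NumericMatrix Y = clone(Y0);

  std::vector<double> eons(n_edges), epns(n_edges), eonns(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    eons[e] = epochs_per_sample[e];
    epns[e] = epochs_per_sample[e] / negative_sample_rate;
    eonns[e] = epns[e];
  }
  uint32_t state = (uint32_t)seed;
  if (state == 0) state = 0x9E3779B9u;
  for (int w = 0; w < 8; ++w) xorshift32(state);  // warm up

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    const double alpha =
        initial_alpha * (1.0 - (double)(epoch - 1) / (double)n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (eons[e] > epoch) continue;
      const int i = head[e] - 1, j = tail[e] - 1;
      double d2 = 0.0;
      for (int m = 0; m < d; ++m) {
        const double diff = Y(i, m) - Y(j, m);
        d2 += diff * diff;
      }
      if (d2 > 0.0) {
        const double pd2b = std::pow(d2, b);
        const double grad_coeff = (-2.0 * a * b * pd2b / d2) / (a * pd2b + 1.0);
        for (int m = 0; m < d; ++m) {
          const double g = clip4(grad_coeff * (Y(i, m) - Y(j, m)));
          Y(i, m) += alpha * g;
          Y(j, m) -= alpha * g;
        }
      }
      eons[e] += epochs_per_sample[e];

      const int n_neg = (int)((epoch - eonns[e]) / epns[e]);
      for (int s = 0; s < n_neg; ++s) {
        const int k = (int)(xorshift32(state) % (uint32_t)n);
        if (k == i) continue;
        double e2 = 0.0;
        for (int m = 0; m < d; ++m) {
          const double diff = Y(i, m) - Y(k, m);
          e2 += diff * diff;
        }
        if (e2 > 0.0) {
          const double pd2b = std::pow(e2, b);
          const double grad_coeff =
              2.0 * gamma * b / ((0.001 + e2) * (a * pd2b + 1.0));
          for (int m = 0; m < d; ++m) {
            Y(i, m) += alpha * clip4(grad_coeff * (Y(i, m) - Y(k, m)));
          }
        } else {
          for (int m = 0; m < d; ++m) Y(i, m) += alpha * 4.0;
        }
      }
      eonns[e] += n_neg * epns[e];
    }
  }
  return Y;
}

// Seeded sampler of unordered pairs (i < j) avoiding a banned edge set.
// banned_keys must be sorted ascending; keys are i * n + j with i < j,
// passed as doubles to allow n^2 beyond 2^31. Returns an m x 2 matrix of
// 1-based indices.
// [[Rcpp::export]]
IntegerMatrix sample_nonedge_pairs_cpp(const int n, const int m,
                                       const NumericVector& banned_keys,
                                       const int seed) {
  IntegerMatrix out(m, 2);
  uint32_t state = (uint32_t)seed;
  if (state == 0) state = 0x85EBCA6Bu;
  for (int w = 0; w < 8; ++w) xorshift32(state);
  const int nb = banned_keys.size();
  int got = 0;
  while (got < m) {
    int i = (int)(xorshift32(state) % (uint32_t)n);
    int j = (int)(xorshift32(state) % (uint32_t)n);
    if (i == j) continue;
    if (i > j) std::swap(i, j);
    const double key = (double)i * (double)n + (double)j;
    // binary search in banned list
    int lo = 0, hi = nb - 1;
    bool banned = false;
    while (lo <= hi) {
      const int mid = (lo + hi) / 2;
      if (banned_keys[mid] == key) { banned = true; break; }
      if (banned_keys[mid] < key) lo = mid + 1; else hi = mid - 1;
    }
    if (banned) continue;
    out(got, 0) = i + 1;
    out(got, 1) = j + 1;
    ++got;
  }
  return out;
}
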