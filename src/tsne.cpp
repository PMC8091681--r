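#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian conditionals p_{j|i} with per-row precision beta_i = 1/(2 sigma_i^2)
// found by bisection so that the row entropy H satisfies exp(H) = perplexity.
// D holds squared distances. Returns the row-stochastic matrix, the precisions
// and a convergence flag per row.
// [[Rcpp::export]]
List perplexity_search_cpp(const NumericMatrix& D, const double perplexity,
                           const double tol, const int max_iter) {
  const int n = D.nrow();
  NumericMatrix P(n, n);
  NumericVector beta(n);
  LogicalVector converged(n);
  const double log_perp = std::log(perplexity);
  std::vector<double> pr(n);

  for (int i = 0; i < n; ++i) {
    double b = 1.0;
    double bmin = R_NegInf, bmax = R_PosInf;
    double sumP = 0.0, H = 0.0;
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      sumP = 0.0;
      double sumDP = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) { pr[j] = 0.0; continue; }
        const double v = std::exp(-D(i, j) * b);
        pr[j] = v;
        sumP += v;
        sumDP += D(i, j) * v;
      }
      // H in nats: log(sumP) + b * E[D]
      H = std::log(sumP) + b * sumDP / sumP;
      const double Hdiff = H - log_perp;
      if (std::fabs(Hdiff) < tol) { ok = true; break; }
      if (Hdiff > 0) {  // entropy too high -> narrow the kernel
        bmin = b;
        b = std::isinf(bmax) ? b * 2.0 : (b + bmax) / 2.0;
      } else {
        bmax = b;
        b = std::isinf(bmin) ? b / 2.0 : (b + bmin) / 2.0;
      }
    }
    for (int j = 0; j < n; ++j) P(i, j) = (j == i) ? 0.0 : pr[j] / sumP;
    beta[i] = b;
    converged[i] = ok;
  }
  return List::create(_["P"] = P, _["beta"] = beta, _["converged"] = converged);
}

// Gradient of sum_{i != j} p_ij log(p_ij / q_ij) with Student-t q:
// dC/dy_i = 4 sum_j (p_ij - q_ij) (y_i - y_j) / (1 + |y_i - y_j|^2)
// [[Rcpp::export]]
NumericMatrix tsne_grad_cpp(const NumericMatrix& P, const NumericMatrix& Y) {
  const int n = Y.nrow(), d = Y.ncol();
  NumericMatrix W(n, n);
  double sumW = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        const double diff = Y(i, m) - Y(j, m);
        s += diff * diff;
      }
      const double w = 1.0 / (1.0 + s);
      W(i, j) = w;
      W(j, i) = w;
      sumW += 2.0 * w;
    }
  }
  NumericMatrix G(n, d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double mult = 4.0 * (P(i, j) - W(i, j) / sumW) * W(i, j);
      for (int m = 0; m < d; ++m) G(i, m) += mult * (Y(i, m) - Y(j, m));
    }
  }
  return G;
}

// Batch gradient descent with momentum and adaptive gains (van der Maaten
// schedule). Early exaggeration multiplies P for the first exagger_iters
// iterations. Fully deterministic given Y0.
// [[Rcpp::export]]
NumericMatrix tsne_inner_cpp(const NumericMatrix& P, const NumericMatrix& Y0,
                             const int iters, const double eta,
                             const double mom_start, const double mom_final,
                             const int mom_switch, const double exaggeration,
                             const int exagger_iters) {
  const int n = Y0.nrow(), d = Y0.ncol();
  NumericMatrix Y = clone(Y0);
  NumericMatrix uY(n, d), gains(n, d);
  std::fill(gains.begin(), gains.end(), 1.0);
  NumericMatrix W(n, n), G(n, d);

  for (int iter = 0; iter < iters; ++iter) {
    const double exag = (iter < exagger_iters) ? exaggeration : 1.0;
    // low-dimensional kernel
    double sumW = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double s = 0.0;
        for (int m = 0; m < d; ++m) {
          const double diff = Y(i, m) - Y(j, m);
          s += diff * diff;
        }
        const double w = 1.0 / (1.0 + s);
        W(i, j) = w;
        W(j, i) = w;
        sumW += 2.0 * w;
      }
    }
    // gradient; symmetric accumulation over i < j
    std::fill(G.begin(), G.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double mult = 4.0 * (exag * P(i, j) - W(i, j) / sumW) * W(i, j);
        for (int m = 0; m < d; ++m) {
          const double g = mult * (Y(i, m) - Y(j, m));
          G(i, m) += g;
          G(j, m) -= g;
        }
      }
    }
    const double momentum = (iter < mom_switch) ? mom_start : mom_final;
    for (int i = 0; i < n; ++i) {
      for (int m = 0; m < d; ++m) {
        const bool same_sign = (G(i, m) > 0.0) == (uY(i, m) > 0.0);
        double g = same_sign ? gains(i, m) * 0.8 : gains(i, m) + 0.2;
        if (g < 0.01) g = 0.01;
        gains(i, m) = g;
        uY(i, m) = momentum * uY(i, m) - eta * g * G(i, m);
        Y(i, m) += uY(i, m);
      }
    }
    // recenter
    for (int m = 0; m < d; ++m) {
      double mean = 0.0;
      for (int i = 0; i < n; ++i) mean += Y(i, m);
      mean /= n;
      for (int i = 0; i < n; ++i) Y(i, m) -= mean;
    }
  }
  return Y;
}
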