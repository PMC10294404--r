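#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// The bins x states log emission-likelihood matrix lb is computed in R as
// two BLAS matrix products (observations x log-emission parameters); the
// O(T K^2) recursions below are the only loops that need compiled code.

// Scaled forward-backward over one chunk given lb = log b_t(k).
// Returns the chunk log-likelihood, per-bin posteriors gamma (rows sum to
// 1), and the summed transition posteriors xi.
// [[Rcpp::export]]
List cpp_forward_backward(const NumericMatrix& lb, const NumericVector& init,
                          const NumericMatrix& trans) {
  const int T = lb.nrow(), K = init.size();
  NumericMatrix b(T, K);
  std::vector<double> lbmax(T);
  for (int t = 0; t < T; ++t) {
    double m = lb(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, lb(t, k));
    lbmax[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(lb(t, k) - m);
  }

  NumericMatrix alpha(T, K), beta(T, K);
  std::vector<double> c(T);
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = init[k] * b(0, k);
    s += alpha(0, k);
  }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      alpha(t, k) = a * b(t, k);
      s += alpha(t, k);
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + lbmax[t];

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double v = 0.0;
      for (int j = 0; j < K; ++j)
        v += trans(k, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, k) = v / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  NumericMatrix xi(K, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) gamma(t, k) = alpha(t, k) * beta(t, k);
  for (int t = 0; t < T - 1; ++t)
    for (int i = 0; i < K; ++i) {
      double ai = alpha(t, i);
      for (int j = 0; j < K; ++j)
        xi(i, j) += ai * trans(i, j) * b(t + 1, j) * beta(t + 1, j) / c[t + 1];
    }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xi"] = xi);
}

// Forward pass only: chunk log-likelihood.
// [[Rcpp::export]]
double cpp_loglik(const NumericMatrix& lb, const NumericVector& init,
                  const NumericMatrix& trans) {
  const int T = lb.nrow(), K = init.size();
  std::vector<double> prev(K), cur(K);
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) {
    double m = lb(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, lb(t, k));
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a;
      if (t == 0) a = init[k];
      else {
        a = 0.0;
        for (int j = 0; j < K; ++j) a += prev[j] * trans(j, k);
      }
      cur[k] = a * std::exp(lb(t, k) - m);
      s += cur[k];
    }
    loglik += std::log(s) + m;
    for (int k = 0; k < K; ++k) prev[k] = cur[k] / s;
  }
  return loglik;
}

// Viterbi decoding in log space; ties broken toward the lowest state index
// (strict > when updating keeps the first maximiser).
// [[Rcpp::export]]
IntegerVector cpp_viterbi(const NumericMatrix& lb, const NumericVector& init,
                          const NumericMatrix& trans) {
  const int T = lb.nrow(), K = init.size();
  NumericMatrix ltrans(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) ltrans(i, j) = std::log(trans(i, j));
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = std::log(init[k]) + lb(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + ltrans(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + ltrans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + lb(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > delta(T - 1, arg)) arg = k;
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}

// Sample a Markov chain path of length n from pre-drawn uniforms (keeps all
// randomness in R's RNG). cum_init: length K cumulative initial; cum_trans:
// K x K with cumulative rows.
// [[Rcpp::export]]
IntegerVector cpp_sample_markov(const NumericVector& cum_init,
                                const NumericMatrix& cum_trans,
                                const NumericVector& u) {
  const int n = u.size(), K = cum_init.size();
  IntegerVector path(n);
  int s = 0;
  while (s < K - 1 && u[0] > cum_init[s]) ++s;
  path[0] = s + 1;
  for (int t = 1; t < n; ++t) {
    int j = 0;
    while (j < K - 1 && u[t] > cum_trans(s, j)) ++j;
    s = j;
    path[t] = s + 1;
  }
  return path;
}
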