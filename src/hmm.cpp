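#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log N(x | mean, var)
static inline double ldnorm(double x, double mean, double var) {
  double d = x - mean;
  return -0.5 * (std::log(2.0 * M_PI * var) + d * d / var);
}

// Scaled forward-backward for a Gaussian-emission HMM on one sequence.
// Returns log-likelihood, posterior state probabilities gamma (T x K),
// summed transition posteriors xi_sum (K x K), and gamma at t=1.
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector obs, NumericVector means,
                          NumericVector vars, NumericMatrix trans,
                          NumericVector init) {
  const int T = obs.size(), K = means.size();
  NumericMatrix logb(T, K), alpha(T, K), beta(T, K), gamma(T, K);
  NumericMatrix xi_sum(K, K);
  NumericVector scale(T);

  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      logb(t, k) = ldnorm(obs[t], means[k], vars[k]);

  // emission probabilities are rescaled per-step; work with b_t(k)
  // relative to their row max to avoid underflow
  NumericMatrix b(T, K);
  NumericVector bmax(T);
  for (int t = 0; t < T; ++t) {
    double m = logb(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logb(t, k));
    bmax[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logb(t, k) - m);
  }

  double loglik = 0.0;
  for (int k = 0; k < K; ++k) alpha(0, k) = init[k] * b(0, k);
  double s0 = 0.0;
  for (int k = 0; k < K; ++k) s0 += alpha(0, k);
  if (s0 <= 0) s0 = DBL_MIN;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s0;
  scale[0] = s0;
  for (int t = 1; t < T; ++t) {
    double st = 0.0;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += alpha(t - 1, j) * trans(j, k);
      alpha(t, k) = acc * b(t, k);
      st += alpha(t, k);
    }
    if (st <= 0) st = DBL_MIN;
    for (int k = 0; k < K; ++k) alpha(t, k) /= st;
    scale[t] = st;
  }
  for (int t = 0; t < T; ++t) loglik += std::log(scale[t]) + bmax[t];

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j)
        acc += trans(k, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, k) = acc / scale[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      s += gamma(t, k);
    }
    if (s <= 0) s = DBL_MIN;
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  for (int t = 0; t < T - 1; ++t) {
    double s = 0.0;
    NumericMatrix xi(K, K);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        xi(j, k) = alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k);
        s += xi(j, k);
      }
    if (s <= 0) s = DBL_MIN;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) xi_sum(j, k) += xi(j, k) / s;
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum);
}

// Viterbi decoding; returns the 1-based maximum-probability state path.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector obs, NumericVector means,
                          NumericVector vars, NumericMatrix trans,
                          NumericVector init) {
  const int T = obs.size(), K = means.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix ltrans(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      ltrans(j, k) = trans(j, k) > 0 ? std::log(trans(j, k)) : -INFINITY;

  for (int k = 0; k < K; ++k)
    delta(0, k) = (init[k] > 0 ? std::log(init[k]) : -INFINITY) +
                  ldnorm(obs[0], means[k], vars[k]);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = -INFINITY;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + ltrans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + ldnorm(obs[t], means[k], vars[k]);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = -INFINITY;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
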