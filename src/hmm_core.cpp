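#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for one observation sequence.
// emis: T x K matrix of per-bin emission probabilities P(x_t | state k)
// A:    K x K row-stochastic transition matrix
// pi:   K initial distribution
// Returns log-likelihood, posterior matrix gamma (T x K, rows sum to 1),
// expected transition counts xi_sum (K x K) and gamma's first row.
// [[Rcpp::export]]
List fb_pass(NumericMatrix emis, NumericMatrix A, NumericVector pi) {
  const int T = emis.nrow(), K = emis.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  NumericVector cvec(T);

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * emis(0, k); s += alpha(0, k); }
  if (s <= 0.0) stop("zero forward mass at position 1");
  cvec[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= emis(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0.0) stop("zero forward mass (numerical underflow?)");
    cvec[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(i, j) * emis(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / cvec[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  for (int t = 0; t + 1 < T; ++t) {
    for (int i = 0; i < K; ++i) {
      const double ai = alpha(t, i);
      for (int j = 0; j < K; ++j) {
        xi(i, j) += ai * A(i, j) * emis(t + 1, j) * beta(t + 1, j) / cvec[t + 1];
      }
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(cvec[t]);

  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi_sum"] = xi);
}

// Log-space forward pass only (log-likelihood without posterior arrays).
// [[Rcpp::export]]
double forward_loglik(NumericMatrix emis, NumericMatrix A, NumericVector pi) {
  const int T = emis.nrow(), K = emis.ncol();
  std::vector<double> cur(K), nxt(K);
  double ll = 0.0, s = 0.0;
  for (int k = 0; k < K; ++k) { cur[k] = pi[k] * emis(0, k); s += cur[k]; }
  if (s <= 0.0) stop("zero forward mass at position 1");
  ll += std::log(s);
  for (int k = 0; k < K; ++k) cur[k] /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += cur[i] * A(i, j);
      nxt[j] = a * emis(t, j);
      s += nxt[j];
    }
    if (s <= 0.0) stop("zero forward mass (numerical underflow?)");
    ll += std::log(s);
    for (int j = 0; j < K; ++j) cur[j] = nxt[j] / s;
  }
  return ll;
}

// Viterbi decode in log space; returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector viterbi_path(NumericMatrix logemis, NumericMatrix logA, NumericVector logpi) {
  const int T = logemis.nrow(), K = logemis.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logemis(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logemis(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = psi(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}
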