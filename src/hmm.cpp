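#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a homogeneous HMM.
//
// logE: T x K matrix of log emission densities. A: K x K row-stochastic
// transition matrix. pi: length-K initial distribution. Emissions are
// exponentiated after subtracting the per-bin maximum, so adding any constant
// to a row of logE leaves the posteriors unchanged and the log-likelihood
// shifted by exactly that constant.
// [[Rcpp::export(name = ".fb_scaled")]]
List fb_scaled(NumericMatrix logE, NumericMatrix A, NumericVector pi) {
  const int T = logE.nrow(), K = logE.ncol();
  if (A.nrow() != K || A.ncol() != K || pi.size() != K)
    stop("dimension mismatch between emissions, transition matrix and initial distribution");

  NumericMatrix E(T, K);
  std::vector<double> m(T);
  for (int t = 0; t < T; ++t) {
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) mx = std::max(mx, logE(t, k));
    if (!R_FINITE(mx))
      stop("bin %d has no finite emission density under any state", t + 1);
    m[t] = mx;
    for (int k = 0; k < K; ++k) E(t, k) = std::exp(logE(t, k) - mx);
  }

  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  std::vector<double> c(T);
  double loglik = 0.0;

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * E(0, k); s += alpha(0, k); }
  if (s <= 0) stop("zero forward mass at bin 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = acc * E(t, k);
      s += alpha(t, k);
    }
    if (s <= 0) stop("zero forward mass at bin %d", t + 1);
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + m[t];

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) acc += A(j, k) * E(t + 1, k) * beta(t + 1, k);
      beta(t, j) = acc / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double z = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); z += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= z;
  }

  // expected transition counts xi_ij = sum_t P(G_{t-1}=i, G_t=j | data)
  NumericMatrix xi(K, K);
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < K; ++i) {
      const double ai = alpha(t - 1, i);
      if (ai == 0.0) continue;
      for (int j = 0; j < K; ++j) {
        xi(i, j) += ai * A(i, j) * E(t, j) * beta(t, j) / c[t];
      }
    }
  }

  return List::create(_["gamma"] = gamma, _["loglik"] = loglik, _["xi"] = xi);
}

// Viterbi decoding in log space. Ties are broken toward the lowest state
// index (strict improvement required to switch the argmax).
// [[Rcpp::export(name = ".viterbi_path")]]
IntegerVector viterbi_path(NumericMatrix logE, NumericMatrix A, NumericVector pi) {
  const int T = logE.nrow(), K = logE.ncol();
  if (A.nrow() != K || A.ncol() != K || pi.size() != K)
    stop("dimension mismatch between emissions, transition matrix and initial distribution");

  NumericMatrix logA(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) logA(i, j) = std::log(A(i, j));

  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = std::log(pi[k]) + logE(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double cand = delta(t - 1, j) + logA(j, k);
        if (cand > best) { best = cand; arg = j; }
      }
      delta(t, k) = best + logE(t, k);
      psi(t, k) = arg;
    }
  }

  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based states
  return path;
}
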