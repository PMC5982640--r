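#include <Rcpp.h>
using namespace Rcpp;

// Log-space HMM recursions. logB is T x S: per-frame per-state emission
// log-density. All recursions use streaming log-sum-exp, so sequences of
// 1e5+ frames do not underflow.

static inline double logsumexp_row(const NumericVector& x) {
  double m = *std::max_element(x.begin(), x.end());
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (double v : x) s += std::exp(v - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
double hmm_forward_cpp(NumericVector logpi, NumericMatrix logT, NumericMatrix logB) {
  const int T = logB.nrow(), S = logB.ncol();
  NumericVector alpha(S), tmp(S), work(S);
  for (int s = 0; s < S; ++s) alpha[s] = logpi[s] + logB(0, s);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < S; ++k) {
      for (int j = 0; j < S; ++j) work[j] = alpha[j] + logT(j, k);
      tmp[k] = logsumexp_row(work) + logB(t, k);
    }
    alpha = clone(tmp);
  }
  return logsumexp_row(alpha);
}

// Forward-backward sufficient statistics for one sequence.
// Returns loglik, gamma (T x S) and summed xi (S x S).
// [[Rcpp::export]]
List hmm_fb_cpp(NumericVector logpi, NumericMatrix logT, NumericMatrix logB) {
  const int T = logB.nrow(), S = logB.ncol();
  NumericMatrix la(T, S), lb(T, S);
  NumericVector work(S);
  for (int s = 0; s < S; ++s) la(0, s) = logpi[s] + logB(0, s);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < S; ++k) {
      for (int j = 0; j < S; ++j) work[j] = la(t - 1, j) + logT(j, k);
      la(t, k) = logsumexp_row(work) + logB(t, k);
    }
  for (int s = 0; s < S; ++s) lb(T - 1, s) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int j = 0; j < S; ++j) {
      for (int k = 0; k < S; ++k) work[k] = logT(j, k) + logB(t + 1, k) + lb(t + 1, k);
      lb(t, j) = logsumexp_row(work);
    }
  NumericVector last(S);
  for (int s = 0; s < S; ++s) last[s] = la(T - 1, s);
  const double ll = logsumexp_row(last);
  NumericMatrix gamma(T, S), xisum(S, S);
  for (int t = 0; t < T; ++t)
    for (int s = 0; s < S; ++s) gamma(t, s) = std::exp(la(t, s) + lb(t, s) - ll);
  for (int t = 0; t < T - 1; ++t)
    for (int j = 0; j < S; ++j)
      for (int k = 0; k < S; ++k)
        xisum(j, k) += std::exp(la(t, j) + logT(j, k) + logB(t + 1, k) + lb(t + 1, k) - ll);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xisum"] = xisum);
}

// Viterbi decoding; ties broken towards the lower state index (strict >).
// Returns 0-based states and the log joint probability of the best path.
// [[Rcpp::export]]
List hmm_viterbi_cpp(NumericVector logpi, NumericMatrix logT, NumericMatrix logB) {
  const int T = logB.nrow(), S = logB.ncol();
  NumericMatrix delta(T, S);
  IntegerMatrix psi(T, S);
  for (int s = 0; s < S; ++s) delta(0, s) = logpi[s] + logB(0, s);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < S; ++k) {
      int best = 0;
      double bv = delta(t - 1, 0) + logT(0, k);
      for (int j = 1; j < S; ++j) {
        double v = delta(t - 1, j) + logT(j, k);
        if (v > bv) { bv = v; best = j; }
      }
      delta(t, k) = bv + logB(t, k);
      psi(t, k) = best;
    }
  int last = 0;
  double bv = delta(T - 1, 0);
  for (int s = 1; s < S; ++s)
    if (delta(T - 1, s) > bv) { bv = delta(T - 1, s); last = s; }
  IntegerVector path(T);
  path[T - 1] = last;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  return List::create(_["states"] = path, _["log_joint"] = bv);
}
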