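#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward algorithm over concatenated independent chains.
// logdens: T_total x N per-observation emission log densities.
// chain_len: lengths of the chains laid out consecutively in logdens.
// Returns the summed log marginal likelihood; -Inf if any step has zero
// total probability.
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix logdens, NumericVector delta,
                          NumericMatrix Gamma, IntegerVector chain_len) {
  const int N = logdens.ncol();
  double ll = 0.0;
  int t0 = 0;
  std::vector<double> phi(N), tmp(N);
  for (int c = 0; c < chain_len.size(); ++c) {
    const int T = chain_len[c];
    // per-row max-shift keeps densities in range before exponentiating
    double m = R_NegInf;
    for (int j = 0; j < N; ++j) m = std::max(m, logdens(t0, j));
    if (!R_finite(m)) return R_NegInf;
    double s = 0.0;
    for (int j = 0; j < N; ++j) {
      phi[j] = delta[j] * std::exp(logdens(t0, j) - m);
      s += phi[j];
    }
    if (s <= 0.0) return R_NegInf;
    ll += std::log(s) + m;
    for (int j = 0; j < N; ++j) phi[j] /= s;
    for (int t = t0 + 1; t < t0 + T; ++t) {
      m = R_NegInf;
      for (int j = 0; j < N; ++j) m = std::max(m, logdens(t, j));
      if (!R_finite(m)) return R_NegInf;
      s = 0.0;
      for (int j = 0; j < N; ++j) {
        double acc = 0.0;
        for (int i = 0; i < N; ++i) acc += phi[i] * Gamma(i, j);
        tmp[j] = acc * std::exp(logdens(t, j) - m);
        s += tmp[j];
      }
      if (s <= 0.0) return R_NegInf;
      ll += std::log(s) + m;
      for (int j = 0; j < N; ++j) phi[j] = tmp[j] / s;
    }
    t0 += T;
  }
  return ll;
}

// Viterbi decoding in log space over concatenated independent chains.
// Returns the 1-based most-probable state path (ties resolved toward the
// lowest state index).
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logdens, NumericVector delta,
                          NumericMatrix Gamma, IntegerVector chain_len) {
  const int N = logdens.ncol();
  const int Ttot = logdens.nrow();
  IntegerVector path(Ttot);
  NumericMatrix lG(N, N);
  NumericVector ld(N);
  for (int i = 0; i < N; ++i) {
    ld[i] = std::log(delta[i]);
    for (int j = 0; j < N; ++j) lG(i, j) = std::log(Gamma(i, j));
  }
  int t0 = 0;
  for (int c = 0; c < chain_len.size(); ++c) {
    const int T = chain_len[c];
    NumericMatrix v(T, N);
    IntegerMatrix bp(T, N);
    for (int j = 0; j < N; ++j) v(0, j) = ld[j] + logdens(t0, j);
    for (int t = 1; t < T; ++t) {
      for (int j = 0; j < N; ++j) {
        double best = R_NegInf;
        int arg = 0;
        for (int i = 0; i < N; ++i) {
          double cand = v(t - 1, i) + lG(i, j);
          if (cand > best) { best = cand; arg = i; }
        }
        v(t, j) = best + logdens(t0 + t, j);
        bp(t, j) = arg;
      }
    }
    double best = R_NegInf;
    int arg = 0;
    for (int j = 0; j < N; ++j) if (v(T - 1, j) > best) { best = v(T - 1, j); arg = j; }
    path[t0 + T - 1] = arg + 1;
    for (int t = T - 1; t > 0; --t) {
      arg = bp(t, arg);
      path[t0 + t - 1] = arg + 1;
    }
    t0 += T;
  }
  return path;
}
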