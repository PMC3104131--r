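#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding of a Gaussian-emission HMM in log space.
// States are indexed 1..K in the order given by `means`/`sds`.
// Exact score ties are broken by the preference order normal (2) >
// increased (3) > decreased (1) for the 3-state copy-number model; for
// general K the order is 2, 3, ..., K, 1 which reduces to the same rule.
// [[Rcpp::export]]
IntegerVector viterbi_path(NumericVector z, NumericVector means,
                           NumericVector sds, NumericMatrix ltrans,
                           NumericVector linit) {
  const int n = z.size(), K = means.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> pref(K);
  for (int k = 0; k < K; ++k) pref[k] = (k + 1) % K;  // 1,2,..,K-1,0
  NumericMatrix lemis(n, K);
  const double l2pi = std::log(2.0 * M_PI);
  for (int k = 0; k < K; ++k) {
    const double m = means[k], s = sds[k], ls = std::log(s);
    for (int t = 0; t < n; ++t) {
      const double d = (z[t] - m) / s;
      lemis(t, k) = -0.5 * l2pi - ls - 0.5 * d * d;
    }
  }
  NumericMatrix V(n, K);
  IntegerMatrix bp(n, K);
  for (int k = 0; k < K; ++k) V(0, k) = linit[k] + lemis(0, k);
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf;
      int arg = pref[0];
      for (int pi = 0; pi < K; ++pi) {
        const int i = pref[pi];
        const double cand = V(t - 1, i) + ltrans(i, j);
        if (cand > best) { best = cand; arg = i; }
      }
      bp(t, j) = arg;
      V(t, j) = best + lemis(t, j);
    }
  }
  IntegerVector path(n);
  double best = R_NegInf;
  int arg = pref[0];
  for (int pi = 0; pi < K; ++pi) {
    const int k = pref[pi];
    if (V(n - 1, k) > best) { best = V(n - 1, k); arg = k; }
  }
  path[n - 1] = arg + 1;
  for (int t = n - 2; t >= 0; --t)
    path[t] = bp(t + 1, path[t + 1] - 1) + 1;
  return path;
}
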