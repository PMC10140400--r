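// Tie-flip Metropolis sampler over unordered dyads for dyad-independent
// ERGM terms. Each step proposes toggling a uniformly random dyad and
// accepts with probability min(1, exp(theta . delta_change)), where the
// change statistics depend only on the dyad's endpoint-attribute pattern.
// Uses R's RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// state:   current edge indicator per dyad (modified in place on a copy)
// pattern: 0-based attribute-pair pattern index per dyad
// delta:   patterns x k change-statistic matrix
// stats0:  sufficient statistics of the initial state
// returns: nsamples x k matrix of post-burn-in, thinned statistics
// [[Rcpp::export]]
NumericMatrix mh_sample_cpp(LogicalVector state, IntegerVector pattern,
                            NumericMatrix delta, NumericVector theta,
                            NumericVector stats0, double burnin,
                            double interval, int nsamples) {
  int D = state.size(), k = theta.size(), np = delta.nrow();
  LogicalVector y = clone(state);
  std::vector<double> stats(stats0.begin(), stats0.end());
  std::vector<double> score(np);
  for (int p = 0; p < np; ++p) {
    double s = 0.0;
    for (int a = 0; a < k; ++a) s += theta[a] * delta(p, a);
    score[p] = s;
  }
  NumericMatrix out(nsamples, k);
  long long burn = (long long)burnin, thin = (long long)interval;
  if (thin < 1) thin = 1;
  int taken = 0;
  for (long long t = 0; taken < nsamples; ++t) {
    int idx = (int)(unif_rand() * D);
    if (idx >= D) idx = D - 1;
    int pat = pattern[idx];
    double sgn = y[idx] ? -1.0 : 1.0;
    double lr = sgn * score[pat];
    if (lr >= 0.0 || unif_rand() < std::exp(lr)) {
      y[idx] = !y[idx];
      for (int a = 0; a < k; ++a) stats[a] += sgn * delta(pat, a);
    }
    if (t >= burn && ((t - burn + 1) % thin) == 0) {
      for (int a = 0; a < k; ++a) out(taken, a) = stats[a];
      ++taken;
    }
  }
  return out;
}
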