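#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Replay a match list n_rand times in randomized order and accumulate the
// final per-item ratings. Shuffling uses R's RNG (unif_rand) so results are
// reproducible under set.seed(). With resample = true, match indices are
// drawn with replacement instead of permuted (a with-replacement bootstrap).
// [[Rcpp::export]]
List elo_replay_cpp(IntegerVector winner, IntegerVector loser, int n_items,
                    double k, double start, int n_rand, bool resample) {
  const int m = winner.size();
  std::vector<double> r(n_items), sum(n_items, 0.0), sumsq(n_items, 0.0);
  std::vector<int> ord(m);
  RNGScope scope;
  for (int b = 0; b < n_rand; ++b) {
    if (resample) {
      for (int i = 0; i < m; ++i)
        ord[i] = (int)(unif_rand() * m);
    } else {
      for (int i = 0; i < m; ++i) ord[i] = i;
      for (int i = m - 1; i > 0; --i) {  // Fisher-Yates
        int j = (int)(unif_rand() * (i + 1));
        std::swap(ord[i], ord[j]);
      }
    }
    std::fill(r.begin(), r.end(), start);
    for (int i = 0; i < m; ++i) {
      const int w = winner[ord[i]] - 1, l = loser[ord[i]] - 1;
      const double e = 1.0 / (1.0 + std::pow(10.0, (r[l] - r[w]) / 400.0));
      const double d = k * (1.0 - e);
      r[w] += d;
      r[l] -= d;
    }
    for (int j = 0; j < n_items; ++j) {
      sum[j] += r[j];
      sumsq[j] += r[j] * r[j];
    }
  }
  NumericVector melo(n_items), sdv(n_items);
  for (int j = 0; j < n_items; ++j) {
    const double mu = sum[j] / n_rand;
    melo[j] = mu;
    double v = 0.0;
    if (n_rand > 1) {
      v = (sumsq[j] - (double)n_rand * mu * mu) / (n_rand - 1);
      if (v < 0.0) v = 0.0;
    }
    sdv[j] = std::sqrt(v);
  }
  return List::create(_["melo"] = melo, _["sd"] = sdv);
}
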