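#include <Rcpp.h>
using namespace Rcpp;

// Sequential Elo pass over an ordered interaction stream.
// winner/loser are 1-based indices into entry_scores. Each interaction
// contributes -log p(winner beats loser at current scores); then
// winner += k * (1 - p), loser -= k * (1 - p).

static inline double win_prob(double si, double sj, double scale) {
  return 1.0 / (1.0 + std::pow(10.0, -(si - sj) / scale));
}

// [[Rcpp::export]]
double elo_seq_nll(IntegerVector winner, IntegerVector loser,
                   NumericVector entry_scores, double k, double scale) {
  int n = winner.size();
  NumericVector s = clone(entry_scores);
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    int w = winner[t] - 1, l = loser[t] - 1;
    double p = win_prob(s[w], s[l], scale);
    nll -= std::log(p);
    double d = k * (1.0 - p);
    s[w] += d;
    s[l] -= d;
  }
  return nll;
}

// Full pass returning the score trace: row t holds all scores after
// interaction t has been applied. Used to expand daily series.
// [[Rcpp::export]]
List elo_seq_run(IntegerVector winner, IntegerVector loser,
                 NumericVector entry_scores, double k, double scale) {
  int n = winner.size(), m = entry_scores.size();
  NumericVector s = clone(entry_scores);
  NumericMatrix trace(n, m);
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    int w = winner[t] - 1, l = loser[t] - 1;
    double p = win_prob(s[w], s[l], scale);
    nll -= std::log(p);
    double d = k * (1.0 - p);
    s[w] += d;
    s[l] -= d;
    for (int j = 0; j < m; ++j) trace(t, j) = s[j];
  }
  return List::create(_["nll"] = nll, _["final_scores"] = s,
                      _["trace"] = trace);
}
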