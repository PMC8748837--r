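#include <Rcpp.h>
using namespace Rcpp;

// Cyclic boosting of per-feature shape graphs on pre-binned features.
//
// Features arrive already discretized, so the "shallow tree" of each
// boosting step reduces to a per-bin mean of the current log-loss gradient
// residuals (y - p): a depth-1 regressor on a categorical. One epoch is a
// full round-robin pass over the features; residuals are refreshed after
// every feature so each learner sees the current model.
//
// X: n x d integer matrix of 1-based bin indices.
// y: 0/1 labels. n_bins: realized bin count per feature.
// Returns the raw (uncentered) graphs; centering happens in R.
// [[Rcpp::export]]
List ebm_boost_cpp(const IntegerMatrix& X, const NumericVector& y,
                   const IntegerVector& n_bins, double learning_rate,
                   int n_epochs, double intercept) {
  const int n = X.nrow(), d = X.ncol();
  std::vector< std::vector<double> > graphs(d);
  for (int j = 0; j < d; ++j) graphs[j].assign(n_bins[j], 0.0);

  std::vector<double> score(n, intercept);
  std::vector<double> sum_res;
  std::vector<int> cnt;
  std::vector<double> upd;

  for (int epoch = 0; epoch < n_epochs; ++epoch) {
    for (int j = 0; j < d; ++j) {
      const int nb = n_bins[j];
      sum_res.assign(nb, 0.0);
      cnt.assign(nb, 0);
      for (int i = 0; i < n; ++i) {
        const double p = 1.0 / (1.0 + std::exp(-score[i]));
        const int b = X(i, j) - 1;
        sum_res[b] += y[i] - p;
        cnt[b] += 1;
      }
      upd.assign(nb, 0.0);
      for (int b = 0; b < nb; ++b) {
        if (cnt[b] > 0) {
          upd[b] = learning_rate * sum_res[b] / cnt[b];
          graphs[j][b] += upd[b];
        }
      }
      for (int i = 0; i < n; ++i) score[i] += upd[X(i, j) - 1];
    }
  }

  List out_graphs(d);
  for (int j = 0; j < d; ++j) out_graphs[j] = NumericVector(graphs[j].begin(), graphs[j].end());
  return List::create(_["graphs"] = out_graphs,
                      _["score"] = NumericVector(score.begin(), score.end()));
}
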