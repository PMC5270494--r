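#include <Rcpp.h>
using namespace Rcpp;

// Inner LVQ1 training loop.
//
// W:       hn x p prototype matrix (modified copy returned)
// pc:      1-based prototype -> class map
// X:       n x p training inputs
// y:       1-based class labels
// alphas:  per-epoch learning rates
// orders:  epochs x n matrix of 1-based presentation orders (drawn in R
//          under the caller's seed, so reproducibility stays in R)
// error_limit / use_limit: optional end-of-epoch training-error stop (%)
// wins:    running win counts (modified copy returned)
//
// Winner = argmin Euclidean distance, ties to the lowest index (strict <
// on an ascending scan). Each presentation moves only the winner by
// +/- alpha * (x - w).
// [[Rcpp::export]]
List lvq_train_loop(NumericMatrix W_in, IntegerVector pc, NumericMatrix X,
                    IntegerVector y, NumericVector alphas,
                    IntegerMatrix orders, double error_limit, bool use_limit,
                    IntegerVector wins_in) {
  NumericMatrix W = clone(W_in);
  IntegerVector wins = clone(wins_in);
  const int hn = W.nrow(), p = W.ncol(), n = X.nrow();
  const int epochs = orders.nrow();
  std::vector<double> err(epochs);
  int epochs_run = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    const double a = alphas[ep];
    for (int t = 0; t < n; ++t) {
      const int j = orders(ep, t) - 1;
      // winner search
      int best = 0;
      double best_d = R_PosInf;
      for (int i = 0; i < hn; ++i) {
        double d = 0.0;
        for (int k = 0; k < p; ++k) {
          const double diff = X(j, k) - W(i, k);
          d += diff * diff;
        }
        if (d < best_d) {
          best_d = d;
          best = i;
        }
      }
      const double s = (pc[best] == y[j]) ? a : -a;
      for (int k = 0; k < p; ++k) {
        W(best, k) += s * (X(j, k) - W(best, k));
      }
      wins[best] += 1;
    }
    // end-of-epoch training error
    int wrong = 0;
    for (int j = 0; j < n; ++j) {
      int best = 0;
      double best_d = R_PosInf;
      for (int i = 0; i < hn; ++i) {
        double d = 0.0;
        for (int k = 0; k < p; ++k) {
          const double diff = X(j, k) - W(i, k);
          d += diff * diff;
        }
        if (d < best_d) {
          best_d = d;
          best = i;
        }
      }
      if (pc[best] != y[j]) ++wrong;
    }
    err[ep] = 100.0 * wrong / n;
    epochs_run = ep + 1;
    if (use_limit && err[ep] <= error_limit) break;
    if (ep % 100 == 99) Rcpp::checkUserInterrupt();
  }

  return List::create(_["W"] = W, _["wins"] = wins,
                      _["epochs_run"] = epochs_run,
                      _["error_pct"] = NumericVector(err.begin(),
                                                     err.begin() + epochs_run));
}
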