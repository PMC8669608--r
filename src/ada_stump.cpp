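#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Discrete AdaBoost with depth-1 decision stumps.
//
// X: n x d feature matrix, y: +1/-1 labels, rounds: boosting rounds.
// Each round picks the (feature, threshold, polarity) stump minimising the
// weighted 0/1 error over all mid-point thresholds of every feature
// (ties: first feature / lowest threshold), then reweights samples by
// exp(-alpha * y * h(x)).  Stops early when no stump beats chance or a
// stump is perfect.  Deterministic: no randomness is involved.
//
// Returns per-feature importance (sum of alpha over rounds in which the
// feature was chosen) and the stump list.
// [[Rcpp::export]]
List ada_stump_boost(NumericMatrix X, NumericVector y, int rounds) {
  const int n = X.nrow(), d = X.ncol();
  if (n < 2) stop("need at least 2 samples");

  // pre-sort sample indices within each feature (once)
  std::vector<int> ord((size_t)n * d);
  for (int j = 0; j < d; ++j) {
    int* o = &ord[(size_t)j * n];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* col = &X(0, j);
    std::sort(o, o + n, [col](int a, int b) { return col[a] < col[b]; });
  }

  std::vector<double> w(n, 1.0 / n);
  NumericVector importance(d);
  std::vector<int> sel_feature;
  std::vector<double> sel_thr, sel_pol, sel_alpha, sel_err;

  for (int r = 0; r < rounds; ++r) {
    double wpos = 0.0;
    for (int i = 0; i < n; ++i) if (y[i] > 0) wpos += w[i];
    const double wneg = 1.0 - wpos;

    double best_err = 0.5;   // must strictly beat chance
    int best_j = -1;
    double best_thr = 0.0, best_pol = 1.0;

    for (int j = 0; j < d; ++j) {
      const int* o = &ord[(size_t)j * n];
      const double* col = &X(0, j);
      double cpos = 0.0, cneg = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        const int i = o[k];
        if (y[i] > 0) cpos += w[i]; else cneg += w[i];
        if (col[o[k]] == col[o[k + 1]]) continue;  // no cut between ties
        // polarity +1: predict +1 for x > thr, -1 otherwise
        const double err_plus = cpos + (wneg - cneg);
        const double err_minus = 1.0 - err_plus;
        if (err_plus < best_err) {
          best_err = err_plus; best_j = j; best_pol = 1.0;
          best_thr = 0.5 * (col[o[k]] + col[o[k + 1]]);
        }
        if (err_minus < best_err) {
          best_err = err_minus; best_j = j; best_pol = -1.0;
          best_thr = 0.5 * (col[o[k]] + col[o[k + 1]]);
        }
      }
    }

    if (best_j < 0) break;  // no informative stump left

    const double eps = 1e-10;
    const double err_c = std::min(std::max(best_err, eps), 1.0 - eps);
    const double alpha = 0.5 * std::log((1.0 - err_c) / err_c);
    importance[best_j] += alpha;
    sel_feature.push_back(best_j + 1);
    sel_thr.push_back(best_thr);
    sel_pol.push_back(best_pol);
    sel_alpha.push_back(alpha);
    sel_err.push_back(best_err);

    double wsum = 0.0;
    const double* col = &X(0, best_j);
    for (int i = 0; i < n; ++i) {
      const double h = best_pol * (col[i] > best_thr ? 1.0 : -1.0);
      w[i] *= std::exp(-alpha * y[i] * h);
      wsum += w[i];
    }
    for (int i = 0; i < n; ++i) w[i] /= wsum;

    if (best_err <= eps) break;  // perfect stump: further rounds repeat it
  }

  return List::create(
    _["importance"] = importance,
    _["stumps"] = DataFrame::create(
      _["feature"] = sel_feature, _["threshold"] = sel_thr,
      _["polarity"] = sel_pol, _["alpha"] = sel_alpha,
      _["error"] = sel_err));
}
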