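#include <Rcpp.h>
#include <cmath>

// Classic dynamic-programming DTW over 2-D point sequences with Euclidean
// local cost and unit-slope moves (match / insert / delete), no window
// constraint. Returns the total accumulated cost.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(Rcpp::NumericVector ax, Rcpp::NumericVector ay,
                Rcpp::NumericVector bx, Rcpp::NumericVector by) {
  const int n = ax.size(), m = bx.size();
  if (n == 0 || m == 0) Rcpp::stop("empty sequence");
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      double c = std::sqrt(dx * dx + dy * dy);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else if (i == 0) best = cur[j - 1];
      else if (j == 0) best = prev[j];
      else {
        best = prev[j - 1];
        if (prev[j] < best) best = prev[j];
        if (cur[j - 1] < best) best = cur[j - 1];
      }
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
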