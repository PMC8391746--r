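#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic-programming DTW with absolute-difference local cost and an
// unconstrained warping window; steps (i-1,j), (i,j-1), (i-1,j-1).
// [[Rcpp::export(name = ".dtw_dp")]]
double dtw_dp(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("dtw: empty input");
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double c = std::fabs(a[i - 1] - b[j - 1]);
      double best = prev[j];
      if (prev[j - 1] < best) best = prev[j - 1];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Average isolation path length per probe row over an ensemble.
// Each tree is a numeric matrix with columns:
//   0 feature (1-based; 0 => external node), 1 split value,
//   2 left child row (1-based), 3 right child row, 4 node size,
//   5 c(size) termination adjustment (external nodes).
// Path length = edges traversed + c(size at external node).
// [[Rcpp::export(name = ".forest_avg_path")]]
NumericVector forest_avg_path(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      double depth = 0.0;
      while (tr(node, 0) > 0) {
        int f = (int)tr(node, 0) - 1;
        node = (X(i, f) < tr(node, 1)) ? (int)tr(node, 2) - 1
                                       : (int)tr(node, 3) - 1;
        depth += 1.0;
      }
      out[i] += depth + tr(node, 5);
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= (double)T;
  return out;
}
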