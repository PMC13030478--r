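#include <Rcpp.h>
using namespace Rcpp;

// Exact Fisher/Jenks dynamic program on weighted distinct values.
// values must be sorted ascending; weights are positive counts.
// Returns 0-based indices of the last member of classes 1..k-1.
// Cost of a contiguous class [i, j] is the weighted within-class sum of
// squared deviations, computed from prefix sums in O(1).
// [[Rcpp::export]]
IntegerVector jenks_dp(NumericVector values, NumericVector weights, int k) {
  int n = values.size();
  if (k < 1 || k > n) stop("k must be in 1..number of distinct values");
  std::vector<double> cw(n + 1, 0.0), cwv(n + 1, 0.0), cwv2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cw[i + 1]  = cw[i] + weights[i];
    cwv[i + 1] = cwv[i] + weights[i] * values[i];
    cwv2[i + 1] = cwv2[i] + weights[i] * values[i] * values[i];
  }
  auto cost = [&](int i, int j) {  // class covering values[i..j]
    double w = cw[j + 1] - cw[i];
    double s = cwv[j + 1] - cwv[i];
    double s2 = cwv2[j + 1] - cwv2[i];
    double c = s2 - s * s / w;
    return c > 0 ? c : 0.0;
  };
  std::vector<std::vector<double>> D(k, std::vector<double>(n, 0.0));
  std::vector<std::vector<int>> B(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) D[0][j] = cost(0, j);
  for (int c = 1; c < k; ++c) {
    for (int j = c; j < n; ++j) {
      double best = R_PosInf; int arg = c;
      for (int i = c; i <= j; ++i) {
        double v = D[c - 1][i - 1] + cost(i, j);
        if (v < best) { best = v; arg = i; }
      }
      D[c][j] = best;
      B[c][j] = arg;
    }
  }
  IntegerVector breaks(k - 1);
  int j = n - 1;
  for (int c = k - 1; c >= 1; --c) {
    int i = B[c][j];
    breaks[c - 1] = i - 1;  // last index of the previous class
    j = i - 1;
  }
  return breaks;
}

// Total within-class SS of the optimal k-partition (for property tests).
// [[Rcpp::export]]
double jenks_dp_ssw(NumericVector values, NumericVector weights, int k) {
  int n = values.size();
  IntegerVector br = jenks_dp(values, weights, k);
  std::vector<int> lo, hi;
  int start = 0;
  for (int c = 0; c < k - 1; ++c) { lo.push_back(start); hi.push_back(br[c]); start = br[c] + 1; }
  lo.push_back(start); hi.push_back(n - 1);
  double total = 0.0;
  for (int c = 0; c < k; ++c) {
    double w = 0, s = 0, s2 = 0;
    for (int i = lo[c]; i <= hi[c]; ++i) {
      w += weights[i]; s += weights[i] * values[i]; s2 += weights[i] * values[i] * values[i];
    }
    if (w > 0) total += std::max(0.0, s2 - s * s / w);
  }
  return total;
}
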