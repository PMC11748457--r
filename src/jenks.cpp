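#include <Rcpp.h>
using namespace Rcpp;

// Exact Fisher-Jenks dynamic program on a sorted value vector.
// Returns the 1-based index (into the sorted vector) of the first
// element of each class, classes 1..k. Within-class cost is the sum of
// squared deviations from the class mean, computed incrementally.
// [[Rcpp::export]]
IntegerVector fisher_jenks_limits(NumericVector sorted_values, int k) {
  const int n = sorted_values.size();
  if (k < 1 || k > n) stop("k must be between 1 and the number of values");

  // lower_class_limits[m][j]: first index of class j for prefix of length m
  std::vector<std::vector<int> > lcl(n + 1, std::vector<int>(k + 1, 0));
  std::vector<std::vector<double> > cost(
      n + 1, std::vector<double>(k + 1, std::numeric_limits<double>::max()));

  for (int j = 1; j <= k; ++j) {
    lcl[1][j] = 1;
    cost[1][j] = 0.0;
  }

  for (int l = 2; l <= n; ++l) {
    double s1 = 0.0, s2 = 0.0, w = 0.0;
    for (int m = 1; m <= l; ++m) {
      // class candidate covering sorted_values[l-m .. l-1]
      int i3 = l - m + 1;
      double val = sorted_values[i3 - 1];
      s2 += val * val;
      s1 += val;
      w += 1.0;
      double variance = s2 - (s1 * s1) / w;
      int i4 = i3 - 1;
      if (i4 != 0) {
        for (int j = 2; j <= k; ++j) {
          double cand = variance + cost[i4][j - 1];
          if (cand <= cost[l][j]) {
            lcl[l][j] = i3;
            cost[l][j] = cand;
          }
        }
      }
    }
    lcl[l][1] = 1;
    cost[l][1] = s2 - (s1 * s1) / w;
  }

  IntegerVector out(k + 1);
  out[k] = n;  // convenience: last position
  int m = n;
  for (int j = k; j >= 1; --j) {
    out[j - 1] = lcl[m][j];
    m = lcl[m][j] - 1;
  }
  out.attr("cost") = cost[n][k];
  return out;
}
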