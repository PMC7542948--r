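#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scan every admissible split of one segment, maximizing the scaled sample
// energy divergence between the two parts:
//   Q(k) = (m*n/(m+n)) * ( 2*B/(m*n) - WX/C(m,2) - WY/C(n,2) )
// with m = k elements on the left, n = L - k on the right, B the sum of
// cross |x_i - y_j|^alpha, WX/WY the within-part pair sums. Incremental
// O(L) updates per split give an O(L^2) scan, which the permutation test
// repeats many times — hence compiled code.
// Returns the best left size k (min_segment <= k <= L - min_segment) and
// the maximal statistic; stat is -Inf when no admissible split exists.
// [[Rcpp::export]]
List energy_best_split(NumericVector x, int min_segment, double alpha) {
  const int L = x.size();
  if (min_segment < 2) min_segment = 2;
  if (L < 2 * min_segment)
    return List::create(_["k"] = NA_INTEGER,
                        _["stat"] = R_NegInf);

  const int k0 = min_segment;
  const bool a1 = (alpha == 1.0); // default moment index: skip pow()
  double WX = 0.0, WY = 0.0, B = 0.0;

  // initial sums at k = k0
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      double d = std::fabs(x[i] - x[j]);
      if (!a1) d = std::pow(d, alpha);
      if (j < k0) WX += d;
      else if (i >= k0) WY += d;
      else B += d;
    }
  }

  double best_stat = R_NegInf;
  int best_k = NA_INTEGER;
  int k = k0;
  while (true) {
    double m = (double)k, n = (double)(L - k);
    double e = 2.0 * B / (m * n)
             - WX / (m * (m - 1.0) / 2.0)
             - WY / (n * (n - 1.0) / 2.0);
    double q = (m * n / (m + n)) * e;
    if (q > best_stat) { best_stat = q; best_k = k; }
    if (k >= L - min_segment) break;
    // move x[k] (0-based) from the right part to the left part
    double a = 0.0, c = 0.0;
    const double e_val = x[k];
    if (a1) {
      for (int i = 0; i < k; ++i) a += std::fabs(x[i] - e_val);
      for (int j = k + 1; j < L; ++j) c += std::fabs(e_val - x[j]);
    } else {
      for (int i = 0; i < k; ++i)
        a += std::pow(std::fabs(x[i] - e_val), alpha);
      for (int j = k + 1; j < L; ++j)
        c += std::pow(std::fabs(e_val - x[j]), alpha);
    }
    WX += a;
    WY -= c;
    B += c - a;
    ++k;
  }
  return List::create(_["k"] = best_k, _["stat"] = best_stat);
}
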