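#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy. Counts unordered pairs
// (i < j) of templates starting within 1..N-m whose Chebyshev distance
// is <= r over m points (B) and over m + 1 points (A). Self-matches are
// excluded by construction; the A/B ratio is unchanged by counting each
// pair once instead of twice.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // templates with an (m+1)-point extension
  double a = 0.0, b = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double t = std::fabs(x[i + k] - x[j + k]);
        if (t > d) d = t;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      b += 1.0;
      double t = std::fabs(x[i + m] - x[j + m]);
      if (t <= r) a += 1.0;  // extension stays within tolerance
    }
  }
  return NumericVector::create(a, b);
}
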