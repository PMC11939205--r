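#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Template match counts for sample entropy under the Chebyshev norm.
// Counts ordered-pair matches (i != j) among the N - m templates
// x[i..i+m-1], i = 0..N-m-1, within tolerance r (B), and matches of the
// extended (m+1)-point templates over the same index range (A).
// Self-matches are excluded. Templates are sorted on their first
// coordinate so candidate pairs are confined to a sliding window, and the
// remaining coordinates are copied into sorted-order arrays so the inner
// scan is sequential in memory. Returns exactly the brute-force counts.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of templates considered
  if (nt < 2) stop("series too short for embedding dimension m");

  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  // coords[k] holds x[i + k] in sorted-by-first-coordinate order
  std::vector<std::vector<double>> coords(m + 1,
                                          std::vector<double>(nt));
  for (int k = 0; k <= m; ++k) {
    for (int ii = 0; ii < nt; ++ii) coords[k][ii] = x[ord[ii] + k];
  }
  const double* c0 = coords[0].data();
  const double* cm = coords[m].data();

  double B = 0.0, A = 0.0;
  for (int ii = 0; ii < nt; ++ii) {
    const double xi = c0[ii];
    const double lim = xi + r;
    for (int jj = ii + 1; jj < nt && c0[jj] <= lim; ++jj) {
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::abs(coords[k][ii] - coords[k][jj]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::abs(cm[ii] - cm[jj]) <= r) A += 1.0;
    }
  }
  // unordered pairs counted once above; report ordered-pair totals to match
  // the i != j double-sum convention
  return NumericVector::create(_["B"] = 2.0 * B, _["A"] = 2.0 * A);
}
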