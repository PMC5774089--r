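#include <Rcpp.h>
using namespace Rcpp;

// Exact permutation tail counts for the Spearman statistic.
// The observed statistic is the cross-product sum of the two mid-rank
// vectors; over all n! permutations of ry this is a monotone function of
// rho, so tail counts on the cross-product are tail counts on rho.
// Enumerated with Heap's algorithm; feasible for n <= 10 (10! = 3.6e6).
// Returns (count <= observed, count >= observed, n!).
// [[Rcpp::export]]
NumericVector spearman_perm_counts(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  if (n != ry.size()) stop("rank vectors differ in length");
  if (n < 1 || n > 10) stop("exact permutation enumeration supports 1 <= n <= 10");
  std::vector<double> x(rx.begin(), rx.end());
  std::vector<double> y(ry.begin(), ry.end());

  double obs = 0.0;
  for (int i = 0; i < n; ++i) obs += x[i] * y[i];
  const double eps = 1e-9 * (1.0 + std::fabs(obs));

  double n_le = 0.0, n_ge = 0.0, total = 0.0;
  std::vector<int> c(n, 0);

  auto tally = [&]() {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i] * y[i];
    if (s <= obs + eps) n_le += 1.0;
    if (s >= obs - eps) n_ge += 1.0;
    total += 1.0;
  };

  tally();
  int i = 0;
  while (i < n) {
    if (c[i] < i) {
      if (i % 2 == 0) std::swap(y[0], y[i]);
      else std::swap(y[c[i]], y[i]);
      tally();
      ++c[i];
      i = 0;
    } else {
      c[i] = 0;
      ++i;
    }
  }
  return NumericVector::create(n_le, n_ge, total);
}
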