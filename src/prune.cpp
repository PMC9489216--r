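#include <Rcpp.h>
using namespace Rcpp;

// Componentwise dominance filter over the columns of A (one alpha vector per
// column). Column i is dropped when some kept column j satisfies
// A(., j) >= A(., i) - tol everywhere with strict excess somewhere, or when
// j < i and the two columns are equal within tol (duplicates keep the first
// occurrence). The upper envelope max_j A(., j) . b is unchanged for every
// belief b.
// [[Rcpp::export]]
LogicalVector keep_undominated(NumericMatrix A, double tol) {
  const int n = A.nrow(), m = A.ncol();
  std::vector<double> colsum(m, 0.0);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += A(i, j);
    colsum[j] = s;
  }
  LogicalVector keep(m, true);
  const double sum_slack = n * tol;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      if (j == i || !keep[j]) continue;
      if (colsum[j] < colsum[i] - sum_slack) continue;  // cannot dominate
      bool geq = true, strict = false;
      for (int s = 0; s < n; ++s) {
        const double d = A(s, j) - A(s, i);
        if (d < -tol) { geq = false; break; }
        if (d > tol) strict = true;
      }
      if (geq && (strict || j < i)) { keep[i] = false; break; }
    }
  }
  return keep;
}
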