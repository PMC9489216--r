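#include <Rcpp.h>
using namespace Rcpp;

// Expected discounted detection probability of a candidate sniff
// displacement sequence over a discretised crosswind belief. Survivor-mass
// form of the cast-and-sniff Bellman recursion expanded to depth dy.size();
// normalisation factors of the conditional Bayes updates cancel exactly.
// [[Rcpp::export]]
double plan_value_cpp(NumericVector dy, double pos, NumericVector y,
                      NumericVector surv, double y_thr, double lambda,
                      double v, double t_sniff) {
  const int n = y.size(), d = dy.size();
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += surv[i];
  if (total <= 0.0) return 0.0;
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) w[i] = surv[i] / total;
  const double inv2s2 = 1.0 / (2.0 * y_thr * y_thr);
  double disc = 1.0, val = 0.0, p = pos;
  for (int k = 0; k < d; ++k) {
    p += dy[k];
    disc *= std::exp(-lambda * (std::fabs(dy[k]) / v + t_sniff));
    double gsum = 0.0;
    for (int i = 0; i < n; ++i) {
      const double u = p - y[i];
      const double g = std::exp(-u * u * inv2s2);
      gsum += w[i] * g;
      w[i] *= (1.0 - g);
    }
    val += disc * gsum;
  }
  return val;
}
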