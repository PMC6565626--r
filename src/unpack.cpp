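#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gradient-descent vector unpacking.
//
// Xt: d x n matrix, one column per candidate word embedding (unit norm).
// y:  length-d target sentence vector (unit norm).
// Weights start at zero; after iteration t any weight below the growing
// threshold t / (tau * max_iter) is set exactly to zero (signed comparison by
// default, magnitude comparison when prune_magnitude is true).
//
// [[Rcpp::export]]
List unpack_gd_cpp(NumericMatrix Xt, NumericVector y, double eta, double tau,
                   int max_iter, int trace_every, bool prune_magnitude) {
  const int d = Xt.nrow();
  const int n = Xt.ncol();
  std::vector<double> w(n, 0.0);
  std::vector<double> yhat(d, 0.0), resid(d, 0.0);
  std::vector<double> trace;
  trace.reserve(trace_every > 0 ? max_iter / trace_every + 1 : 1);
  double cost = 0.0;
  const double *xp = REAL(Xt);

  for (int t = 1; t <= max_iter; ++t) {
    std::fill(yhat.begin(), yhat.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double wi = w[i];
      if (wi == 0.0) continue;
      const double *col = xp + (size_t)i * d;
      for (int k = 0; k < d; ++k) yhat[k] += wi * col[k];
    }
    cost = 0.0;
    for (int k = 0; k < d; ++k) {
      resid[k] = y[k] - yhat[k];
      cost += resid[k] * resid[k];
    }
    cost *= 0.5;
    if (!std::isfinite(cost))
      stop("vector unpacking diverged (non-finite cost): learning rate eta = %f is unstable",
           eta);

    const double thr = (double)t / (tau * (double)max_iter);
    for (int i = 0; i < n; ++i) {
      const double *col = xp + (size_t)i * d;
      double g = 0.0;
      for (int k = 0; k < d; ++k) g += resid[k] * col[k];
      double wi = w[i] + eta * g;
      const bool prune = prune_magnitude ? (std::fabs(wi) < thr) : (wi < thr);
      if (prune) wi = 0.0;
      w[i] = wi;
    }
    if (trace_every > 0 && (t % trace_every == 0)) trace.push_back(cost);
  }

  // final estimate / cost after the last update+prune
  std::fill(yhat.begin(), yhat.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    const double wi = w[i];
    if (wi == 0.0) continue;
    const double *col = xp + (size_t)i * d;
    for (int k = 0; k < d; ++k) yhat[k] += wi * col[k];
  }
  double final_cost = 0.0;
  for (int k = 0; k < d; ++k) {
    const double r = y[k] - yhat[k];
    final_cost += r * r;
  }
  final_cost *= 0.5;

  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["estimate"] = NumericVector(yhat.begin(), yhat.end()),
                      _["final_cost"] = final_cost,
                      _["cost_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = max_iter);
}
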