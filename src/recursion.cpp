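#include <Rcpp.h>
using namespace Rcpp;

// First-order linear recursion x[i] = a[i] * x[i-1] + b[i] * eps[i], i = 1..n,
// with x[0] = x0. Shared kernel for the exact one-step Ornstein-Uhlenbeck
// update and the Euler-Maruyama integrator; coefficients may vary per step
// (quasi-static drag). Kept in C++ because the recursion cannot be
// vectorised in R and records run to millions of samples.
// [[Rcpp::export(name = ".linear_recursion")]]
NumericVector linear_recursion(NumericVector a, NumericVector b,
                               NumericVector eps, double x0) {
  R_xlen_t n = a.size();
  if (b.size() != n || eps.size() != n)
    stop("a, b and eps must have equal length");
  NumericVector x(n);
  double prev = x0;
  for (R_xlen_t i = 0; i < n; ++i) {
    prev = a[i] * prev + b[i] * eps[i];
    x[i] = prev;
  }
  return x;
}
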