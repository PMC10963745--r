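#include <Rcpp.h>
#include <cmath>

// In-place Adam update for one parameter array. Called once per parameter
// per minibatch; the hot loop of training, so it avoids the temporary
// allocations an equivalent R expression would make. All four arrays are
// privately owned by the calling environments and may be mutated.
// [[Rcpp::export]]
void adam_update_inplace(Rcpp::NumericVector param, Rcpp::NumericVector grad,
                         Rcpp::NumericVector m, Rcpp::NumericVector v,
                         double lr, double beta1, double beta2, double eps,
                         double bc1, double bc2) {
  R_xlen_t n = param.size();
  if (grad.size() != n || m.size() != n || v.size() != n) {
    Rcpp::stop("adam_update_inplace: length mismatch");
  }
  double *p = REAL(param), *g = REAL(grad), *mm = REAL(m), *vv = REAL(v);
  const double a1 = 1.0 - beta1, a2 = 1.0 - beta2;
  const double isq2 = 1.0 / std::sqrt(bc2);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    const double mi = beta1 * mm[i] + a1 * gi;
    const double vi = beta2 * vv[i] + a2 * gi * gi;
    mm[i] = mi;
    vv[i] = vi;
    p[i] -= lr * (mi / bc1) / (std::sqrt(vi) * isq2 + eps);
  }
}
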