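// Small fused kernels for the training engine. They modify freshly
// allocated temporaries in place (the callers guarantee the inputs are
// unshared), avoiding the extra passes and allocations of the equivalent
// base-R expressions.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// out = relu(M + b[col]) computed in place on M
// [[Rcpp::export]]
NumericMatrix bias_relu_inplace(NumericMatrix M, NumericVector b) {
  const int n = M.nrow(), p = M.ncol();
  if (b.size() != p) stop("bias length mismatch");
  for (int j = 0; j < p; ++j) {
    const double bj = b[j];
    double *col = &M(0, j);
    for (int i = 0; i < n; ++i) {
      const double v = col[i] + bj;
      col[i] = v > 0 ? v : 0;
    }
  }
  return M;
}

// relu in place
// [[Rcpp::export]]
NumericMatrix relu_inplace(NumericMatrix M) {
  const R_xlen_t n = static_cast<R_xlen_t>(M.nrow()) * M.ncol();
  double *x = M.begin();
  for (R_xlen_t i = 0; i < n; ++i) if (x[i] < 0) x[i] = 0;
  return M;
}

// G *= (act > 0), in place on G (the ReLU backward mask)
// [[Rcpp::export]]
NumericMatrix relu_mask_inplace(NumericMatrix G, NumericMatrix act) {
  const R_xlen_t n = static_cast<R_xlen_t>(G.nrow()) * G.ncol();
  if (n != static_cast<R_xlen_t>(act.nrow()) * act.ncol())
    stop("shape mismatch");
  double *g = G.begin();
  const double *a = act.begin();
  for (R_xlen_t i = 0; i < n; ++i) if (a[i] <= 0) g[i] = 0;
  return G;
}

// one bias-corrected Adam update, in place on theta / m / v
// [[Rcpp::export]]
void adam_update_inplace(NumericVector theta, NumericVector m, NumericVector v,
                         NumericVector g, double lr, double beta1, double beta2,
                         int t, double eps) {
  const R_xlen_t n = theta.size();
  if (m.size() != n || v.size() != n || g.size() != n) stop("length mismatch");
  const double bc1 = 1.0 - std::pow(beta1, t), bc2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    theta[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}
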