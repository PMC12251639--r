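// Single-pass elementwise kernels for the encoder's hot path. The GELU
// (tanh approximation) is applied to every activation of every layer, so
// the fused forward (value + cached tanh term) and the polynomial backward
// are the dominant elementwise costs of training.
#include <Rcpp.h>
using namespace Rcpp;

static const double GELU_C = 0.7978845608028654;  // sqrt(2/pi)

// [[Rcpp::export]]
List gelu_fwd_cpp(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n), t(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = x[i];
    double ti = std::tanh(GELU_C * (xi + 0.044715 * xi * xi * xi));
    t[i] = ti;
    y[i] = 0.5 * xi * (1.0 + ti);
  }
  return List::create(Named("y") = y, Named("t") = t);
}

// [[Rcpp::export]]
NumericVector gelu_grad_t_cpp(NumericVector x, NumericVector t) {
  R_xlen_t n = x.size();
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = x[i], ti = t[i];
    g[i] = 0.5 * (1.0 + ti) +
      0.5 * xi * (1.0 - ti * ti) * GELU_C * (1.0 + 0.134145 * xi * xi);
  }
  return g;
}
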