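// Elementwise and dense-layer kernels for the network hot path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(const NumericVector& x) {
  const R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = x[i] > 0.0 ? x[i] : 0.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(const NumericVector& dout,
                           const NumericVector& act) {
  const R_xlen_t n = dout.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = act[i] > 0.0 ? dout[i] : 0.0;
  out.attr("dim") = dout.attr("dim");
  return out;
}

// [[Rcpp::export]]
arma::mat dense_fwd_cpp(const arma::mat& X, const arma::mat& W,
                        const arma::vec& b) {
  arma::mat out = X * W;
  out.each_row() += b.t();
  return out;
}
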