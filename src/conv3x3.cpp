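// 3x3 same-padding convolution, forward and backward, via im2col and BLAS.
// The im2col matrix is returned to R so the weight gradient can reuse it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// [[Rcpp::export]]
List conv3x3_forward_cpp(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b) {
  const uword h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const uword N = h * w;
  if (W.n_rows != 9 * cin) stop("weight rows do not match 9 * c_in");
  cube pad(h + 2, w + 2, cin, fill::zeros);
  pad.subcube(1, 1, 0, h, w, cin - 1) = x;
  mat cols(N, 9 * cin);
  uword k = 0;
  for (uword dx = 0; dx < 3; ++dx) {
    for (uword dy = 0; dy < 3; ++dy) {
      for (uword c = 0; c < cin; ++c) {
        cols.col(k * cin + c) =
          vectorise(pad.slice(c).submat(dy, dx, dy + h - 1, dx + w - 1));
      }
      ++k;
    }
  }
  mat out = cols * W;
  out.each_row() += b.t();
  cube outc(h, w, W.n_cols);
  std::memcpy(outc.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return List::create(_["out"] = outc, _["cols"] = cols);
}

// [[Rcpp::export]]
List conv3x3_backward_cpp(const arma::cube& dout, const arma::mat& cols,
                          const arma::mat& W) {
  const uword h = dout.n_rows, w = dout.n_cols, cout_n = dout.n_slices;
  const uword N = h * w;
  const uword cin = W.n_rows / 9;
  if (W.n_cols != cout_n) stop("weight cols do not match c_out");
  const mat dmat(const_cast<double*>(dout.memptr()), N, cout_n, false, true);
  mat dW = cols.t() * dmat;
  vec db = sum(dmat, 0).t();
  mat dcols = dmat * W.t();
  cube dpad(h + 2, w + 2, cin, fill::zeros);
  uword k = 0;
  for (uword dx = 0; dx < 3; ++dx) {
    for (uword dy = 0; dy < 3; ++dy) {
      for (uword c = 0; c < cin; ++c) {
        const mat blk(dcols.colptr(k * cin + c), h, w, false, true);
        dpad.slice(c).submat(dy, dx, dy + h - 1, dx + w - 1) += blk;
      }
      ++k;
    }
  }
  cube dx_out = dpad.subcube(1, 1, 0, h, w, cin - 1);
  return List::create(_["dx"] = dx_out, _["dW"] = dW, _["db"] = db);
}
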