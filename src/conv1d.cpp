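// Length-preserving 1-D cross-correlation over multi-channel signals.
//
// Layout conventions (column-major, matching R arrays):
//   signals  x : cube [in_channels  x time x batch]
//   kernels  w : cube [out_channels x in_channels x kernel_length]
//   output   y : cube [out_channels x time x batch]
//
// Zero padding keeps the temporal length: pad_left on the left and
// (k - 1 - pad_left) on the right.  Each kernel tap is one GEMM of the
// [out x in] tap matrix against the whole shifted padded batch, which
// keeps the bulk of the arithmetic inside BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static cube pad_time(const cube& x, uword pad_left, uword pad_right) {
  cube xp(x.n_rows, x.n_cols + pad_left + pad_right, x.n_slices, fill::zeros);
  xp.cols(pad_left, pad_left + x.n_cols - 1) = x;
  return xp;
}

// [[Rcpp::export(rng = false)]]
arma::cube conv1d_fwd_cpp(const arma::cube& x, const arma::cube& w,
                          const arma::vec& bias, int pad_left) {
  const uword c_out = w.n_rows, c_in = w.n_cols, k = w.n_slices;
  const uword T = x.n_cols, B = x.n_slices;
  if (x.n_rows != c_in)
    Rcpp::stop("input has %d channels but kernel expects %d", (int)x.n_rows, (int)c_in);
  cube xp = pad_time(x, (uword)pad_left, k - 1 - (uword)pad_left);
  const uword Tp = T + k - 1;
  const mat xmat(const_cast<double*>(xp.memptr()), c_in, Tp * B, false, true);
  cube y(c_out, T, B);
  for (uword b = 0; b < B; ++b) y.slice(b) = repmat(bias, 1, T);
  for (uword j = 0; j < k; ++j) {
    const mat yj = w.slice(j) * xmat;  // c_out x (Tp*B)
    for (uword b = 0; b < B; ++b)
      y.slice(b) += yj.cols(b * Tp + j, b * Tp + j + T - 1);
  }
  return y;
}

// Gradients of the loss w.r.t. input, kernels and bias given dL/dy.
// [[Rcpp::export(rng = false)]]
Rcpp::List conv1d_bwd_cpp(const arma::cube& x, const arma::cube& w,
                          const arma::cube& dy, int pad_left) {
  const uword c_out = w.n_rows, c_in = w.n_cols, k = w.n_slices;
  const uword T = x.n_cols, B = x.n_slices;
  const uword pl = (uword)pad_left;
  cube xp = pad_time(x, pl, k - 1 - pl);
  const uword Tp = T + k - 1;
  cube dxp(c_in, Tp, B, fill::zeros);
  cube dw(c_out, c_in, k, fill::zeros);
  const mat dymat(const_cast<double*>(dy.memptr()), c_out, T * B, false, true);
  vec db = sum(dymat, 1);
  for (uword j = 0; j < k; ++j) {
    const mat dxj = w.slice(j).t() * dymat;  // c_in x (T*B)
    mat& dwj = dw.slice(j);
    for (uword b = 0; b < B; ++b) {
      dxp.slice(b).cols(j, j + T - 1) += dxj.cols(b * T, b * T + T - 1);
      dwj += dy.slice(b) * xp.slice(b).cols(j, j + T - 1).t();
    }
  }
  cube dx = dxp.cols(pl, pl + T - 1);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
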