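// Dilated/strided 1-D convolution kernels for the TCN trunk.
// Tensors follow the R array layout: (channels, time, batch) cubes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// x: (C_in, T, B); W: (C_out, C_in, K); b: length C_out
// [[Rcpp::export]]
arma::cube conv1d_forward_cpp(const arma::cube& x, const arma::cube& W,
                              const arma::vec& b, const int stride,
                              const int dil, const int pad) {
  const int t_in = x.n_cols, batch = x.n_slices;
  const int c_in = x.n_rows, c_out = W.n_rows, k = W.n_slices;
  const int span = (k - 1) * dil + 1;
  const int t_pad = t_in + 2 * pad;
  const int t_out = (t_pad - span) / stride + 1;
  cube y(c_out, t_out, batch);
  std::vector<mat> wk(k);
  for (int kk = 0; kk < k; ++kk) wk[kk] = W.slice(kk);
  mat xp(c_in, t_pad, fill::zeros);
  uvec idx(t_out);
  for (int bi = 0; bi < batch; ++bi) {
    xp.cols(pad, pad + t_in - 1) = x.slice(bi);
    mat& ys = y.slice(bi);
    ys.zeros();
    for (int kk = 0; kk < k; ++kk) {
      const int off = kk * dil;
      if (stride == 1) {
        ys += wk[kk] * xp.cols(off, off + t_out - 1);
      } else {
        for (int t = 0; t < t_out; ++t) idx[t] = t * stride + off;
        ys += wk[kk] * xp.cols(idx);
      }
    }
    ys.each_col() += b;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_backward_cpp(const arma::cube& dy, const arma::cube& x,
                               const arma::cube& W, const int stride,
                               const int dil, const int pad) {
  const int t_in = x.n_cols, batch = x.n_slices;
  const int c_in = x.n_rows, c_out = W.n_rows, k = W.n_slices;
  const int span = (k - 1) * dil + 1;
  const int t_pad = t_in + 2 * pad;
  const int t_out = (t_pad - span) / stride + 1;
  cube dx(c_in, t_in, batch);
  cube dW(c_out, c_in, k, fill::zeros);
  vec db(c_out, fill::zeros);
  std::vector<mat> wkt(k);
  for (int kk = 0; kk < k; ++kk) wkt[kk] = W.slice(kk).t();
  mat xp(c_in, t_pad, fill::zeros);
  mat dxp(c_in, t_pad);
  uvec idx(t_out);
  for (int bi = 0; bi < batch; ++bi) {
    xp.cols(pad, pad + t_in - 1) = x.slice(bi);
    dxp.zeros();
    const mat& dyb = dy.slice(bi);
    db += sum(dyb, 1);
    for (int kk = 0; kk < k; ++kk) {
      const int off = kk * dil;
      if (stride == 1) {
        dW.slice(kk) += dyb * xp.cols(off, off + t_out - 1).t();
        dxp.cols(off, off + t_out - 1) += wkt[kk] * dyb;
      } else {
        for (int t = 0; t < t_out; ++t) idx[t] = t * stride + off;
        dW.slice(kk) += dyb * xp.cols(idx).t();
        dxp.cols(idx) += wkt[kk] * dyb;
      }
    }
    dx.slice(bi) = dxp.cols(pad, pad + t_in - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
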