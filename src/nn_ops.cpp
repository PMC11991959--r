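// Elementwise / per-channel ops for the TCN, on (channels, time, batch)
// cubes viewed as (channels, time*batch) matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List bn_forward_cpp(const arma::mat& x, const arma::vec& gamma,
                          const arma::vec& beta, const arma::vec& run_mean,
                          const arma::vec& run_var, const bool training,
                          const double momentum, const double eps) {
  vec mu, v;
  if (training) {
    mu = mean(x, 1);
    v = mean(square(x.each_col() - mu), 1);
  } else {
    mu = run_mean;
    v = run_var;
  }
  vec inv_sd = 1.0 / sqrt(v + eps);
  mat xhat = (x.each_col() - mu);
  xhat.each_col() %= inv_sd;
  mat y = xhat.each_col() % gamma;
  y.each_col() += beta;
  vec new_rm = run_mean, new_rv = run_var;
  if (training) {
    new_rm = (1 - momentum) * run_mean + momentum * mu;
    new_rv = (1 - momentum) * run_var + momentum * v;
  }
  return Rcpp::List::create(
      Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat,
      Rcpp::Named("inv_sd") = inv_sd, Rcpp::Named("run_mean") = new_rm,
      Rcpp::Named("run_var") = new_rv);
}

// [[Rcpp::export]]
Rcpp::List bn_backward_cpp(const arma::mat& dy, const arma::mat& xhat,
                           const arma::vec& inv_sd, const arma::vec& gamma,
                           const bool training) {
  vec dgamma = sum(dy % xhat, 1);
  vec dbeta = sum(dy, 1);
  mat dx;
  if (training) {
    mat dxhat = dy.each_col() % gamma;
    vec m1 = mean(dxhat, 1);
    vec m2 = mean(dxhat % xhat, 1);
    dx = dxhat.each_col() - m1;
    dx -= xhat.each_col() % m2;
    dx.each_col() %= inv_sd;
  } else {
    dx = dy.each_col() % (gamma % inv_sd);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
arma::cube relu_cpp(const arma::cube& x) {
  cube y = x;
  y.transform([](double v) { return v > 0 ? v : 0.0; });
  return y;
}

// dy masked by (out > 0)
// [[Rcpp::export]]
arma::cube relu_grad_cpp(const arma::cube& dy, const arma::cube& out) {
  cube dx = dy;
  const uword n = dx.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (out[i] <= 0) dx[i] = 0.0;
  }
  return dx;
}

// scale channel c of sample b by mask(c, b) (spatial dropout)
// [[Rcpp::export]]
arma::cube channel_scale_cpp(const arma::cube& x, const arma::mat& mask) {
  cube y = x;
  for (uword b = 0; b < y.n_slices; ++b) {
    y.slice(b).each_col() %= mask.col(b);
  }
  return y;
}
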