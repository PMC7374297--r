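// Elementwise and normalization kernels of the trunk, kept in C++ so the
// training loop does not allocate R-level temporaries per batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(rng = false)]]
arma::cube relu_cpp(const arma::cube& x) {
  cube y = x;
  y.for_each([](double& v) { if (v < 0) v = 0; });
  return y;
}

// dy masked by the forward output (y > 0)
// [[Rcpp::export(rng = false)]]
arma::cube relu_bwd_cpp(const arma::cube& dy, const arma::cube& y) {
  cube dx = dy;
  const double* yp = y.memptr();
  double* dp = dx.memptr();
  for (uword i = 0; i < dx.n_elem; ++i) if (yp[i] <= 0) dp[i] = 0;
  return dx;
}

// Per-channel batch normalization given precomputed statistics.
// Returns y and xhat (needed by the backward pass).
// [[Rcpp::export(rng = false)]]
Rcpp::List bn_fwd_cpp(const arma::cube& x, const arma::vec& mu,
                      const arma::vec& inv_sd, const arma::vec& gamma,
                      const arma::vec& beta) {
  const uword C = x.n_rows, ncol = x.n_elem / C;
  cube xhat(arma::size(x)), y(arma::size(x));
  const double* xp = x.memptr();
  double* hp = xhat.memptr();
  double* yp = y.memptr();
  for (uword j = 0; j < ncol; ++j) {
    const double* xj = xp + j * C;
    double* hj = hp + j * C;
    double* yj = yp + j * C;
    for (uword c = 0; c < C; ++c) {
      const double h = (xj[c] - mu[c]) * inv_sd[c];
      hj[c] = h;
      yj[c] = h * gamma[c] + beta[c];
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List bn_bwd_cpp(const arma::cube& dy, const arma::cube& xhat,
                      const arma::vec& gamma, const arma::vec& inv_sd) {
  const uword C = dy.n_rows, n = dy.n_elem, ncol = n / C;
  const double N = (double)ncol;
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  const double* dp = dy.memptr();
  const double* hp = xhat.memptr();
  for (uword j = 0; j < ncol; ++j) {
    const double* dj = dp + j * C;
    const double* hj = hp + j * C;
    for (uword c = 0; c < C; ++c) {
      dgamma[c] += dj[c] * hj[c];
      dbeta[c] += dj[c];
    }
  }
  cube dx(arma::size(dy));
  double* xp = dx.memptr();
  for (uword j = 0; j < ncol; ++j) {
    const double* dj = dp + j * C;
    const double* hj = hp + j * C;
    double* xj = xp + j * C;
    for (uword c = 0; c < C; ++c)
      xj[c] = (dj[c] * gamma[c] - dbeta[c] / N - hj[c] * dgamma[c] / N) * inv_sd[c];
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List channel_stats_cpp(const arma::cube& x) {
  const uword C = x.n_rows, n = x.n_elem, ncol = n / C;
  vec mu(C, fill::zeros), m2(C, fill::zeros);
  const double* xp = x.memptr();
  for (uword j = 0; j < ncol; ++j) {
    const double* xj = xp + j * C;
    for (uword c = 0; c < C; ++c) {
      mu[c] += xj[c];
      m2[c] += xj[c] * xj[c];
    }
  }
  const double N = (double)(n / C);
  mu /= N;
  vec v = m2 / N - mu % mu;
  v.for_each([](double& val) { if (val < 0) val = 0; });
  return Rcpp::List::create(Rcpp::Named("mu") = mu, Rcpp::Named("var") = v);
}

// [[Rcpp::export(rng = false)]]
arma::cube pool_halve_cpp(const arma::cube& x) {
  cube y(x.n_rows, x.n_cols / 2, x.n_slices);
  for (uword b = 0; b < x.n_slices; ++b)
    for (uword t = 0; t < y.n_cols; ++t)
      y.slice(b).col(t) = 0.5 * (x.slice(b).col(2 * t) + x.slice(b).col(2 * t + 1));
  return y;
}

// [[Rcpp::export(rng = false)]]
arma::cube upsample2_cpp(const arma::cube& x) {
  cube y(x.n_rows, 2 * x.n_cols, x.n_slices);
  for (uword b = 0; b < x.n_slices; ++b)
    for (uword t = 0; t < x.n_cols; ++t) {
      y.slice(b).col(2 * t) = x.slice(b).col(t);
      y.slice(b).col(2 * t + 1) = x.slice(b).col(t);
    }
  return y;
}

// Backward of upsample2: sum consecutive output-gradient pairs.
// [[Rcpp::export(rng = false)]]
arma::cube half_sum_cpp(const arma::cube& x) {
  cube y(x.n_rows, x.n_cols / 2, x.n_slices);
  for (uword b = 0; b < x.n_slices; ++b)
    for (uword t = 0; t < y.n_cols; ++t)
      y.slice(b).col(t) = x.slice(b).col(2 * t) + x.slice(b).col(2 * t + 1);
  return y;
}

// [[Rcpp::export(rng = false)]]
arma::cube add_cubes_cpp(const arma::cube& a, const arma::cube& b) {
  return a + b;
}
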