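// Performance kernels for the 3x3 convolution layers.
//
// Feature batches are (n*H*W) x C matrices whose rows are sample-major,
// column-major pixels, so each channel column is a stack of n H x W images.
// Zero-padded 3x3 convolution is computed as an in-C++ im2col gather
// followed by one BLAS gemm; the backward pass reuses the same gather and
// its transpose scatter. Weight rows are ordered offset-major:
// row = o * cin + ci with o = (dc + 1) * 3 + (dr + 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// clamped shift ranges for one offset: output rows r0..r1 read input r0+dr..
static inline void shift_range(int dr, int len, int& o0, int& o1) {
  o0 = std::max(0, -dr);
  o1 = std::min(len - 1, len - 1 - dr);
}

static mat im2col3(const mat& x, int n, int H, int Wd) {
  const int cin = x.n_cols;
  mat cols(x.n_rows, 9 * cin, fill::zeros);
  const cube xc(const_cast<double*>(x.memptr()), H, Wd * n, cin, false, true);
  for (int o = 0; o < 9; ++o) {
    const int dc = o / 3 - 1, dr = o % 3 - 1;
    int r0, r1, c0, c1;
    shift_range(dr, H, r0, r1);
    shift_range(dc, Wd, c0, c1);
    if (r1 < r0 || c1 < c0) continue;
    for (int ci = 0; ci < cin; ++ci) {
      mat view(cols.colptr(o * cin + ci), H, Wd * n, false, true);
      for (int s = 0; s < n; ++s) {
        const int off = s * Wd;
        view.submat(r0, c0 + off, r1, c1 + off) =
            xc.slice(ci).submat(r0 + dr, c0 + dc + off, r1 + dr, c1 + dc + off);
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv3_fwd")]]
arma::mat conv3_fwd(const arma::mat& x, const arma::mat& W,
                    const arma::vec& b, int n, int H, int Wd) {
  mat y = im2col3(x, n, H, Wd) * W;
  y.each_row() += b.t();
  return y;
}

// [[Rcpp::export(name = ".conv3_bwd")]]
Rcpp::List conv3_bwd(const arma::mat& x, const arma::mat& W,
                     const arma::mat& dy, int n, int H, int Wd) {
  const int cin = x.n_cols;
  const mat cols = im2col3(x, n, H, Wd);
  mat dW = cols.t() * dy;
  mat dcols = dy * W.t();
  mat dx(x.n_rows, cin, fill::zeros);
  cube dxc(dx.memptr(), H, Wd * n, cin, false, true);
  for (int o = 0; o < 9; ++o) {
    const int dc = o / 3 - 1, dr = o % 3 - 1;
    int r0, r1, c0, c1;
    shift_range(dr, H, r0, r1);
    shift_range(dc, Wd, c0, c1);
    if (r1 < r0 || c1 < c0) continue;
    for (int ci = 0; ci < cin; ++ci) {
      const mat dview(dcols.colptr(o * cin + ci), H, Wd * n, false, true);
      for (int s = 0; s < n; ++s) {
        const int off = s * Wd;
        dxc.slice(ci).submat(r0 + dr, c0 + dc + off, r1 + dr, c1 + dc + off) +=
            dview.submat(r0, c0 + off, r1, c1 + off);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = sum(dy, 0).t());
}

// y = x * diag(scale) + shift broadcast over rows (fused batch-norm affine)
// [[Rcpp::export(name = ".scale_shift_cols")]]
arma::mat scale_shift_cols(const arma::mat& x, const arma::vec& scale,
                           const arma::vec& shift) {
  mat y = x;
  y.each_row() %= scale.t();
  y.each_row() += shift.t();
  return y;
}

// batch-norm training forward: returns xhat and y = gamma * xhat + beta
// [[Rcpp::export(name = ".bn_fwd")]]
Rcpp::List bn_fwd(const arma::mat& x, const arma::vec& invstd,
                  const arma::vec& mu, const arma::vec& gamma,
                  const arma::vec& beta) {
  mat xhat = x;
  xhat.each_row() -= mu.t();
  xhat.each_row() %= invstd.t();
  mat y = xhat;
  y.each_row() %= gamma.t();
  y.each_row() += beta.t();
  return Rcpp::List::create(Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("y") = y);
}

// batch-norm backward in one pass
// [[Rcpp::export(name = ".bn_bwd")]]
Rcpp::List bn_bwd(const arma::mat& dy, const arma::mat& xhat,
                  const arma::vec& gamma, const arma::vec& invstd) {
  const uword N = dy.n_rows, C = dy.n_cols;
  mat dx(N, C);
  vec dgamma(C), dbeta(C);
  for (uword c = 0; c < C; ++c) {
    const vec dyc = dy.col(c);
    const vec xh = xhat.col(c);
    dgamma(c) = dot(dyc, xh);
    dbeta(c) = accu(dyc);
    const vec dxhat = gamma(c) * dyc;
    const double m1 = accu(dxhat) / N;
    const double m2 = dot(dxhat, xh) / N;
    dx.col(c) = invstd(c) * (dxhat - xh * m2 - m1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
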