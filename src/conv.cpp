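// Dilated 2D convolution primitives for the contact-prediction network.
// Tensors are arma::cube with slices = channels; spatial maps are L x L.
// Weights for a k x k conv are a (C_out) x (C_in * k * k) matrix whose
// column order is (channel, kernel-row, kernel-col) with kernel-col fastest,
// matching the im2col layout below. "same" zero padding is used throughout,
// so kernel size must be odd.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static mat im2col_dil(const cube &x, const int k, const int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = dil * (k - 1) / 2;
  mat out(C * k * k, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat &xc = x.slice(c);
    for (int kr = 0; kr < k; ++kr) {
      for (int kc = 0; kc < k; ++kc) {
        const int row = c * k * k + kr * k + kc;
        const int dr = kr * dil - pad, dc = kc * dil - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dc;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dr;
            if (si < 0 || si >= H) continue;
            out(row, j * H + i) = xc(si, sj);
          }
        }
      }
    }
  }
  return out;
}

static void col2im_add(cube &gx, const mat &gcols, const int k, const int dil) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  const int pad = dil * (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    mat &gc = gx.slice(c);
    for (int kr = 0; kr < k; ++kr) {
      for (int kc = 0; kc < k; ++kc) {
        const int row = c * k * k + kr * k + kc;
        const int dr = kr * dil - pad, dc = kc * dil - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dc;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dr;
            if (si < 0 || si >= H) continue;
            gc(si, sj) += gcols(row, j * H + i);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube &x, const arma::mat &w,
                          const arma::vec &b, const int k, const int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = w.n_rows;
  if ((int)w.n_cols != (int)x.n_slices * k * k)
    Rcpp::stop("weight shape does not match input channels / kernel");
  mat cols = im2col_dil(x, k, dil);
  mat o = w * cols;            // cout x (H*W)
  o.each_col() += b;
  cube out(H, W, cout);
  for (int c = 0; c < cout; ++c)
    out.slice(c) = reshape(o.row(c).t(), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(const arma::cube &x, const arma::mat &w,
                           const arma::cube &gout, const int k, const int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = gout.n_slices;
  mat gmat(cout, H * W);
  for (int c = 0; c < cout; ++c)
    gmat.row(c) = vectorise(gout.slice(c)).t();
  mat cols = im2col_dil(x, k, dil);
  mat gw = gmat * cols.t();
  vec gb = sum(gmat, 1);
  mat gcols = w.t() * gmat;
  cube gx(H, W, x.n_slices, fill::zeros);
  col2im_add(gx, gcols, k, dil);
  return Rcpp::List::create(Rcpp::Named("gw") = gw, Rcpp::Named("gb") = gb,
                            Rcpp::Named("gx") = gx);
}
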