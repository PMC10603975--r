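#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// 'same'-padded im2col / col2im pair used by the convolution layers.
// Output spatial size is ceil(H/stride); total padding
// max((Hout-1)*stride + k - H, 0) split floor(begin)/rest(end).
// Column layout matches an R array of dim (k, k, Cin) flattened
// column-major: row index ki fastest, then kj, then channel.

static void pad_amounts(const int H, const int k, const int s,
                        int &hout, int &pbeg) {
  hout = (H + s - 1) / s;
  int ptot = (hout - 1) * s + k - H;
  if (ptot < 0) ptot = 0;
  pbeg = ptot / 2;
}

// [[Rcpp::export]]
arma::mat im2col_same(const arma::cube &x, const int k, const int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Hout, Wout, pr, pc;
  pad_amounts(H, k, stride, Hout, pr);
  pad_amounts(W, k, stride, Wout, pc);
  arma::mat cols((arma::uword)Hout * Wout, (arma::uword)k * k * C,
                 arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword col = (arma::uword)c * k * k + kj * k + ki;
        for (int oj = 0; oj < Wout; ++oj) {
          const int ij = oj * stride - pc + kj;
          if (ij < 0 || ij >= W) continue;
          for (int oi = 0; oi < Hout; ++oi) {
            const int ii = oi * stride - pr + ki;
            if (ii < 0 || ii >= H) continue;
            cols((arma::uword)oj * Hout + oi, col) = x(ii, ij, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube col2im_same(const arma::mat &cols, const int H, const int W,
                       const int C, const int k, const int stride) {
  int Hout, Wout, pr, pc;
  pad_amounts(H, k, stride, Hout, pr);
  pad_amounts(W, k, stride, Wout, pc);
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword col = (arma::uword)c * k * k + kj * k + ki;
        for (int oj = 0; oj < Wout; ++oj) {
          const int ij = oj * stride - pc + kj;
          if (ij < 0 || ij >= W) continue;
          for (int oi = 0; oi < Hout; ++oi) {
            const int ii = oi * stride - pr + ki;
            if (ii < 0 || ii >= H) continue;
            x(ii, ij, c) += cols((arma::uword)oj * Hout + oi, col);
          }
        }
      }
    }
  }
  return x;
}
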