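// Convolution primitives for the image VAE.
// Layout convention: one image per matrix row, flattened in channel-major,
// row-major-within-channel order (index = c*H*W + h*W + w).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_side(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

static void im2col_one(const double* x, int C, int H, int W,
                       int k, int stride, int pad, mat& cols) {
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int row = c * k * k + ki * k + kj;
        for (int ho = 0; ho < Ho; ++ho) {
          const int hi = ho * stride - pad + ki;
          const bool hok = hi >= 0 && hi < H;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            cols(row, ho * Wo + wo) =
              (hok && wi >= 0 && wi < W) ? xc[hi * W + wi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const mat& cols, int C, int H, int W,
                       int k, int stride, int pad, double* x) {
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);
  std::fill(x, x + (size_t)C * H * W, 0.0);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int row = c * k * k + ki * k + kj;
        for (int ho = 0; ho < Ho; ++ho) {
          const int hi = ho * stride - pad + ki;
          if (hi < 0 || hi >= H) continue;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            xc[hi * W + wi] += cols(row, ho * Wo + wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv2d_forward(const arma::mat& X, const arma::mat& Wmat,
                             const arma::vec& b, int C, int H, int W,
                             int k, int stride, int pad) {
  const int n = X.n_rows;
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);
  const int Cout = Wmat.n_rows;
  mat out(n, (size_t)Cout * Ho * Wo);
  mat cols((size_t)C * k * k, (size_t)Ho * Wo);
  for (int i = 0; i < n; ++i) {
    rowvec xi = X.row(i);
    im2col_one(xi.memptr(), C, H, W, k, stride, pad, cols);
    mat o = Wmat * cols;            // Cout x (Ho*Wo)
    o.each_col() += b;
    out.row(i) = vectorise(o.t()).t();  // channel-major flatten
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_backward(const arma::mat& X, const arma::mat& Wmat,
                               const arma::mat& dOut, int C, int H, int W,
                               int k, int stride, int pad) {
  const int n = X.n_rows;
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);
  const int Cout = Wmat.n_rows;
  mat dX(n, X.n_cols);
  mat dW(size(Wmat), fill::zeros);
  vec db(Cout, fill::zeros);
  mat cols((size_t)C * k * k, (size_t)Ho * Wo);
  for (int i = 0; i < n; ++i) {
    rowvec xi = X.row(i);
    im2col_one(xi.memptr(), C, H, W, k, stride, pad, cols);
    // dOut row back to Cout x (Ho*Wo)
    mat dmat = reshape(dOut.row(i).t(), (size_t)Ho * Wo, Cout).t();
    dW += dmat * cols.t();
    db += sum(dmat, 1);
    mat dcols = Wmat.t() * dmat;
    rowvec dxi(X.n_cols);
    col2im_one(dcols, C, H, W, k, stride, pad, dxi.memptr());
    dX.row(i) = dxi;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Transposed convolution: output side Ho = (Hi - 1) * stride - 2 * pad + k.
// Wt has shape Cin x (Cout*k*k); adjoint of the forward convolution above.
// [[Rcpp::export]]
arma::mat cpp_convt2d_forward(const arma::mat& X, const arma::mat& Wt,
                              const arma::vec& b, int Cin, int Hi, int Wi,
                              int Cout, int k, int stride, int pad) {
  const int n = X.n_rows;
  const int Ho = (Hi - 1) * stride - 2 * pad + k;
  const int Wo = (Wi - 1) * stride - 2 * pad + k;
  mat out(n, (size_t)Cout * Ho * Wo);
  for (int i = 0; i < n; ++i) {
    // xmat: Cin x (Hi*Wi)
    mat xmat = reshape(X.row(i).t(), (size_t)Hi * Wi, Cin).t();
    mat cols = Wt.t() * xmat;  // (Cout*k*k) x (Hi*Wi)
    rowvec oi((size_t)Cout * Ho * Wo);
    col2im_one(cols, Cout, Ho, Wo, k, stride, pad, oi.memptr());
    for (int c = 0; c < Cout; ++c)
      oi.subvec((size_t)c * Ho * Wo, (size_t)(c + 1) * Ho * Wo - 1) += b(c);
    out.row(i) = oi;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_convt2d_backward(const arma::mat& X, const arma::mat& Wt,
                                const arma::mat& dOut, int Cin, int Hi, int Wi,
                                int Cout, int k, int stride, int pad) {
  const int n = X.n_rows;
  const int Ho = (Hi - 1) * stride - 2 * pad + k;
  const int Wo = (Wi - 1) * stride - 2 * pad + k;
  mat dX(n, X.n_cols);
  mat dWt(size(Wt), fill::zeros);
  vec db(Cout, fill::zeros);
  mat dcols((size_t)Cout * k * k, (size_t)Hi * Wi);
  for (int i = 0; i < n; ++i) {
    rowvec doi = dOut.row(i);
    im2col_one(doi.memptr(), Cout, Ho, Wo, k, stride, pad, dcols);
    mat xmat = reshape(X.row(i).t(), (size_t)Hi * Wi, Cin).t();
    dWt += xmat * dcols.t();
    mat dxmat = Wt * dcols;  // Cin x (Hi*Wi)
    dX.row(i) = vectorise(dxmat.t()).t();
    mat dmat = reshape(doi.t(), (size_t)Ho * Wo, Cout).t();
    db += sum(dmat, 1);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dWt,
                            Rcpp::Named("db") = db);
}
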