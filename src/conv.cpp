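// Batched 3x3 convolution kernels for the CNN inverse solver.
//
// Activations are (H*W*B) x C matrices, rows pixel-fastest then image.
// spix is the (H*W) x 9 gather table: spix(p, o) is the 1-based source
// pixel feeding kernel offset o at output pixel p, with 0 meaning a
// zero-padded read. Circular padding along the image width is encoded in
// the table, so the backward pass is exactly the adjoint scatter of the
// same table. The im2col matrix is never materialized: each offset is
// gathered into one reusable (H*W*B) x C buffer and immediately folded
// into the running products, which keeps the working set small.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void gather_offset(const arma::mat& A, const int* sp, int HW, int B,
                          arma::mat& Mo) {
  const int C = A.n_cols;
  for (int c = 0; c < C; ++c) {
    double* dst = Mo.colptr(c);
    const double* src = A.colptr(c);
    for (int b = 0; b < B; ++b) {
      const int off = b * HW;
      for (int p = 0; p < HW; ++p) {
        const int s = sp[p];
        dst[off + p] = (s > 0) ? src[off + s - 1] : 0.0;
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv_fwd_cpp(const arma::mat& A, const IntegerMatrix& spix, int B,
                       const arma::mat& K, const arma::vec& bias) {
  const int HW = spix.nrow();
  const int C = A.n_cols;
  arma::mat Z(static_cast<size_t>(HW) * B, K.n_cols);
  Z.each_row() = bias.t();
  arma::mat Mo(static_cast<size_t>(HW) * B, C);
  for (int o = 0; o < 9; ++o) {
    gather_offset(A, &spix(0, o), HW, B, Mo);
    Z += Mo * K.rows(o * C, (o + 1) * C - 1);
  }
  return Z;
}

// [[Rcpp::export]]
List conv_bwd_cpp(const arma::mat& dZ, const arma::mat& A, const arma::mat& K,
                  const IntegerMatrix& spix, int B) {
  const int HW = spix.nrow();
  const int C = A.n_cols;
  arma::mat dK(9 * C, K.n_cols);
  arma::mat dA(static_cast<size_t>(HW) * B, C, arma::fill::zeros);
  arma::mat Mo(static_cast<size_t>(HW) * B, C);
  arma::mat dMo;
  for (int o = 0; o < 9; ++o) {
    const int* sp = &spix(0, o);
    gather_offset(A, sp, HW, B, Mo);
    dK.rows(o * C, (o + 1) * C - 1) = Mo.t() * dZ;
    dMo = dZ * K.rows(o * C, (o + 1) * C - 1).t();
    for (int c = 0; c < C; ++c) {
      const double* src = dMo.colptr(c);
      double* dst = dA.colptr(c);
      for (int b = 0; b < B; ++b) {
        const int off = b * HW;
        for (int p = 0; p < HW; ++p) {
          const int s = sp[p];
          if (s > 0) dst[off + s - 1] += src[off + p];
        }
      }
    }
  }
  return List::create(_["dA"] = dA, _["dK"] = dK,
                      _["db"] = arma::sum(dZ, 0));
}
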