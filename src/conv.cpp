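// 2-D convolution primitives for the dense noise-estimation network.
//
// Layout conventions (must match the R side):
//   * images/activations: R array (H, W, C, N), column-major, HU floats
//   * conv weights: matrix (k*k*Cin) x Cout with row index
//       (dy + half) + k*(dx + half) + k*k*c          (dy/dx in [-half, half])
//     which is exactly an R array dim(k, k, Cin, Cout) flattened over the
//     first three dimensions.
//   * zero padding, stride 1, "same" output size; k is odd (1 or 3 here).
//
// The forward pass builds an im2col patch matrix in column-chunks so that a
// full 512x512 slice never materialises the whole (H*W) x (9*Cin) matrix;
// the chunked products are plain BLAS gemm calls.

#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col_cols(const double* x, int H, int W, int Cin, int k,
                        int j0, int j1, arma::mat& col) {
  // col: (H*(j1-j0)) x (k*k*Cin); rows are pixels of image columns [j0, j1)
  const int half = k / 2;
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int dx = -half; dx <= half; ++dx) {
      for (int dy = -half; dy <= half; ++dy) {
        const int cidx = (dy + half) + k * (dx + half) + k * k * c;
        double* dst = col.colptr(cidx);
        for (int j = j0; j < j1; ++j) {
          const int sj = j + dx;
          if (sj < 0 || sj >= W) continue;
          const double* src = xc + (std::size_t)sj * H;
          double* drow = dst + (std::size_t)(j - j0) * H;
          const int i_lo = std::max(0, -dy), i_hi = std::min(H, H - dy);
          for (int i = i_lo; i < i_hi; ++i) drow[i] = src[i + dy];
        }
      }
    }
  }
}

static void col2im_cols(const arma::mat& dcol, double* dx_out, int H, int W,
                        int Cin, int k, int j0, int j1) {
  // scatter-add transpose of im2col_cols
  const int half = k / 2;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx_out + (std::size_t)c * H * W;
    for (int dx = -half; dx <= half; ++dx) {
      for (int dy = -half; dy <= half; ++dy) {
        const int cidx = (dy + half) + k * (dx + half) + k * k * c;
        const double* src = dcol.colptr(cidx);
        for (int j = j0; j < j1; ++j) {
          const int sj = j + dx;
          if (sj < 0 || sj >= W) continue;
          double* dstcol = xc + (std::size_t)sj * H;
          const double* srow = src + (std::size_t)(j - j0) * H;
          const int i_lo = std::max(0, -dy), i_hi = std::min(H, H - dy);
          for (int i = i_lo; i < i_hi; ++i) dstcol[i + dy] += srow[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd", rng = false)]]
NumericVector conv_fwd(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                       NumericVector b, int k, int chunk_cols = 64) {
  const int H = dims[0], W = dims[1], Cin = dims[2], N = dims[3];
  const int Cout = Wm.ncol();
  if (Wm.nrow() != k * k * Cin) stop("weight matrix does not match k*k*Cin");
  if (b.size() != Cout) stop("bias length does not match Cout");

  NumericVector out((std::size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wa(const_cast<double*>(Wm.begin()), Wm.nrow(), Cout, false);
  const arma::rowvec ba(const_cast<double*>(b.begin()), Cout, false);

  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (std::size_t)n * H * W * Cin;
    double* os = out.begin() + (std::size_t)n * H * W * Cout;
    for (int j0 = 0; j0 < W; j0 += chunk_cols) {
      const int j1 = std::min(W, j0 + chunk_cols);
      arma::mat col(H * (j1 - j0), k * k * Cin);
      im2col_cols(xs, H, W, Cin, k, j0, j1, col);
      arma::mat y = col * Wa;
      y.each_row() += ba;
      // write rows into out pixels [j0*H, j1*H) of each output channel
      for (int co = 0; co < Cout; ++co) {
        double* dst = os + (std::size_t)co * H * W + (std::size_t)j0 * H;
        std::memcpy(dst, y.colptr(co), sizeof(double) * y.n_rows);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv_bwd", rng = false)]]
List conv_bwd(NumericVector x, IntegerVector dims, NumericMatrix Wm,
              NumericVector dy, int k, int chunk_cols = 64) {
  const int H = dims[0], W = dims[1], Cin = dims[2], N = dims[3];
  const int Cout = Wm.ncol();
  const arma::mat Wa(const_cast<double*>(Wm.begin()), Wm.nrow(), Cout, false);

  NumericVector dx((std::size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat dW(Wm.nrow(), Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);

  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (std::size_t)n * H * W * Cin;
    const double* gs = dy.begin() + (std::size_t)n * H * W * Cout;
    double* dxs = dx.begin() + (std::size_t)n * H * W * Cin;
    for (int j0 = 0; j0 < W; j0 += chunk_cols) {
      const int j1 = std::min(W, j0 + chunk_cols);
      const int rows = H * (j1 - j0);
      arma::mat gchunk(rows, Cout);
      for (int co = 0; co < Cout; ++co) {
        const double* src = gs + (std::size_t)co * H * W + (std::size_t)j0 * H;
        std::memcpy(gchunk.colptr(co), src, sizeof(double) * rows);
      }
      arma::mat col(rows, k * k * Cin);
      im2col_cols(xs, H, W, Cin, k, j0, j1, col);
      dW += col.t() * gchunk;
      db += arma::sum(gchunk, 0);
      arma::mat dcol = gchunk * Wa.t();
      col2im_cols(dcol, dxs, H, W, Cin, k, j0, j1);
    }
  }
  return List::create(Named("dx") = dx,
                      Named("dW") = NumericMatrix(wrap(dW)),
                      Named("db") = NumericVector(wrap(arma::vec(db.t()))));
}
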