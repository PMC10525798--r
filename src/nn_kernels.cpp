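// Low-level kernels for the hand-rolled network core.
//
// Feature-map batches are stored as (N*H*W) x C matrices: one column per
// channel, rows are pixels in sample-major, then column-major (row fastest)
// order, matching R's matrix layout per sample plane. 3x3 convolutions use
// im2col gathers driven by a precomputed 1-based index matrix into the
// zero-padded plane (built and cached on the R side), followed by one BLAS
// gemm. Backward passes recompute the gather instead of caching the column
// matrix, trading a little time for a lot of memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// zero-pad each sample plane by 1 pixel on all sides
// [[Rcpp::export]]
arma::mat nn_pad2(const arma::mat& X, int N, int H, int W) {
  const int Hp = H + 2, Wp = W + 2;
  mat Xp(static_cast<uword>(N) * Hp * Wp, X.n_cols, fill::zeros);
  for (uword c = 0; c < X.n_cols; ++c) {
    const double* src = X.colptr(c);
    double* dst = Xp.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < W; ++w)
        std::copy(src + (static_cast<size_t>(n) * W + w) * H,
                  src + (static_cast<size_t>(n) * W + w) * H + H,
                  dst + static_cast<size_t>(n) * Hp * Wp +
                      (w + 1) * static_cast<size_t>(Hp) + 1);
  }
  return Xp;
}

// drop the 1-pixel border again (adjoint of nn_pad2)
// [[Rcpp::export]]
arma::mat nn_unpad2(const arma::mat& Xp, int N, int H, int W) {
  const int Hp = H + 2, Wp = W + 2;
  mat X(static_cast<uword>(N) * H * W, Xp.n_cols);
  for (uword c = 0; c < Xp.n_cols; ++c) {
    const double* src = Xp.colptr(c);
    double* dst = X.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < W; ++w)
        std::copy(src + static_cast<size_t>(n) * Hp * Wp +
                      (w + 1) * static_cast<size_t>(Hp) + 1,
                  src + static_cast<size_t>(n) * Hp * Wp +
                      (w + 1) * static_cast<size_t>(Hp) + 1 + H,
                  dst + (static_cast<size_t>(n) * W + w) * H);
  }
  return X;
}

static mat im2col_gather(const mat& Xp, const imat& idx) {
  const uword R = idx.n_rows, C = Xp.n_cols, K = idx.n_cols;
  mat col(R, K * C);
  for (uword j = 0; j < K; ++j) {
    const sword* ip = idx.colptr(j);
    for (uword c = 0; c < C; ++c) {
      const double* src = Xp.colptr(c);
      double* dst = col.colptr(j * C + c);
      for (uword r = 0; r < R; ++r) dst[r] = src[ip[r] - 1];
    }
  }
  return col;
}

// out = im2col(Xp) * W ; W is (9*Cin) x Cout with taps ordered as idx cols
// [[Rcpp::export]]
arma::mat nn_conv3_fwd(const arma::mat& Xp, const arma::imat& idx,
                       const arma::mat& W) {
  return im2col_gather(Xp, idx) * W;
}

// backward of nn_conv3_fwd: returns dXp (padded), dW
// [[Rcpp::export]]
Rcpp::List nn_conv3_bwd(const arma::mat& Xp, const arma::imat& idx,
                        const arma::mat& W, const arma::mat& dout) {
  const uword C = Xp.n_cols, K = idx.n_cols;
  mat col = im2col_gather(Xp, idx);
  mat dW = col.t() * dout;
  mat dcol = dout * W.t();
  mat dXp(Xp.n_rows, C, fill::zeros);
  for (uword j = 0; j < K; ++j) {
    const sword* ip = idx.colptr(j);
    for (uword c = 0; c < C; ++c) {
      double* dst = dXp.colptr(c);
      const double* src = dcol.colptr(j * C + c);
      for (uword r = 0; r < idx.n_rows; ++r) dst[ip[r] - 1] += src[r];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dXp") = dXp,
                            Rcpp::Named("dW") = dW);
}

// 2x2 max pooling (stride 2); records the winning quadrant for backward
// [[Rcpp::export]]
Rcpp::List nn_maxpool_fwd(const arma::mat& X, int N, int H, int W) {
  const int Ho = H / 2, Wo = W / 2;
  const uword R = static_cast<uword>(N) * Ho * Wo, C = X.n_cols;
  mat out(R, C);
  imat which(R, C);
  for (uword c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    double* dst = out.colptr(c);
    sword* wh = which.colptr(c);
    uword o = 0;
    for (int n = 0; n < N; ++n) {
      const size_t base = static_cast<size_t>(n) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        const size_t col0 = base + static_cast<size_t>(2 * wo) * H;
        const size_t col1 = col0 + H;
        for (int ro = 0; ro < Ho; ++ro, ++o) {
          const size_t r0 = 2 * ro;
          double v[4] = {src[col0 + r0], src[col0 + r0 + 1],
                         src[col1 + r0], src[col1 + r0 + 1]};
          int best = 0;
          for (int k = 1; k < 4; ++k) if (v[k] > v[best]) best = k;
          dst[o] = v[best];
          wh[o] = best;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("which") = which);
}

// [[Rcpp::export]]
arma::mat nn_maxpool_bwd(const arma::mat& dout, const arma::imat& which,
                         int N, int H, int W) {
  const int Ho = H / 2, Wo = W / 2;
  const uword C = dout.n_cols;
  mat dX(static_cast<uword>(N) * H * W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const double* src = dout.colptr(c);
    const sword* wh = which.colptr(c);
    double* dst = dX.colptr(c);
    uword o = 0;
    for (int n = 0; n < N; ++n) {
      const size_t base = static_cast<size_t>(n) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        const size_t col0 = base + static_cast<size_t>(2 * wo) * H;
        for (int ro = 0; ro < Ho; ++ro, ++o) {
          const int k = static_cast<int>(wh[o]);
          const size_t off = col0 + (k >= 2 ? H : 0) + 2 * ro + (k & 1);
          dst[off] += src[o];
        }
      }
    }
  }
  return dX;
}

// nearest-neighbor 2x upsampling
// [[Rcpp::export]]
arma::mat nn_upsample_fwd(const arma::mat& X, int N, int H, int W) {
  const int Ho = 2 * H, Wo = 2 * W;
  const uword C = X.n_cols;
  mat out(static_cast<uword>(N) * Ho * Wo, C);
  for (uword c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    double* dst = out.colptr(c);
    for (int n = 0; n < N; ++n) {
      const size_t bi = static_cast<size_t>(n) * H * W;
      const size_t bo = static_cast<size_t>(n) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        const double* scol = src + bi + static_cast<size_t>(w / 2) * H;
        double* dcol = dst + bo + static_cast<size_t>(w) * Ho;
        for (int r = 0; r < Ho; ++r) dcol[r] = scol[r / 2];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat nn_upsample_bwd(const arma::mat& dout, int N, int H, int W) {
  const int Ho = 2 * H, Wo = 2 * W;
  const uword C = dout.n_cols;
  mat dX(static_cast<uword>(N) * H * W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const double* src = dout.colptr(c);
    double* dst = dX.colptr(c);
    for (int n = 0; n < N; ++n) {
      const size_t bi = static_cast<size_t>(n) * H * W;
      const size_t bo = static_cast<size_t>(n) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        double* dcol = dst + bi + static_cast<size_t>(w / 2) * H;
        const double* scol = src + bo + static_cast<size_t>(w) * Ho;
        for (int r = 0; r < Ho; ++r) dcol[r / 2] += scol[r];
      }
    }
  }
  return dX;
}
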