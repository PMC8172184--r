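// Dense kernels for the U-net segmenter. Feature maps are arma::mat with
// one row per pixel (column-major pixel index p = r + c*H, 0-based) and one
// column per channel. Convolutions are 3x3, stride 1, zero-padded "same";
// im2col + GEMM does the heavy lifting.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col3(const arma::mat& X, int H, int W) {
  const int C = X.n_cols;
  const int n = H * W;
  arma::mat XC(n, 9 * C, arma::fill::zeros);
  int o = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++o) {
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      for (int ch = 0; ch < C; ++ch) {
        const double* xs = X.colptr(ch);
        double* xd = XC.colptr(ch * 9 + o);
        for (int c = c0; c < c1; ++c) {
          const double* src = xs + (size_t)(c + dc) * H + (r0 + dr);
          double* dst = xd + (size_t)c * H + r0;
          std::memcpy(dst, src, sizeof(double) * (r1 - r0));
        }
      }
    }
  }
  return XC;
}

// [[Rcpp::export(name = ".conv3x3_forward")]]
arma::mat conv3x3_forward(const arma::mat& X, int H, int W,
                          const arma::mat& K, const arma::rowvec& b) {
  arma::mat Y = im2col3(X, H, W) * K;
  Y.each_row() += b;
  return Y;
}

// [[Rcpp::export(name = ".conv3x3_backward")]]
List conv3x3_backward(const arma::mat& X, int H, int W,
                      const arma::mat& K, const arma::mat& dY) {
  arma::mat XC = im2col3(X, H, W);
  arma::mat dK = XC.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dXC = dY * K.t();

  const int C = X.n_cols;
  arma::mat dX(X.n_rows, C, arma::fill::zeros);
  int o = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++o) {
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      for (int ch = 0; ch < C; ++ch) {
        const double* gs = dXC.colptr(ch * 9 + o);
        double* gd = dX.colptr(ch);
        for (int c = c0; c < c1; ++c) {
          const double* src = gs + (size_t)c * H + r0;
          double* dst = gd + (size_t)(c + dc) * H + (r0 + dr);
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dK"] = dK, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(const arma::mat& X, int H, int W) {
  const int C = X.n_cols, Ho = H / 2, Wo = W / 2;
  arma::mat Y(Ho * Wo, C);
  arma::imat idx(Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* xs = X.colptr(ch);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const int cand[4] = {
          2 * r + (2 * c) * H,     2 * r + 1 + (2 * c) * H,
          2 * r + (2 * c + 1) * H, 2 * r + 1 + (2 * c + 1) * H };
        int best = cand[0];
        for (int k = 1; k < 4; ++k) if (xs[cand[k]] > xs[best]) best = cand[k];
        Y(r + c * Ho, ch) = xs[best];
        idx(r + c * Ho, ch) = best;
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
arma::mat maxpool2_backward(const arma::mat& dY, const arma::imat& idx,
                            int H, int W) {
  const int C = dY.n_cols;
  arma::mat dX(H * W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    double* gd = dX.colptr(ch);
    const double* gs = dY.colptr(ch);
    const arma::sword* is = idx.colptr(ch);
    for (arma::uword p = 0; p < dY.n_rows; ++p) gd[is[p]] += gs[p];
  }
  return dX;
}

// [[Rcpp::export(name = ".upsample2_forward")]]
arma::mat upsample2_forward(const arma::mat& X, int H, int W) {
  const int C = X.n_cols, Ho = 2 * H, Wo = 2 * W;
  arma::mat Y(Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* xs = X.colptr(ch);
    double* yd = Y.colptr(ch);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r)
        yd[r + c * Ho] = xs[(r / 2) + (c / 2) * H];
  }
  return Y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
arma::mat upsample2_backward(const arma::mat& dY, int H, int W) {
  const int C = dY.n_cols, Ho = 2 * H;
  arma::mat dX(H * W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    double* gd = dX.colptr(ch);
    const double* gs = dY.colptr(ch);
    for (int c = 0; c < 2 * W; ++c)
      for (int r = 0; r < Ho; ++r)
        gd[(r / 2) + (c / 2) * H] += gs[r + c * Ho];
  }
  return dX;
}
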