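// Minimal im2col-based 2-D convolution kernels used by the tinycnn encoder.
// Activation layout is (C, H, W, N) column-major (channel fastest), matching
// the R arrays built in nn.R. Weights are (Cout x C*K*K) matrices with the
// column index running channel-fastest, then kernel row, then kernel column.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const double* x, int C, int H, int W, int N,
                        int K, int stride, int pad, int Ho, int Wo) {
  arma::mat cols(C * K * K, (std::size_t)Ho * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (std::size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        std::size_t col = (std::size_t)n * Ho * Wo + (std::size_t)wo * Ho + ho;
        double* dst = cols.colptr(col);
        for (int kw = 0; kw < K; ++kw) {
          int wi = wo * stride - pad + kw;
          for (int kh = 0; kh < K; ++kh) {
            int hi = ho * stride - pad + kh;
            double* d = dst + (std::size_t)(kw * K + kh) * C;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W) {
              const double* src = xn + (std::size_t)(wi * H + hi) * C;
              std::copy(src, src + C, d);
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv2d_forward")]]
List conv2d_forward(NumericVector x, IntegerVector xdim,
                    const arma::mat& w, const arma::vec& b,
                    int stride, int pad) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int K = (int)std::lround(std::sqrt((double)w.n_cols / C));
  int Ho = (H + 2 * pad - K) / stride + 1;
  int Wo = (W + 2 * pad - K) / stride + 1;
  arma::mat cols = im2col(REAL(x), C, H, W, N, K, stride, pad, Ho, Wo);
  arma::mat out = w * cols;            // (Cout x Ho*Wo*N)
  out.each_col() += b;
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create((int)w.n_rows, Ho, Wo, N);
  return List::create(_["out"] = res, _["cols"] = cols);
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector dout, IntegerVector xdim,
                     const arma::mat& w, const arma::mat& cols,
                     int stride, int pad) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int K = (int)std::lround(std::sqrt((double)w.n_cols / C));
  int Ho = (H + 2 * pad - K) / stride + 1;
  int Wo = (W + 2 * pad - K) / stride + 1;
  int Cout = (int)w.n_rows;
  arma::mat dmat(REAL(dout), Cout, (std::size_t)Ho * Wo * N, false, true);
  arma::mat dw = dmat * cols.t();
  arma::vec db = arma::sum(dmat, 1);
  arma::mat dcols = w.t() * dmat;      // (C*K*K x Ho*Wo*N)

  NumericVector dx((std::size_t)C * H * W * N);
  double* dxp = REAL(dx);
  for (int n = 0; n < N; ++n) {
    double* dxn = dxp + (std::size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        std::size_t col = (std::size_t)n * Ho * Wo + (std::size_t)wo * Ho + ho;
        const double* src = dcols.colptr(col);
        for (int kw = 0; kw < K; ++kw) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            double* d = dxn + (std::size_t)(wi * H + hi) * C;
            const double* s = src + (std::size_t)(kw * K + kh) * C;
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
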