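// Convolution arithmetic for the RFC-Net engine.
//
// Feature maps are stored as C x (H*W*N) matrices: one row per channel,
// spatial index p = col*H + row (column-major, 0-based), samples of a batch
// concatenated along columns. All kernels are 3x3 with padding 1; stride is
// 1 or 2. Convolutions are computed as im2col followed by a BLAS GEMM;
// transposed convolutions (upsampling) use the adjoint col2im.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int H, int stride) {
  // kernel 3, pad 1: stride 1 -> H, stride 2 -> H/2 (H even)
  return (H + 2 - 3) / stride + 1;
}

// Build the (9*C) x (Ho*Wo) patch matrix for sample n0. Patch row layout:
// kernel-tap-major with channels contiguous -- row index = k*C + c, with tap
// k = (dc+1)*3 + (dr+1) for offsets dr, dc in {-1, 0, 1}. Kernel matrices
// use the matching column order. Out-of-range taps are zero (padding).
// Channel contiguity makes the inner copy a memcpy over C doubles.
static arma::mat im2col_one(const arma::mat& X, int H, int W, int stride,
                            int n0) {
  const int C = X.n_rows;
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  arma::mat cols((size_t)C * 9, (size_t)Ho * Wo, arma::fill::zeros);
  const size_t off = (size_t)n0 * H * W;
  const double* xp = X.memptr();
  double* cp = cols.memptr();
  const size_t crows = (size_t)C * 9;
  for (int wc = 0; wc < Wo; ++wc) {
    const int c0 = wc * stride - 1;
    for (int wr = 0; wr < Ho; ++wr) {
      const size_t p = (size_t)wc * Ho + wr;
      const int r0 = wr * stride - 1;
      double* dst0 = cp + p * crows;
      for (int dc = 0; dc < 3; ++dc) {
        const int cc = c0 + dc;
        if (cc < 0 || cc >= W) continue;
        for (int dr = 0; dr < 3; ++dr) {
          const int rr = r0 + dr;
          if (rr < 0 || rr >= H) continue;
          const size_t src = off + (size_t)cc * H + rr;
          std::memcpy(dst0 + (size_t)(dc * 3 + dr) * C, xp + src * C,
                      sizeof(double) * C);
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add patch columns back onto the H x W grid.
static void col2im_one(const arma::mat& cols, arma::mat& X, int H, int W,
                       int stride, int n0) {
  const int C = X.n_rows;
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const size_t off = (size_t)n0 * H * W;
  double* xp = X.memptr();
  const double* cp = cols.memptr();
  const size_t crows = (size_t)C * 9;
  for (int wc = 0; wc < Wo; ++wc) {
    const int c0 = wc * stride - 1;
    for (int wr = 0; wr < Ho; ++wr) {
      const size_t p = (size_t)wc * Ho + wr;
      const int r0 = wr * stride - 1;
      const double* src0 = cp + p * crows;
      for (int dc = 0; dc < 3; ++dc) {
        const int cc = c0 + dc;
        if (cc < 0 || cc >= W) continue;
        for (int dr = 0; dr < 3; ++dr) {
          const int rr = r0 + dr;
          if (rr < 0 || rr >= H) continue;
          double* dst = xp + (off + (size_t)cc * H + rr) * C;
          const double* s = src0 + (size_t)(dc * 3 + dr) * C;
          for (int c = 0; c < C; ++c) dst[c] += s[c];
        }
      }
    }
  }
}

// Forward 3x3 convolution. X: Cin x (H*W*N); Wt: Cout x (Cin*9).
// Returns Cout x (Ho*Wo*N).
// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericMatrix cpp_conv_fwd(const NumericMatrix& X, const NumericMatrix& Wt,
                           int H, int W, int N, int stride) {
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const arma::mat Xv(const_cast<double*>(X.begin()), X.nrow(), X.ncol(), false);
  const arma::mat Wv(const_cast<double*>(Wt.begin()), Wt.nrow(), Wt.ncol(), false);
  NumericMatrix Y(Wt.nrow(), (R_xlen_t)Ho * Wo * N);
  arma::mat Yv(Y.begin(), Y.nrow(), Y.ncol(), false);
  for (int n = 0; n < N; ++n) {
    arma::mat cols = im2col_one(Xv, H, W, stride, n);
    Yv.cols((size_t)n * Ho * Wo, (size_t)(n + 1) * Ho * Wo - 1) = Wv * cols;
  }
  return Y;
}

// Backward pass of the 3x3 convolution: gradients w.r.t. input and kernel.
// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(const NumericMatrix& X, const NumericMatrix& dY,
                  const NumericMatrix& Wt, int H, int W, int N, int stride) {
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const arma::mat Xv(const_cast<double*>(X.begin()), X.nrow(), X.ncol(), false);
  const arma::mat dYv(const_cast<double*>(dY.begin()), dY.nrow(), dY.ncol(), false);
  const arma::mat Wv(const_cast<double*>(Wt.begin()), Wt.nrow(), Wt.ncol(), false);
  NumericMatrix dX(X.nrow(), X.ncol());
  NumericMatrix dW(Wt.nrow(), Wt.ncol());
  arma::mat dXv(dX.begin(), dX.nrow(), dX.ncol(), false);
  arma::mat dWv(dW.begin(), dW.nrow(), dW.ncol(), false);
  for (int n = 0; n < N; ++n) {
    arma::mat dYn = dYv.cols((size_t)n * Ho * Wo, (size_t)(n + 1) * Ho * Wo - 1);
    arma::mat cols = im2col_one(Xv, H, W, stride, n);
    dWv += dYn * cols.t();
    arma::mat dcols = Wv.t() * dYn;
    col2im_one(dcols, dXv, H, W, stride, n);
  }
  return List::create(Named("dx") = dX, Named("dw") = dW);
}

// Transposed convolution (stride-2 3x3 upsampling, output 2H x 2W).
// X: Cin x (h*w*N); Wt: Cin x (Cout*9). Returns Cout x (2h*2w*N).
// [[Rcpp::export(name = ".cpp_deconv_fwd")]]
NumericMatrix cpp_deconv_fwd(const NumericMatrix& X, const NumericMatrix& Wt,
                             int h, int w, int N) {
  const int H = 2 * h, W = 2 * w;
  const int Cout = Wt.ncol() / 9;
  const arma::mat Xv(const_cast<double*>(X.begin()), X.nrow(), X.ncol(), false);
  const arma::mat Wv(const_cast<double*>(Wt.begin()), Wt.nrow(), Wt.ncol(), false);
  NumericMatrix Y(Cout, (R_xlen_t)H * W * N);
  arma::mat Yv(Y.begin(), Y.nrow(), Y.ncol(), false);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn = Xv.cols((size_t)n * h * w, (size_t)(n + 1) * h * w - 1);
    arma::mat dcols = Wv.t() * Xn;  // (Cout*9) x (h*w)
    col2im_one(dcols, Yv, H, W, 2, n);
  }
  return Y;
}

// Backward pass of the transposed convolution.
// [[Rcpp::export(name = ".cpp_deconv_bwd")]]
List cpp_deconv_bwd(const NumericMatrix& X, const NumericMatrix& dY,
                    const NumericMatrix& Wt, int h, int w, int N) {
  const int H = 2 * h, W = 2 * w;
  const arma::mat Xv(const_cast<double*>(X.begin()), X.nrow(), X.ncol(), false);
  const arma::mat dYv(const_cast<double*>(dY.begin()), dY.nrow(), dY.ncol(), false);
  const arma::mat Wv(const_cast<double*>(Wt.begin()), Wt.nrow(), Wt.ncol(), false);
  NumericMatrix dX(X.nrow(), X.ncol());
  NumericMatrix dW(Wt.nrow(), Wt.ncol());
  arma::mat dXv(dX.begin(), dX.nrow(), dX.ncol(), false);
  arma::mat dWv(dW.begin(), dW.nrow(), dW.ncol(), false);
  for (int n = 0; n < N; ++n) {
    arma::mat cols = im2col_one(dYv, H, W, 2, n);  // (Cout*9) x (h*w)
    arma::mat Xn = Xv.cols((size_t)n * h * w, (size_t)(n + 1) * h * w - 1);
    dXv.cols((size_t)n * h * w, (size_t)(n + 1) * h * w - 1) = Wv * cols;
    dWv += Xn * cols.t();
  }
  return List::create(Named("dx") = dX, Named("dw") = dW);
}

// Sample a single-channel image at fractional (row, col) positions
// (0-based, pixel centres on integers). method 0 = bilinear, 1 = nearest.
// Queries outside the image return `fill`.
// [[Rcpp::export(name = ".cpp_warp_sample")]]
NumericVector cpp_warp_sample(const NumericMatrix& src,
                              const NumericVector& qr, const NumericVector& qc,
                              int method, double fill) {
  const int H = src.nrow(), W = src.ncol();
  const R_xlen_t n = qr.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double r = qr[i], c = qc[i];
    if (method == 1) {
      const int ri = (int)std::lround(r), ci = (int)std::lround(c);
      out[i] = (ri < 0 || ri >= H || ci < 0 || ci >= W) ? fill : src(ri, ci);
    } else {
      if (r < -0.5 || r > H - 0.5 || c < -0.5 || c > W - 0.5) {
        out[i] = fill;
        continue;
      }
      const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
      const double fr = r - r0, fc = c - c0;
      auto at = [&](int rr, int cc) -> double {
        if (rr < 0) rr = 0;
        if (rr >= H) rr = H - 1;
        if (cc < 0) cc = 0;
        if (cc >= W) cc = W - 1;
        return src(rr, cc);
      };
      out[i] = (1 - fr) * (1 - fc) * at(r0, c0) + fr * (1 - fc) * at(r0 + 1, c0) +
               (1 - fr) * fc * at(r0, c0 + 1) + fr * fc * at(r0 + 1, c0 + 1);
    }
  }
  return out;
}

// Fused batch-norm (+ optional ReLU) forward, training mode: per-row batch
// statistics. Returns out, xhat, and the per-row mean / std (with eps).
// [[Rcpp::export(name = ".cpp_bn_relu_train")]]
List cpp_bn_relu_train(const NumericMatrix& z, const NumericVector& gamma,
                       const NumericVector& beta, double eps, bool relu) {
  const int C = z.nrow();
  const R_xlen_t M = z.ncol();
  NumericVector mu(C), sd(C);
  NumericMatrix xhat(C, M), out(C, M);
  const double* zp = z.begin();
  for (R_xlen_t j = 0; j < M; ++j)
    for (int c = 0; c < C; ++c) mu[c] += zp[j * C + c];
  for (int c = 0; c < C; ++c) mu[c] /= M;
  for (R_xlen_t j = 0; j < M; ++j)
    for (int c = 0; c < C; ++c) {
      const double d = zp[j * C + c] - mu[c];
      sd[c] += d * d;
    }
  for (int c = 0; c < C; ++c) sd[c] = std::sqrt(sd[c] / M + eps);
  double* xp = xhat.begin();
  double* op = out.begin();
  for (R_xlen_t j = 0; j < M; ++j)
    for (int c = 0; c < C; ++c) {
      const double xh = (zp[j * C + c] - mu[c]) / sd[c];
      xp[j * C + c] = xh;
      double o = gamma[c] * xh + beta[c];
      if (relu && o < 0) o = 0;
      op[j * C + c] = o;
    }
  return List::create(Named("out") = out, Named("xhat") = xhat,
                      Named("mu") = mu, Named("sd") = sd);
}

// Fused batch-norm (+ optional ReLU) forward with fixed running statistics.
// [[Rcpp::export(name = ".cpp_bn_relu_eval")]]
NumericMatrix cpp_bn_relu_eval(const NumericMatrix& z,
                               const NumericVector& gamma,
                               const NumericVector& beta,
                               const NumericVector& rmean,
                               const NumericVector& rvar, double eps,
                               bool relu) {
  const int C = z.nrow();
  const R_xlen_t M = z.ncol();
  NumericMatrix out(C, M);
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    const double sd = std::sqrt(rvar[c] + eps);
    a[c] = gamma[c] / sd;
    b[c] = beta[c] - gamma[c] * rmean[c] / sd;
  }
  const double* zp = z.begin();
  double* op = out.begin();
  for (R_xlen_t j = 0; j < M; ++j)
    for (int c = 0; c < C; ++c) {
      double o = a[c] * zp[j * C + c] + b[c];
      if (relu && o < 0) o = 0;
      op[j * C + c] = o;
    }
  return out;
}

// Fused ReLU + batch-norm backward. `out` is the forward output (used for
// the ReLU mask when relu = true).
// [[Rcpp::export(name = ".cpp_bn_relu_bwd")]]
List cpp_bn_relu_bwd(const NumericMatrix& dy, const NumericMatrix& out,
                     const NumericMatrix& xhat, const NumericVector& gamma,
                     const NumericVector& sd, bool relu) {
  const int C = dy.nrow();
  const R_xlen_t M = dy.ncol();
  NumericVector s1(C), s2(C);
  const double* dp = dy.begin();
  const double* op = out.begin();
  const double* xp = xhat.begin();
  for (R_xlen_t j = 0; j < M; ++j)
    for (int c = 0; c < C; ++c) {
      double g = dp[j * C + c];
      if (relu && op[j * C + c] <= 0) g = 0;
      s1[c] += g;
      s2[c] += g * xp[j * C + c];
    }
  NumericMatrix dx(C, M);
  std::vector<double> a(C), b1(C), b2(C);
  for (int c = 0; c < C; ++c) {
    a[c] = gamma[c] / sd[c];
    b1[c] = s1[c] / M;
    b2[c] = s2[c] / M;
  }
  double* qp = dx.begin();
  for (R_xlen_t j = 0; j < M; ++j)
    for (int c = 0; c < C; ++c) {
      double g = dp[j * C + c];
      if (relu && op[j * C + c] <= 0) g = 0;
      qp[j * C + c] = a[c] * (g - b1[c] - xp[j * C + c] * b2[c]);
    }
  return List::create(Named("dx") = dx, Named("dgamma") = s2,
                      Named("dbeta") = s1);
}

// Attach the (h, w, n) tensor-dimension attribute in place (the caller owns
// the freshly allocated matrix, so no copy is needed).
// [[Rcpp::export(name = ".cpp_set_td")]]
SEXP cpp_set_td(SEXP m, SEXP td) {
  Rf_setAttrib(m, Rf_install("td"), td);
  return m;
}
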