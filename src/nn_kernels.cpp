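// Low-level kernels for the convolutional graph engine.
// Feature maps are dense arrays with dim (H, W, C), column-major, doubles.
// The im2col buffer uses layout (N x k*k*C) with N = Ho*Wo, so that the
// forward GEMM  y = col * W  writes the output cube's memory directly
// (slice c of the output == column c of the product) and column copies in
// im2col/col2im are contiguous along the image's fastest (row) dimension.
// Convolution weights are (k*k*C_in, C_out) with row index
// r = c_in*k*k + kx*k + ky.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".cc_im2col")]]
arma::mat cc_im2col(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  arma::mat col((arma::uword)Ho * Wo, (arma::uword)k * k * C,
                arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int r = c * k * k + kx * k + ky;
        double* dst = col.colptr(r);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kx;
          if (j < 0 || j >= W) continue;
          const double* xcol = xs + (arma::uword)j * H;
          double* d = dst + (arma::uword)oj * Ho;
          if (stride == 1) {
            const int i0 = -pad + ky;             // input row of oi = 0
            const int lo = std::max(0, -i0);      // first valid oi
            const int hi = std::min(Ho, H - i0);  // one past last valid oi
            if (hi > lo)
              std::memcpy(d + lo, xcol + i0 + lo,
                          (size_t)(hi - lo) * sizeof(double));
          } else {
            for (int oi = 0; oi < Ho; ++oi) {
              const int i = oi * stride - pad + ky;
              if (i >= 0 && i < H) d[oi] = xcol[i];
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".cc_col2im")]]
arma::cube cc_col2im(const arma::mat& col, int H, int W, int C,
                     int k, int stride, int pad) {
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xs = x.slice_memptr(c);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int r = c * k * k + kx * k + ky;
        const double* src = col.colptr(r);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kx;
          if (j < 0 || j >= W) continue;
          double* xcol = xs + (arma::uword)j * H;
          const double* s = src + (arma::uword)oj * Ho;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + ky;
            if (i >= 0 && i < H) xcol[i] += s[oi];
          }
        }
      }
    }
  }
  return x;
}

// Forward convolution (optionally fused ReLU); caches the im2col matrix for
// the backward pass when requested.
// [[Rcpp::export(name = ".cc_conv_forward")]]
List cc_conv_forward(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b, int k, int stride, int pad,
                     bool keep_col, bool relu) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(Wd, k, stride, pad);
  const int Cout = W.n_cols;
  arma::mat col = cc_im2col(x, k, stride, pad);
  arma::cube y(Ho, Wo, Cout);
  arma::mat ym(y.memptr(), (arma::uword)Ho * Wo, Cout, false, true);
  ym = col * W;
  ym.each_row() += b.t();
  if (relu) y.transform([](double v) { return v > 0 ? v : 0.0; });
  if (keep_col)
    return List::create(_["y"] = y, _["col"] = col);
  return List::create(_["y"] = y);
}

// [[Rcpp::export(name = ".cc_conv_backward")]]
List cc_conv_backward(const arma::cube& dy, const arma::mat& col,
                      const arma::mat& W, int H, int Win, int Cin,
                      int k, int stride, int pad, bool need_dx) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  const arma::mat dym(const_cast<double*>(dy.memptr()),
                      (arma::uword)Ho * Wo, Cout, false, true);
  arma::mat dW = col.t() * dym;
  arma::vec db = arma::sum(dym, 0).t();
  if (!need_dx)
    return List::create(_["dW"] = dW, _["db"] = db);
  arma::mat dcol = dym * W.t();
  arma::cube dx = cc_col2im(dcol, H, Win, Cin, k, stride, pad);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Separable max pooling (window k, stride `stride`, symmetric zero pad):
// a vertical then a horizontal max pass, each O(k) per cell, tracking the
// argmax (1-based linear index into x) for the backward scatter.
// [[Rcpp::export(name = ".cc_maxpool_forward")]]
List cc_maxpool_forward(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<double> vmax((size_t)Ho * W);
  std::vector<int> varg((size_t)Ho * W);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    // vertical pass: for each column j, max over rows in the window
    for (int j = 0; j < W; ++j) {
      const double* xcol = xs + (arma::uword)j * H;
      for (int oi = 0; oi < Ho; ++oi) {
        const int lo = std::max(0, oi * stride - pad);
        const int hi = std::min(H - 1, oi * stride - pad + k - 1);
        double best = NEG; int bi = -1;
        for (int i = lo; i <= hi; ++i)
          if (xcol[i] > best) { best = xcol[i]; bi = i; }
        vmax[(size_t)j * Ho + oi] = best;
        varg[(size_t)j * Ho + oi] = bi;
      }
    }
    // horizontal pass
    for (int oj = 0; oj < Wo; ++oj) {
      const int lo = std::max(0, oj * stride - pad);
      const int hi = std::min(W - 1, oj * stride - pad + k - 1);
      for (int oi = 0; oi < Ho; ++oi) {
        double best = NEG; int bj = -1;
        for (int j = lo; j <= hi; ++j) {
          const double v = vmax[(size_t)j * Ho + oi];
          if (v > best) { best = v; bj = j; }
        }
        y(oi, oj, c) = (bj < 0) ? 0.0 : best;
        idx(oi, oj, c) = (bj < 0) ? 1 :
          (arma::uword)c * H * W + (arma::uword)bj * H +
          varg[(size_t)bj * Ho + oi] + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cc_maxpool_backward")]]
arma::cube cc_maxpool_backward(const arma::cube& dy, const arma::ucube& idx,
                               int H, int W, int C) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  const arma::uword n = dy.n_elem;
  for (arma::uword t = 0; t < n; ++t)
    dx(idx(t) - 1) += dy(t);
  return dx;
}

// [[Rcpp::export(name = ".cc_upsample2_forward")]]
arma::cube cc_upsample2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j) {
      const double* xcol = x.slice_memptr(c) + (arma::uword)j * H;
      double* y0 = y.slice_memptr(c) + (arma::uword)(2 * j) * 2 * H;
      double* y1 = y0 + 2 * H;
      for (int i = 0; i < H; ++i) {
        y0[2 * i] = y0[2 * i + 1] = xcol[i];
        y1[2 * i] = y1[2 * i + 1] = xcol[i];
      }
    }
  return y;
}

// [[Rcpp::export(name = ".cc_upsample2_backward")]]
arma::cube cc_upsample2_backward(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j) {
      const double* d0 = dy.slice_memptr(c) + (arma::uword)(2 * j) * 2 * H;
      const double* d1 = d0 + 2 * H;
      double* xcol = dx.slice_memptr(c) + (arma::uword)j * H;
      for (int i = 0; i < H; ++i)
        xcol[i] = d0[2 * i] + d0[2 * i + 1] + d1[2 * i] + d1[2 * i + 1];
    }
  return dx;
}

// ReLU backward helper: dy masked by (y > 0), in C++ to avoid two R copies.
// [[Rcpp::export(name = ".cc_relu_backward")]]
arma::cube cc_relu_backward(const arma::cube& dy, const arma::cube& y) {
  arma::cube dx = dy;
  const arma::uword n = dx.n_elem;
  const double* yp = y.memptr();
  double* dp = dx.memptr();
  for (arma::uword t = 0; t < n; ++t)
    if (yp[t] <= 0) dp[t] = 0;
  return dx;
}
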