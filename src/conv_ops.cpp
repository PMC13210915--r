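// Low-level dense tensor kernels for the network stack.
//
// Tensor layout throughout: column-major R arrays dim = (H, W, C, N).
// Convolution weights: dim = (K, K, Cin/groups, Cout).
// All kernels are im2col/col2im + BLAS GEMM via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int H, int K, int stride, int pad, int dil) {
  return (H + 2 * pad - dil * (K - 1) - 1) / stride + 1;
}

// Gather one sample's group-slice into a (K*K*cg) x (Ho*Wo) matrix.
static void im2col(const double* x, int H, int W, int c0, int cg,
                   int K, int stride, int pad, int dil, arma::mat& col) {
  const int Ho = out_size(H, K, stride, pad, dil);
  const int Wo = out_size(W, K, stride, pad, dil);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int cidx = ho + Ho * wo;
      double* dst = col.colptr(cidx);
      for (int ci = 0; ci < cg; ++ci) {
        const double* plane = x + (size_t)(c0 + ci) * H * W;
        for (int kw = 0; kw < K; ++kw) {
          const int w_in = wo * stride - pad + dil * kw;
          for (int kh = 0; kh < K; ++kh) {
            const int h_in = ho * stride - pad + dil * kh;
            double v = 0.0;
            if (h_in >= 0 && h_in < H && w_in >= 0 && w_in < W)
              v = plane[h_in + (size_t)H * w_in];
            dst[kh + K * kw + K * K * ci] = v;
          }
        }
      }
    }
  }
}

// Scatter-add a column matrix back to the input plane (adjoint of im2col).
static void col2im(const arma::mat& col, double* gx, int H, int W, int c0, int cg,
                   int K, int stride, int pad, int dil) {
  const int Ho = out_size(H, K, stride, pad, dil);
  const int Wo = out_size(W, K, stride, pad, dil);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int cidx = ho + Ho * wo;
      const double* src = col.colptr(cidx);
      for (int ci = 0; ci < cg; ++ci) {
        double* plane = gx + (size_t)(c0 + ci) * H * W;
        for (int kw = 0; kw < K; ++kw) {
          const int w_in = wo * stride - pad + dil * kw;
          if (w_in < 0 || w_in >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            const int h_in = ho * stride - pad + dil * kh;
            if (h_in < 0 || h_in >= H) continue;
            plane[h_in + (size_t)H * w_in] += src[kh + K * kw + K * K * ci];
          }
        }
      }
    }
  }
}

// Direct depthwise convolution (cg_in == 1, one output channel per group,
// stride 1): y[c] = x[c] * w[c], looped over kernel taps without im2col.
static void depthwise_fwd(const double* x, const double* w, double* y,
                          int H, int W, int C, int N, int K, int pad, int dil) {
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x + ((size_t)n * C + c) * H * W;
      double* ys = y + ((size_t)n * C + c) * H * W;
      std::fill(ys, ys + (size_t)H * W, 0.0);
      for (int kw = 0; kw < K; ++kw) {
        for (int kh = 0; kh < K; ++kh) {
          const double wv = w[kh + K * kw + K * K * c];
          const int dh = dil * kh - pad, dw = dil * kw - pad;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          for (int wj = w0; wj < w1; ++wj) {
            const double* xr = xs + (size_t)(wj + dw) * H + dh;
            double* yr = ys + (size_t)wj * H;
            for (int hi = h0; hi < h1; ++hi) yr[hi] += wv * xr[hi];
          }
        }
      }
    }
  }
}

// Shift-GEMM path for K=3, stride 1, pad 1, dil 1, groups 1: for each of the
// nine taps, one GEMM over the flat (H*W x C) matrix with a row offset, then
// subtraction of the rows that wrongly wrapped across column (image) borders.
// mode 0: fwd (Y += Xshift * Wtap), 1: bwd input (GX_shift += GY * Wtap'),
// 2: bwd weight (GWtap += Xshift' * GY).
static void conv3x3_tapgemm(const double* xp, const double* gp, double* op,
                            double* wgrad, const double* w,
                            int H, int W, int C, int Cout, int N, int mode) {
  const int HW = H * W;
  // per-tap weight slices and geometry, hoisted out of the sample loop so a
  // sample's X and Y stay cache-resident across all nine taps
  arma::mat Wtap[9];
  arma::mat GWtap[9];
  int offs[9], r0s[9], r1s[9], hbads[9];
  for (int kw = 0; kw < 3; ++kw) {
    for (int kh = 0; kh < 3; ++kh) {
      const int t = kh + 3 * kw;
      const int dh = kh - 1, dw = kw - 1;
      offs[t] = dh + H * dw;
      r0s[t] = std::max(0, -offs[t]);
      r1s[t] = HW - 1 - std::max(0, offs[t]);
      hbads[t] = (dh < 0) ? 0 : (dh > 0 ? H - 1 : -1);
      if (mode != 2) {
        Wtap[t].set_size(C, Cout);
        for (int ci = 0; ci < C; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wtap[t](ci, co) = w[kh + 3 * kw + 9 * ci + 9 * C * co];
      } else GWtap[t].zeros(C, Cout);
    }
  }
  for (int n = 0; n < N; ++n) {
    const arma::mat X(const_cast<double*>(xp) + (size_t)n * HW * C, HW, C, false, true);
    for (int t = 0; t < 9; ++t) {
      const int off = offs[t], r0 = r0s[t], r1 = r1s[t], hbad = hbads[t];
      if (r1 < r0) continue;
      if (mode == 0) {
        arma::mat Y(op + (size_t)n * HW * Cout, HW, Cout, false, true);
        Y.rows(r0, r1) += X.rows(r0 + off, r1 + off) * Wtap[t];
        if (hbad >= 0)
          for (int wj = 0; wj < W; ++wj) {
            const int r = H * wj + hbad;
            if (r >= r0 && r <= r1) Y.row(r) -= X.row(r + off) * Wtap[t];
          }
      } else if (mode == 1) {
        const arma::mat GY(const_cast<double*>(gp) + (size_t)n * HW * Cout, HW, Cout, false, true);
        arma::mat GX(op + (size_t)n * HW * C, HW, C, false, true);
        GX.rows(r0 + off, r1 + off) += GY.rows(r0, r1) * Wtap[t].t();
        if (hbad >= 0)
          for (int wj = 0; wj < W; ++wj) {
            const int r = H * wj + hbad;
            if (r >= r0 && r <= r1) GX.row(r + off) -= GY.row(r) * Wtap[t].t();
          }
      } else {
        const arma::mat GY(const_cast<double*>(gp) + (size_t)n * HW * Cout, HW, Cout, false, true);
        GWtap[t] += X.rows(r0 + off, r1 + off).t() * GY.rows(r0, r1);
        if (hbad >= 0)
          for (int wj = 0; wj < W; ++wj) {
            const int r = H * wj + hbad;
            if (r >= r0 && r <= r1) GWtap[t] -= X.row(r + off).t() * GY.row(r);
          }
      }
    }
  }
  if (mode == 2)
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh) {
        const int t = kh + 3 * kw;
        for (int ci = 0; ci < C; ++ci)
          for (int co = 0; co < Cout; ++co)
            wgrad[kh + 3 * kw + 9 * ci + 9 * C * co] += GWtap[t](ci, co);
      }
}

static inline bool is_conv3_fast(int K, int stride, int pad, int dil, int groups) {
  return K == 3 && stride == 1 && pad == 1 && dil == 1 && groups == 1;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                             int stride, int pad, int dil, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], cg_in = wd[2], Cout = wd[3];
  if (C != cg_in * groups) stop("conv2d: channel/group mismatch");
  const int cg_out = Cout / groups;
  const int Ho = out_size(H, K, stride, pad, dil);
  const int Wo = out_size(W, K, stride, pad, dil);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  if (cg_in == 1 && cg_out == 1 && stride == 1 && !bias.isNotNull() &&
      Ho == H && Wo == W) {
    depthwise_fwd(x.begin(), w.begin(), y.begin(), H, W, C, N, K, pad, dil);
    return y;
  }
  if (is_conv3_fast(K, stride, pad, dil, groups)) {
    if (bias.isNotNull()) {
      NumericVector b(bias);
      for (int n = 0; n < N; ++n)
        for (int co = 0; co < Cout; ++co)
          std::fill(y.begin() + ((size_t)n * Cout + co) * Ho * Wo,
                    y.begin() + ((size_t)n * Cout + co + 1) * Ho * Wo, b[co]);
    } else std::fill(y.begin(), y.end(), 0.0);
    conv3x3_tapgemm(x.begin(), nullptr, y.begin(), nullptr, w.begin(),
                    H, W, C, Cout, N, 0);
    return y;
  }
  const double* xp = x.begin();
  double* yp = y.begin();
  const bool fast1x1 = (K == 1 && stride == 1 && pad == 0);
  arma::mat col(fast1x1 ? 1 : K * K * cg_in, fast1x1 ? 1 : Ho * Wo);
  const arma::mat Wall(const_cast<double*>(w.begin()), K * K * cg_in, Cout, false, true);
  const double* bp = bias.isNotNull() ? NumericVector(bias).begin() : nullptr;
  for (int n = 0; n < N; ++n) {
    const double* xs = xp + (size_t)n * H * W * C;
    double* ys = yp + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      arma::mat Wg = Wall.cols(g * cg_out, (g + 1) * cg_out - 1);
      arma::mat Y(ys + (size_t)g * cg_out * Ho * Wo, Ho * Wo, cg_out, false, true);
      if (fast1x1) {
        const arma::mat X(const_cast<double*>(xs) + (size_t)g * cg_in * H * W,
                          H * W, cg_in, false, true);
        Y = X * Wg;
      } else {
        im2col(xs, H, W, g * cg_in, cg_in, K, stride, pad, dil, col);
        Y = col.t() * Wg;
      }
      if (bp) {
        for (int co = 0; co < cg_out; ++co)
          Y.col(co) += bp[g * cg_out + co];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector conv2d_bwd_input_cpp(NumericVector gy, NumericVector w,
                                   int H, int W, int stride, int pad, int dil, int groups) {
  IntegerVector gd = gy.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2], N = gd[3];
  const int K = wd[0], cg_in = wd[2];
  const int C = cg_in * groups, cg_out = Cout / groups;
  if (out_size(H, K, stride, pad, dil) != Ho || out_size(W, K, stride, pad, dil) != Wo)
    stop("conv2d_bwd_input: geometry mismatch");
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  if (cg_in == 1 && Cout == C && stride == 1 && groups == C &&
      Ho == H && Wo == W) {
    // depthwise adjoint: gx[h+dh, w+dw, c] += w[k,c] * gy[h, w, c]
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        const double* gs = gy.begin() + ((size_t)n * C + c) * Ho * Wo;
        double* xs = gx.begin() + ((size_t)n * C + c) * H * W;
        for (int kw = 0; kw < K; ++kw) {
          for (int kh = 0; kh < K; ++kh) {
            const double wv = w[kh + K * kw + K * K * c];
            const int dh = dil * kh - pad, dw = dil * kw - pad;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
            for (int wj = w0; wj < w1; ++wj) {
              const double* gr = gs + (size_t)wj * H;
              double* xr = xs + (size_t)(wj + dw) * H + dh;
              for (int hi = h0; hi < h1; ++hi) xr[hi] += wv * gr[hi];
            }
          }
        }
      }
    }
    return gx;
  }
  if (is_conv3_fast(K, stride, pad, dil, groups)) {
    conv3x3_tapgemm(gx.begin(), gy.begin(), gx.begin(), nullptr, w.begin(),
                    H, W, C, Cout, N, 1);
    return gx;
  }
  const arma::mat Wall(const_cast<double*>(w.begin()), K * K * cg_in, Cout, false, true);
  const bool fast1x1 = (K == 1 && stride == 1 && pad == 0);
  arma::mat colg(fast1x1 ? 1 : K * K * cg_in, fast1x1 ? 1 : Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* gys = gy.begin() + (size_t)n * Ho * Wo * Cout;
    double* gxs = gx.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      const arma::mat GY(const_cast<double*>(gys) + (size_t)g * cg_out * Ho * Wo,
                         Ho * Wo, cg_out, false, true);
      arma::mat Wg = Wall.cols(g * cg_out, (g + 1) * cg_out - 1);
      if (fast1x1) {
        arma::mat GX(gxs + (size_t)g * cg_in * H * W, H * W, cg_in, false, true);
        GX = GY * Wg.t();
      } else {
        colg = Wg * GY.t();
        col2im(colg, gxs, H, W, g * cg_in, cg_in, K, stride, pad, dil);
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector conv2d_bwd_weight_cpp(NumericVector x, NumericVector gy,
                                    int K, int stride, int pad, int dil, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2];
  const int cg_in = C / groups, cg_out = Cout / groups;
  NumericVector gw(Rf_allocVector(REALSXP, (R_xlen_t)K * K * cg_in * Cout));
  std::fill(gw.begin(), gw.end(), 0.0);
  gw.attr("dim") = IntegerVector::create(K, K, cg_in, Cout);
  if (cg_in == 1 && Cout == C && stride == 1 && groups == C &&
      Ho == H && Wo == W) {
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        const double* xs = x.begin() + ((size_t)n * C + c) * H * W;
        const double* gs = gy.begin() + ((size_t)n * C + c) * Ho * Wo;
        for (int kw = 0; kw < K; ++kw) {
          for (int kh = 0; kh < K; ++kh) {
            const int dh = dil * kh - pad, dw = dil * kw - pad;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
            double acc = 0;
            for (int wj = w0; wj < w1; ++wj) {
              const double* xr = xs + (size_t)(wj + dw) * H + dh;
              const double* gr = gs + (size_t)wj * H;
              for (int hi = h0; hi < h1; ++hi) acc += xr[hi] * gr[hi];
            }
            gw[kh + K * kw + K * K * c] += acc;
          }
        }
      }
    }
    return gw;
  }
  if (is_conv3_fast(K, stride, pad, dil, groups)) {
    conv3x3_tapgemm(x.begin(), gy.begin(), nullptr, gw.begin(), nullptr,
                    H, W, C, Cout, N, 2);
    return gw;
  }
  arma::mat GW(gw.begin(), K * K * cg_in, Cout, false, true);
  const bool fast1x1 = (K == 1 && stride == 1 && pad == 0);
  arma::mat col(fast1x1 ? 1 : K * K * cg_in, fast1x1 ? 1 : Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    const double* gys = gy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      const arma::mat GY(const_cast<double*>(gys) + (size_t)g * cg_out * Ho * Wo,
                         Ho * Wo, cg_out, false, true);
      if (fast1x1) {
        const arma::mat X(const_cast<double*>(xs) + (size_t)g * cg_in * H * W,
                          H * W, cg_in, false, true);
        GW.cols(g * cg_out, (g + 1) * cg_out - 1) += X.t() * GY;
      } else {
        im2col(xs, H, W, g * cg_in, cg_in, K, stride, pad, dil, col);
        GW.cols(g * cg_out, (g + 1) * cg_out - 1) += col * GY;
      }
    }
  }
  return gw;
}

// 2x2 stride-2 max pooling; also returns flat argmax (0-based, within sample plane).
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  IntegerVector arg(Rf_allocVector(INTSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + ((size_t)n * C + c) * H * W;
      double* yp = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      int* ap = arg.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int best = 2 * ho + (size_t)H * (2 * wo);
          double bv = plane[best];
          const int cand[3] = {2 * ho + 1 + H * (2 * wo), 2 * ho + H * (2 * wo + 1),
                               2 * ho + 1 + H * (2 * wo + 1)};
          for (int k = 0; k < 3; ++k)
            if (plane[cand[k]] > bv) { bv = plane[cand[k]]; best = cand[k]; }
          yp[ho + Ho * wo] = bv;
          ap[ho + Ho * wo] = best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector gy, IntegerVector argmax, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* gp = gy.begin() + ((size_t)n * C + c) * Ho * Wo;
      const int* ap = argmax.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* xp = gx.begin() + ((size_t)n * C + c) * H * W;
      for (int i = 0; i < Ho * Wo; ++i) xp[ap[i]] += gp[i];
    }
  }
  return gx;
}
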