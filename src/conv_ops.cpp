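// Low-level kernels for the convolutional layers.
//
// Tensor layout: an activation tensor with spatial size H x W, C channels
// and N images is stored as a (H*W*N) x C matrix whose row index is
// h + H*(w + W*n) (0-based). This keeps channel-wise operations (batch
// norm, ReLU) as plain column operations in R and makes convolution a
// single BLAS matrix product on the im2col expansion below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

// Expand x into the im2col matrix: rows are output positions
// ho + Ho*(wo + Wo*n), columns are kernel taps dh + k*(dw + k*c).
// Out-of-image taps (zero padding) stay zero.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericMatrix x, int H, int W, int N,
                         int k, int stride, int pad) {
  const int C = x.ncol();
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  NumericMatrix out(Ho * Wo * N, k * k * C);
  const double* xp = x.begin();
  double* op = out.begin();
  const int n_out_rows = Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (long)c * H * W * N;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        double* ocol = op + ((long)(dh + k * (dw + k * c))) * n_out_rows;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wsrc = wo * stride - pad + dw;
            const bool wok = wsrc >= 0 && wsrc < W;
            double* od = ocol + (long)Ho * (wo + (long)Wo * n);
            if (!wok) {
              for (int ho = 0; ho < Ho; ++ho) od[ho] = 0.0;
              continue;
            }
            const double* xs = xc + (long)H * (wsrc + (long)W * n);
            for (int ho = 0; ho < Ho; ++ho) {
              const int hsrc = ho * stride - pad + dh;
              od[ho] = (hsrc >= 0 && hsrc < H) ? xs[hsrc] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add the im2col gradient back onto the input tensor.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(NumericMatrix dcol, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  NumericMatrix dx(H * W * N, C);
  const double* dp = dcol.begin();
  double* xp = dx.begin();
  const int n_out_rows = Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (long)c * H * W * N;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const double* dcolc = dp + ((long)(dh + k * (dw + k * c))) * n_out_rows;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wsrc = wo * stride - pad + dw;
            if (wsrc < 0 || wsrc >= W) continue;
            const double* dd = dcolc + (long)Ho * (wo + (long)Wo * n);
            double* xs = xc + (long)H * (wsrc + (long)W * n);
            for (int ho = 0; ho < Ho; ++ho) {
              const int hsrc = ho * stride - pad + dh;
              if (hsrc >= 0 && hsrc < H) xs[hsrc] += dd[ho];
            }
          }
        }
      }
    }
  }
  return dx;
}

// 2x2 max pooling with stride 2. Returns the pooled tensor and the
// (1-based) row index in x of each maximum, for the backward pass.
// [[Rcpp::export]]
List maxpool2_cpp(NumericMatrix x, int H, int W, int N) {
  const int C = x.ncol();
  const int Ho = H / 2, Wo = W / 2;
  NumericMatrix out(Ho * Wo * N, C);
  IntegerMatrix arg(Ho * Wo * N, C);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const long orow = ho + (long)Ho * (wo + (long)Wo * n);
          double best = -1e300;
          long besti = 0;
          for (int dw = 0; dw < 2; ++dw) {
            for (int dh = 0; dh < 2; ++dh) {
              const long irow = (2 * ho + dh) +
                (long)H * ((2 * wo + dw) + (long)W * n);
              const double v = x(irow, c);
              if (v > best) { best = v; besti = irow; }
            }
          }
          out(orow, c) = best;
          arg(orow, c) = (int)besti + 1;
        }
      }
    }
  }
  return List::create(Named("out") = out, Named("argmax") = arg);
}

// [[Rcpp::export]]
NumericMatrix maxpool2_backward_cpp(NumericMatrix dout, IntegerMatrix arg,
                                    int in_rows) {
  const int C = dout.ncol();
  NumericMatrix dx(in_rows, C);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < dout.nrow(); ++r) {
      dx(arg(r, c) - 1, c) += dout(r, c);
    }
  }
  return dx;
}

// y = x * scale[c] + shift[c], one pass (used by batch norm and bias adds)
// [[Rcpp::export]]
NumericMatrix col_scale_shift_cpp(NumericMatrix x, NumericVector scale,
                                  NumericVector shift) {
  const int P = x.nrow(), C = x.ncol();
  NumericMatrix y(P, C);
  for (int c = 0; c < C; ++c) {
    const double a = scale[c], b = shift[c];
    const double* xc = x.begin() + (long)c * P;
    double* yc = y.begin() + (long)c * P;
    for (int r = 0; r < P; ++r) yc[r] = xc[r] * a + b;
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix relu_cpp(NumericMatrix x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xp = x.begin();
  double* yp = y.begin();
  const long n = (long)x.nrow() * x.ncol();
  for (long i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericMatrix relu_backward_cpp(NumericMatrix dout, NumericMatrix out) {
  NumericMatrix dx(dout.nrow(), dout.ncol());
  const double* dp = dout.begin();
  const double* op = out.begin();
  double* xp = dx.begin();
  const long n = (long)dout.nrow() * dout.ncol();
  for (long i = 0; i < n; ++i) xp[i] = op[i] > 0 ? dp[i] : 0.0;
  return dx;
}

// fused batch-norm backward (training mode):
// dxhat = dout * gamma; dx = (dxhat - mean(dxhat) - xhat*mean(dxhat*xhat)) * inv_sd
// also accumulates dgamma = sum(dout*xhat), dbeta = sum(dout), per channel.
// [[Rcpp::export]]
List bn_backward_cpp(NumericMatrix dout, NumericMatrix xhat,
                     NumericVector gamma, NumericVector inv_sd) {
  const int P = dout.nrow(), C = dout.ncol();
  NumericMatrix dx(P, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dc = dout.begin() + (long)c * P;
    const double* hc = xhat.begin() + (long)c * P;
    double* xc = dx.begin() + (long)c * P;
    double s1 = 0, s2 = 0, sg = 0, sb = 0;
    const double g = gamma[c];
    for (int r = 0; r < P; ++r) {
      sg += dc[r] * hc[r];
      sb += dc[r];
      s1 += dc[r] * g;
      s2 += dc[r] * g * hc[r];
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double m1 = s1 / P, m2 = s2 / P, isd = inv_sd[c];
    for (int r = 0; r < P; ++r) {
      xc[r] = (dc[r] * g - m1 - hc[r] * m2) * isd;
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// per-channel mean and biased variance in one pass
// [[Rcpp::export]]
List bn_stats_cpp(NumericMatrix x) {
  const int P = x.nrow(), C = x.ncol();
  NumericVector mu(C), va(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (long)c * P;
    double s = 0, s2 = 0;
    for (int r = 0; r < P; ++r) { s += xc[r]; s2 += xc[r] * xc[r]; }
    const double m = s / P;
    mu[c] = m;
    va[c] = s2 / P - m * m;
  }
  return List::create(Named("mu") = mu, Named("va") = va);
}
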