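#include <Rcpp.h>
using namespace Rcpp;

// Tensors are flat doubles in (C, H, W, B) order, channel fastest.
// All convolutions are correlations (no kernel flip), stride 1, zero padding.

static inline R_xlen_t idx4(int c, int h, int w, int b, int C, int H, int W) {
  return (R_xlen_t)c + (R_xlen_t)C * ((R_xlen_t)h + (R_xlen_t)H * ((R_xlen_t)w + (R_xlen_t)W * b));
}

// depthwise conv forward: one K x K kernel per channel, ker laid out (C, K, K)
// [[Rcpp::export]]
NumericVector cpp_dw_fwd(NumericVector x, NumericVector ker,
                         int C, int H, int W, int B, int K, int pad) {
  NumericVector out((R_xlen_t)C * H * W * B);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < K; ++j) {
      for (int i = 0; i < K; ++i) {
        const double* kij = &ker[(R_xlen_t)C * (i + K * j)];
        for (int w = 0; w < W; ++w) {
          int wi = w + j - pad;
          if (wi < 0 || wi >= W) continue;
          for (int h = 0; h < H; ++h) {
            int hi = h + i - pad;
            if (hi < 0 || hi >= H) continue;
            double* o = &out[idx4(0, h, w, b, C, H, W)];
            const double* xi = &x[idx4(0, hi, wi, b, C, H, W)];
            for (int c = 0; c < C; ++c) o[c] += kij[c] * xi[c];
          }
        }
      }
    }
  }
  return out;
}

// depthwise conv backward: returns list(dx, dker)
// [[Rcpp::export]]
List cpp_dw_bwd(NumericVector x, NumericVector ker, NumericVector dy,
                int C, int H, int W, int B, int K, int pad) {
  NumericVector dx((R_xlen_t)C * H * W * B);
  NumericVector dker((R_xlen_t)C * K * K);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < K; ++j) {
      for (int i = 0; i < K; ++i) {
        const double* kij = &ker[(R_xlen_t)C * (i + K * j)];
        double* dkij = &dker[(R_xlen_t)C * (i + K * j)];
        for (int w = 0; w < W; ++w) {
          int wi = w + j - pad;
          if (wi < 0 || wi >= W) continue;
          for (int h = 0; h < H; ++h) {
            int hi = h + i - pad;
            if (hi < 0 || hi >= H) continue;
            const double* g = &dy[idx4(0, h, w, b, C, H, W)];
            const double* xi = &x[idx4(0, hi, wi, b, C, H, W)];
            double* dxi = &dx[idx4(0, hi, wi, b, C, H, W)];
            for (int c = 0; c < C; ++c) {
              dxi[c] += kij[c] * g[c];
              dkij[c] += xi[c] * g[c];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dker"] = dker);
}

// small dense conv forward (used by spatial attention, 2 -> 1 channels)
// weights laid out (Cout, Cin, K, K), Cout fastest
// [[Rcpp::export]]
NumericVector cpp_conv2_fwd(NumericVector x, NumericVector wt,
                            int Cin, int Cout, int H, int W, int B,
                            int K, int pad) {
  NumericVector out((R_xlen_t)Cout * H * W * B);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* o = &out[idx4(0, h, w, b, Cout, H, W)];
        for (int j = 0; j < K; ++j) {
          int wi = w + j - pad;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < K; ++i) {
            int hi = h + i - pad;
            if (hi < 0 || hi >= H) continue;
            const double* xi = &x[idx4(0, hi, wi, b, Cin, H, W)];
            const double* wk = &wt[(R_xlen_t)Cout * Cin * (i + K * j)];
            for (int ci = 0; ci < Cin; ++ci)
              for (int co = 0; co < Cout; ++co)
                o[co] += wk[co + Cout * ci] * xi[ci];
          }
        }
      }
    }
  }
  return out;
}

// small dense conv backward: returns list(dx, dw)
// [[Rcpp::export]]
List cpp_conv2_bwd(NumericVector x, NumericVector wt, NumericVector dy,
                   int Cin, int Cout, int H, int W, int B, int K, int pad) {
  NumericVector dx((R_xlen_t)Cin * H * W * B);
  NumericVector dw((R_xlen_t)Cout * Cin * K * K);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* g = &dy[idx4(0, h, w, b, Cout, H, W)];
        for (int j = 0; j < K; ++j) {
          int wi = w + j - pad;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < K; ++i) {
            int hi = h + i - pad;
            if (hi < 0 || hi >= H) continue;
            const double* xi = &x[idx4(0, hi, wi, b, Cin, H, W)];
            double* dxi = &dx[idx4(0, hi, wi, b, Cin, H, W)];
            const double* wk = &wt[(R_xlen_t)Cout * Cin * (i + K * j)];
            double* dwk = &dw[(R_xlen_t)Cout * Cin * (i + K * j)];
            for (int ci = 0; ci < Cin; ++ci)
              for (int co = 0; co < Cout; ++co) {
                dxi[ci] += wk[co + Cout * ci] * g[co];
                dwk[co + Cout * ci] += xi[ci] * g[co];
              }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// 2x2 stride-2 pooling; mode 0 = max (argmax recorded as 0..3), 1 = average
// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector x, int C, int H, int W, int B, int mode) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)C * Ho * Wo * B);
  IntegerVector arg(mode == 0 ? (R_xlen_t)C * Ho * Wo * B : 0);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        R_xlen_t oo = idx4(0, h, w, b, C, Ho, Wo);
        R_xlen_t i00 = idx4(0, 2 * h, 2 * w, b, C, H, W);
        R_xlen_t i10 = idx4(0, 2 * h + 1, 2 * w, b, C, H, W);
        R_xlen_t i01 = idx4(0, 2 * h, 2 * w + 1, b, C, H, W);
        R_xlen_t i11 = idx4(0, 2 * h + 1, 2 * w + 1, b, C, H, W);
        for (int c = 0; c < C; ++c) {
          double v0 = x[i00 + c], v1 = x[i10 + c], v2 = x[i01 + c], v3 = x[i11 + c];
          if (mode == 1) {
            out[oo + c] = 0.25 * (v0 + v1 + v2 + v3);
          } else {
            double m = v0; int a = 0;
            if (v1 > m) { m = v1; a = 1; }
            if (v2 > m) { m = v2; a = 2; }
            if (v3 > m) { m = v3; a = 3; }
            out[oo + c] = m;
            arg[oo + c] = a;
          }
        }
      }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bwd(NumericVector dy, IntegerVector arg,
                           int C, int H, int W, int B, int mode) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)C * H * W * B);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        R_xlen_t oo = idx4(0, h, w, b, C, Ho, Wo);
        R_xlen_t at[4] = {idx4(0, 2 * h, 2 * w, b, C, H, W),
                          idx4(0, 2 * h + 1, 2 * w, b, C, H, W),
                          idx4(0, 2 * h, 2 * w + 1, b, C, H, W),
                          idx4(0, 2 * h + 1, 2 * w + 1, b, C, H, W)};
        for (int c = 0; c < C; ++c) {
          double g = dy[oo + c];
          if (mode == 1) {
            for (int q = 0; q < 4; ++q) dx[at[q] + c] += 0.25 * g;
          } else {
            dx[at[arg[oo + c]] + c] += g;
          }
        }
      }
  return dx;
}

// channel pooling for spatial attention: out channel 0 = max over c,
// channel 1 = mean over c; argmax channel recorded for backprop
// [[Rcpp::export]]
List cpp_chpool_fwd(NumericVector x, int C, int H, int W, int B) {
  R_xlen_t n = (R_xlen_t)H * W * B;
  NumericVector out(2 * n);
  IntegerVector arg(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    const double* xi = &x[(R_xlen_t)C * p];
    double m = xi[0], s = xi[0];
    int a = 0;
    for (int c = 1; c < C; ++c) {
      s += xi[c];
      if (xi[c] > m) { m = xi[c]; a = c; }
    }
    out[2 * p] = m;
    out[2 * p + 1] = s / C;
    arg[p] = a;
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_chpool_bwd(NumericVector dy, IntegerVector arg,
                             int C, int H, int W, int B) {
  R_xlen_t n = (R_xlen_t)H * W * B;
  NumericVector dx((R_xlen_t)C * n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double gmax = dy[2 * p], gavg = dy[2 * p + 1] / C;
    double* dxi = &dx[(R_xlen_t)C * p];
    for (int c = 0; c < C; ++c) dxi[c] += gavg;
    dxi[arg[p]] += gmax;
  }
  return dx;
}

// ---- fused helpers for the training path ----

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector x, NumericVector dy) {
  R_xlen_t n = x.size();
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < n; ++i) dx[i] = x[i] > 0 ? dy[i] : 0.0;
  return dx;
}

// batch normalization over (H,W,B) per channel. Returns y, mu, invstd.
// training mode computes batch statistics; eval mode uses the supplied ones.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector mu_in, NumericVector var_in,
                int C, int training, double eps) {
  R_xlen_t n = x.size();
  R_xlen_t m = n / C;
  NumericVector mu(C), var(C);
  if (training) {
    for (R_xlen_t p = 0; p < m; ++p) {
      const double* xi = &x[(R_xlen_t)C * p];
      for (int c = 0; c < C; ++c) mu[c] += xi[c];
    }
    for (int c = 0; c < C; ++c) mu[c] /= m;
    for (R_xlen_t p = 0; p < m; ++p) {
      const double* xi = &x[(R_xlen_t)C * p];
      for (int c = 0; c < C; ++c) {
        double d = xi[c] - mu[c];
        var[c] += d * d;
      }
    }
    for (int c = 0; c < C; ++c) var[c] /= m;
  } else {
    mu = clone(mu_in);
    var = clone(var_in);
  }
  NumericVector invstd(C);
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  NumericVector y(n);
  for (R_xlen_t p = 0; p < m; ++p) {
    const double* xi = &x[(R_xlen_t)C * p];
    double* yi = &y[(R_xlen_t)C * p];
    for (int c = 0; c < C; ++c)
      yi[c] = gamma[c] * (xi[c] - mu[c]) * invstd[c] + beta[c];
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = var,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector mu, NumericVector invstd,
                NumericVector gamma, NumericVector dy, int C) {
  R_xlen_t n = x.size();
  R_xlen_t m = n / C;
  NumericVector dgamma(C), dbeta(C), sdx(C), sdxx(C);
  for (R_xlen_t p = 0; p < m; ++p) {
    const double* xi = &x[(R_xlen_t)C * p];
    const double* g = &dy[(R_xlen_t)C * p];
    for (int c = 0; c < C; ++c) {
      double xh = (xi[c] - mu[c]) * invstd[c];
      dgamma[c] += g[c] * xh;
      dbeta[c] += g[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    sdx[c] = dbeta[c] / m;          // mean of dy
    sdxx[c] = dgamma[c] / m;        // mean of dy * xhat
  }
  NumericVector dx(n);
  for (R_xlen_t p = 0; p < m; ++p) {
    const double* xi = &x[(R_xlen_t)C * p];
    const double* g = &dy[(R_xlen_t)C * p];
    double* d = &dx[(R_xlen_t)C * p];
    for (int c = 0; c < C; ++c) {
      double xh = (xi[c] - mu[c]) * invstd[c];
      d[c] = gamma[c] * invstd[c] * (g[c] - sdx[c] - xh * sdxx[c]);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// per-channel, per-sample global average pool: (C,H,W,B) -> C x B
// [[Rcpp::export]]
NumericMatrix cpp_gap_fwd(NumericVector x, int C, int HW, int B) {
  NumericMatrix s(C, B);
  for (int b = 0; b < B; ++b) {
    for (R_xlen_t p = 0; p < HW; ++p) {
      const double* xi = &x[(R_xlen_t)C * (p + (R_xlen_t)HW * b)];
      for (int c = 0; c < C; ++c) s(c, b) += xi[c];
    }
    for (int c = 0; c < C; ++c) s(c, b) /= HW;
  }
  return s;
}

// y = x * (alpha * a[c,b] + beta * sp[h,w,b])
// [[Rcpp::export]]
NumericVector cpp_sca_gate_fwd(NumericVector x, NumericMatrix a,
                               NumericVector sp, double alpha, double beta,
                               int C, int HW, int B) {
  NumericVector y(x.size());
  for (int b = 0; b < B; ++b)
    for (R_xlen_t p = 0; p < HW; ++p) {
      R_xlen_t at = (R_xlen_t)C * (p + (R_xlen_t)HW * b);
      double sb = beta * sp[p + (R_xlen_t)HW * b];
      const double* xi = &x[at];
      double* yi = &y[at];
      for (int c = 0; c < C; ++c) yi[c] = xi[c] * (alpha * a(c, b) + sb);
    }
  return y;
}

// backward of the gate: given dy, x, a, sp returns
// dx (elementwise through the gate), da (C x B, pre-alpha), dsp (HWB,
// pre-beta), dalpha, dbeta
// [[Rcpp::export]]
List cpp_sca_gate_bwd(NumericVector x, NumericVector dy, NumericMatrix a,
                      NumericVector sp, double alpha, double beta,
                      int C, int HW, int B) {
  NumericVector dx(x.size());
  NumericMatrix da(C, B);
  NumericVector dsp((R_xlen_t)HW * B);
  double dalpha = 0, dbeta = 0;
  for (int b = 0; b < B; ++b)
    for (R_xlen_t p = 0; p < HW; ++p) {
      R_xlen_t at = (R_xlen_t)C * (p + (R_xlen_t)HW * b);
      double spv = sp[p + (R_xlen_t)HW * b];
      const double* xi = &x[at];
      const double* g = &dy[at];
      double* d = &dx[at];
      double dsp_acc = 0;
      for (int c = 0; c < C; ++c) {
        double dgate = g[c] * xi[c];
        d[c] = g[c] * (alpha * a(c, b) + beta * spv);
        da(c, b) += dgate;
        dsp_acc += dgate;
        dalpha += dgate * a(c, b);
        dbeta += dgate * spv;
      }
      dsp[p + (R_xlen_t)HW * b] = dsp_acc;
    }
  return List::create(_["dx"] = dx, _["da"] = da, _["dsp"] = dsp,
                      _["dalpha"] = dalpha, _["dbeta"] = dbeta);
}

// add ds[c,b] / HW to every spatial position (gradient of the global pool)
// [[Rcpp::export]]
NumericVector cpp_gap_bwd_add(NumericVector dx, NumericMatrix ds,
                              int C, int HW, int B) {
  NumericVector out = clone(dx);
  for (int b = 0; b < B; ++b)
    for (R_xlen_t p = 0; p < HW; ++p) {
      double* d = &out[(R_xlen_t)C * (p + (R_xlen_t)HW * b)];
      for (int c = 0; c < C; ++c) d[c] += ds(c, b) / HW;
    }
  return out;
}

// bicubic scale-2 resampling tables: for each output index the four source
// indices (clamped) and Keys (a = -1/2) weights
static void bicubic_taps(int n, std::vector<int>& idx, std::vector<double>& w) {
  idx.resize(8 * (size_t)n);
  w.resize(8 * (size_t)n);
  for (int o = 0; o < 2 * n; ++o) {
    double u = o / 2.0 - 0.25;
    int i0 = (int)std::floor(u);
    for (int q = 0; q < 4; ++q) {
      int k = i0 - 1 + q;
      double t = std::fabs(u - k);
      double a = -0.5, wv;
      if (t <= 1) wv = (a + 2) * t * t * t - (a + 3) * t * t + 1;
      else if (t < 2) wv = a * t * t * t - 5 * a * t * t + 8 * a * t - 4 * a;
      else wv = 0;
      int kc = k < 0 ? 0 : (k >= n ? n - 1 : k);
      idx[4 * (size_t)o + q] = kc;
      w[4 * (size_t)o + q] = wv;
    }
  }
}

// separable bicubic 2x upsampling of (C,H,W,B) -> (C,2H,2W,B)
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x, int C, int H, int W, int B) {
  std::vector<int> ih; std::vector<double> wh;
  std::vector<int> iw; std::vector<double> ww;
  bicubic_taps(H, ih, wh);
  bicubic_taps(W, iw, ww);
  int H2 = 2 * H, W2 = 2 * W;
  std::vector<double> tmp((size_t)C * H2 * W * B, 0.0);   // H pass
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h2 = 0; h2 < H2; ++h2) {
        double* t = &tmp[(size_t)C * (h2 + (size_t)H2 * (w + (size_t)W * b))];
        for (int q = 0; q < 4; ++q) {
          double wv = wh[4 * (size_t)h2 + q];
          const double* xi = &x[idx4(0, ih[4 * (size_t)h2 + q], w, b, C, H, W)];
          for (int c = 0; c < C; ++c) t[c] += wv * xi[c];
        }
      }
  NumericVector out((R_xlen_t)C * H2 * W2 * B);
  for (int b = 0; b < B; ++b)
    for (int w2 = 0; w2 < W2; ++w2)
      for (int h2 = 0; h2 < H2; ++h2) {
        double* o = &out[idx4(0, h2, w2, b, C, H2, W2)];
        for (int q = 0; q < 4; ++q) {
          double wv = ww[4 * (size_t)w2 + q];
          const double* t = &tmp[(size_t)C * (h2 + (size_t)H2 *
                                 (iw[4 * (size_t)w2 + q] + (size_t)W * b))];
          for (int c = 0; c < C; ++c) o[c] += wv * t[c];
        }
      }
  return out;
}

// adjoint of cpp_upsample2_fwd: (C,2H,2W,B) -> (C,H,W,B)
// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy, int C, int H, int W, int B) {
  std::vector<int> ih; std::vector<double> wh;
  std::vector<int> iw; std::vector<double> ww;
  bicubic_taps(H, ih, wh);
  bicubic_taps(W, iw, ww);
  int H2 = 2 * H, W2 = 2 * W;
  std::vector<double> tmp((size_t)C * H2 * W * B, 0.0);   // W-pass adjoint
  for (int b = 0; b < B; ++b)
    for (int w2 = 0; w2 < W2; ++w2)
      for (int h2 = 0; h2 < H2; ++h2) {
        const double* g = &dy[idx4(0, h2, w2, b, C, H2, W2)];
        for (int q = 0; q < 4; ++q) {
          double wv = ww[4 * (size_t)w2 + q];
          double* t = &tmp[(size_t)C * (h2 + (size_t)H2 *
                           (iw[4 * (size_t)w2 + q] + (size_t)W * b))];
          for (int c = 0; c < C; ++c) t[c] += wv * g[c];
        }
      }
  NumericVector dx((R_xlen_t)C * H * W * B);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h2 = 0; h2 < H2; ++h2) {
        const double* t = &tmp[(size_t)C * (h2 + (size_t)H2 * (w + (size_t)W * b))];
        for (int q = 0; q < 4; ++q) {
          double wv = wh[4 * (size_t)h2 + q];
          double* d = &dx[idx4(0, ih[4 * (size_t)h2 + q], w, b, C, H, W)];
          for (int c = 0; c < C; ++c) d[c] += wv * t[c];
        }
      }
  return dx;
}
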