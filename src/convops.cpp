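#include <Rcpp.h>
using namespace Rcpp;

// Activation tensors are R arrays with dim (H, W, C, N), column-major.
// im2col emits a (k*k*C) x (Ho*Wo*N) matrix; row index runs (ki, kj, c),
// column index runs (ho, wo, n). A kernel array (k, k, Cin, Cout) flattened
// to (k*k*Cin, Cout) therefore matches the row ordering exactly.

static inline void get_dims(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int k, int stride, int pad) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int nrow = k * k * C;
  NumericMatrix out(nrow, (R_xlen_t)Ho * Wo * N);
  const double* px = REAL(x);
  double* po = REAL(out);
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        double* pc = po + col * nrow;
        for (int c = 0; c < C; ++c) {
          const double* pxc = px + ((R_xlen_t)n * C + c) * HW;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            bool wok = (wi >= 0 && wi < W);
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              double v = 0.0;
              if (wok && hi >= 0 && hi < H) v = pxc[(R_xlen_t)wi * H + hi];
              pc[c * k * k + kj * k + ki] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Transpose of im2col: scatter-add columns back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int nrow = k * k * C;
  NumericVector x((R_xlen_t)H * W * C * N);
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  double* px = REAL(x);
  const double* po = REAL(cols);
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        const double* pc = po + col * nrow;
        for (int c = 0; c < C; ++c) {
          double* pxc = px + ((R_xlen_t)n * C + c) * HW;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              pxc[(R_xlen_t)wi * H + hi] += pc[c * k * k + kj * k + ki];
            }
          }
        }
      }
    }
  }
  return x;
}

// Depthwise convolution, kernel w with dim (k, k, C).
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector w, int stride, int pad) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int k = wd[0];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  double* py = REAL(y);
  const R_xlen_t HW = (R_xlen_t)H * W, HoWo = (R_xlen_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* pxc = px + ((R_xlen_t)n * C + c) * HW;
      const double* pwc = pw + (R_xlen_t)c * k * k;
      double* pyc = py + ((R_xlen_t)n * C + c) * HoWo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              acc += pwc[kj * k + ki] * pxc[(R_xlen_t)wi * H + hi];
            }
          }
          pyc[(R_xlen_t)wo * Ho + ho] = acc;
        }
      }
    }
  }
  return y;
}

// Gradients of the depthwise convolution: returns list(dx, dw).
// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int k = wd[0];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)k * k * C);
  dw.attr("dim") = IntegerVector::create(k, k, C);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  const double* pdy = REAL(dy);
  double* pdx = REAL(dx);
  double* pdw = REAL(dw);
  const R_xlen_t HW = (R_xlen_t)H * W, HoWo = (R_xlen_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* pxc = px + ((R_xlen_t)n * C + c) * HW;
      const double* pwc = pw + (R_xlen_t)c * k * k;
      const double* pdyc = pdy + ((R_xlen_t)n * C + c) * HoWo;
      double* pdxc = pdx + ((R_xlen_t)n * C + c) * HW;
      double* pdwc = pdw + (R_xlen_t)c * k * k;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double g = pdyc[(R_xlen_t)wo * Ho + ho];
          if (g == 0.0) continue;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              pdxc[(R_xlen_t)wi * H + hi] += g * pwc[kj * k + ki];
              pdwc[kj * k + ki] += g * pxc[(R_xlen_t)wi * H + hi];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Max pooling; also returns the 1-based linear argmax into x for backward.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx((R_xlen_t)Ho * Wo * C * N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = REAL(x);
  double* py = REAL(y);
  double* pidx = REAL(idx);
  const R_xlen_t HW = (R_xlen_t)H * W, HoWo = (R_xlen_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* pxc = px + ((R_xlen_t)n * C + c) * HW;
      R_xlen_t base = ((R_xlen_t)n * C + c) * HW;
      double* pyc = py + ((R_xlen_t)n * C + c) * HoWo;
      double* pic = pidx + ((R_xlen_t)n * C + c) * HoWo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          R_xlen_t bidx = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              double v = pxc[(R_xlen_t)wi * H + hi];
              if (v > best) { best = v; bidx = base + (R_xlen_t)wi * H + hi; }
            }
          }
          pyc[(R_xlen_t)wo * Ho + ho] = best;
          pic[(R_xlen_t)wo * Ho + ho] = (double)(bidx + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, NumericVector idx,
                              int H, int W, int C, int N) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  double* pdx = REAL(dx);
  const double* pdy = REAL(dy);
  const double* pidx = REAL(idx);
  R_xlen_t M = dy.size();
  for (R_xlen_t i = 0; i < M; ++i) {
    R_xlen_t j = (R_xlen_t)pidx[i] - 1;
    if (j >= 0) pdx[j] += pdy[i];
  }
  return dx;
}

// Fused per-channel affine y = x * scale[c] + shift[c].
// [[Rcpp::export]]
NumericVector chan_affine_cpp(NumericVector x, NumericVector scale,
                              NumericVector shift) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* px = REAL(x);
  double* py = REAL(y);
  const double* ps = REAL(scale);
  const double* pb = REAL(shift);
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double s = ps[c], b = pb[c];
      const double* pxc = px + ((R_xlen_t)n * C + c) * HW;
      double* pyc = py + ((R_xlen_t)n * C + c) * HW;
      for (R_xlen_t i = 0; i < HW; ++i) pyc[i] = pxc[i] * s + b;
    }
  }
  return y;
}

// Per-channel mean and (biased) variance over (H, W, N).
// [[Rcpp::export]]
List chan_stats_cpp(NumericVector x) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  NumericVector mu(C), va(C);
  const double* px = REAL(x);
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* pxc = px + ((R_xlen_t)n * C + c) * HW;
      for (R_xlen_t i = 0; i < HW; ++i) { s += pxc[i]; s2 += pxc[i] * pxc[i]; }
    }
    double m = s / (HW * N);
    mu[c] = m;
    double v = s2 / (HW * N) - m * m;
    va[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = va, _["m"] = (double)(HW * N));
}

// Per-channel sum over (H, W, N).
// [[Rcpp::export]]
NumericVector chan_sum_cpp(NumericVector x) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  NumericVector out(C);
  const double* px = REAL(x);
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* pxc = px + ((R_xlen_t)n * C + c) * HW;
      for (R_xlen_t i = 0; i < HW; ++i) s += pxc[i];
    }
    out[c] = s;
  }
  return out;
}
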