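#include <Rcpp.h>
using namespace Rcpp;

// Column-major single-sample layout throughout: x[h + H*w + H*W*c] for an
// (H, W, C) array. im2col row index r = kh + k*kw + k*k*c (kh fastest),
// column index p = ho + Hout*wo. col2im is the exact transpose (scatter-add),
// so conv backward-data and transposed-convolution forward share it.

// Batched variants: input (H, W, C, N) column-major; output columns ordered
// p fastest, then sample n -> (k*k*C, P*N).

// [[Rcpp::export]]
NumericMatrix cpp_im2col_batch(NumericVector x, int H, int W, int C, int N,
                               int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const int P = Hout * Wout;
  const int rows = k * k * C;
  NumericMatrix out(rows, P * N);
  const int samp = H * W * C;
  for (int n = 0; n < N; ++n) {
    const double* xs = &x[0] + (size_t)n * samp;
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        const int p = ho + Hout * wo + P * n;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        double* col = &out(0, p);
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h >= 0 && h < H && w >= 0 && w < W)
                col[kh + k * kw + k * k * c] = xs[h + H * w + H * W * c];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im_batch(NumericMatrix cols, int H, int W, int C, int N,
                               int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const int P = Hout * Wout;
  NumericVector x((size_t)H * W * C * N);
  const int samp = H * W * C;
  for (int n = 0; n < N; ++n) {
    double* xs = &x[0] + (size_t)n * samp;
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        const int p = ho + Hout * wo + P * n;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        const double* col = &cols(0, p);
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h >= 0 && h < H && w >= 0 && w < W)
                xs[h + H * w + H * W * c] += col[kh + k * kw + k * k * c];
            }
          }
        }
      }
    }
  }
  return x;
}

// Depthwise 3x3, stride 1, pad 1. w is (9, C); x is (H, W, C, N).
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                             int H, int W, int C, int N) {
  NumericVector y((size_t)H * W * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = &x[0] + (size_t)(c + C * n) * H * W;
      double* ys = &y[0] + (size_t)(c + C * n) * H * W;
      const double* wc = &w(0, c);
      const double bc = b[c];
      for (int ww = 0; ww < W; ++ww) {
        for (int h = 0; h < H; ++h) {
          double acc = bc;
          for (int kw = -1; kw <= 1; ++kw) {
            const int wj = ww + kw;
            if (wj < 0 || wj >= W) continue;
            for (int kh = -1; kh <= 1; ++kh) {
              const int hj = h + kh;
              if (hj < 0 || hj >= H) continue;
              acc += wc[(kh + 1) + 3 * (kw + 1)] * xs[hj + H * wj];
            }
          }
          ys[h + H * ww] = acc;
        }
      }
    }
  }
  return y;
}

// backward of depthwise conv: returns dx; accumulates dw (9, C) and db (C)
// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericMatrix w, NumericVector g,
                    int H, int W, int C, int N) {
  NumericVector dx((size_t)H * W * C * N);
  NumericMatrix dw(9, C);
  NumericVector db(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = &x[0] + (size_t)(c + C * n) * H * W;
      const double* gs = &g[0] + (size_t)(c + C * n) * H * W;
      double* dxs = &dx[0] + (size_t)(c + C * n) * H * W;
      const double* wc = &w(0, c);
      double* dwc = &dw(0, c);
      for (int ww = 0; ww < W; ++ww) {
        for (int h = 0; h < H; ++h) {
          const double gv = gs[h + H * ww];
          db[c] += gv;
          for (int kw = -1; kw <= 1; ++kw) {
            const int wj = ww + kw;
            if (wj < 0 || wj >= W) continue;
            for (int kh = -1; kh <= 1; ++kh) {
              const int hj = h + kh;
              if (hj < 0 || hj >= H) continue;
              const int r = (kh + 1) + 3 * (kw + 1);
              dwc[r] += gv * xs[hj + H * wj];
              dxs[hj + H * wj] += gv * wc[r];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, Hout * Wout);
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      const int p = ho + Hout * wo;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            const int r = kh + k * kw + k * k * c;
            if (h >= 0 && h < H && w >= 0 && w < W)
              out(r, p) = x[h + H * w + H * W * c];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector x(H * W * C);
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      const int p = ho + Hout * wo;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            const int r = kh + k * kw + k * k * c;
            if (h >= 0 && h < H && w >= 0 && w < W)
              x[h + H * w + H * W * c] += cols(r, p);
          }
        }
      }
    }
  }
  return x;
}
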