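#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction (im2col) and its adjoint (col2im) for 2-D convolution.
//
// Tensor layout is channel-major (C, H, W, B) in R's column-major order,
// i.e. element (c, h, w, b) lives at c + C*(h + H*(w + W*b)).  The patch
// matrix has one column per (output position, batch item), ordered
// ho-fastest then wo then b, and one row per (kh, kw, c) with kh fastest.
// A weight matrix of shape (kh*kw*Cin) x Cout then gives the convolution
// output as crossprod(W, patches) = (Cout x positions), which keeps the
// channel dimension fastest so batch-norm and activations recycle
// per-channel vectors without any transposition.

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_chwb(const NumericVector& x, int C, int H, int W, int B,
                          int kh, int kw, int stride, int pad) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1)
    stop("spatial size too small for this kernel/stride/padding");
  const int K = kh * kw * C;
  const int N = Ho * Wo * B;
  NumericMatrix cols(K, N);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int b = 0; b < B; ++b) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double* dst = cp + (R_xlen_t)K * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * b));
        for (int c = 0; c < C; ++c) {
          for (int kwi = 0; kwi < kw; ++kwi) {
            const int wi = wo * stride + kwi - pad;
            const bool w_ok = (wi >= 0 && wi < W);
            for (int khi = 0; khi < kh; ++khi) {
              const int hi = ho * stride + khi - pad;
              const int k = khi + kh * (kwi + kw * c);
              if (w_ok && hi >= 0 && hi < H) {
                dst[k] = xp[c + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * b))];
              } else {
                dst[k] = 0.0;
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_chwb(const NumericMatrix& cols, int C, int H, int W,
                          int B, int kh, int kw, int stride, int pad) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const int K = kh * kw * C;
  const int N = Ho * Wo * B;
  if (cols.nrow() != K || cols.ncol() != N)
    stop("col2im: patch matrix shape does not match the stated geometry");
  NumericVector x((R_xlen_t)C * H * W * B);
  double* xp = x.begin();
  const double* cp = cols.begin();
  for (int b = 0; b < B; ++b) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double* src = cp + (R_xlen_t)K * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * b));
        for (int c = 0; c < C; ++c) {
          for (int kwi = 0; kwi < kw; ++kwi) {
            const int wi = wo * stride + kwi - pad;
            if (wi < 0 || wi >= W) continue;
            for (int khi = 0; khi < kh; ++khi) {
              const int hi = ho * stride + khi - pad;
              if (hi < 0 || hi >= H) continue;
              const int k = khi + kh * (kwi + kw * c);
              xp[c + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * b))] += src[k];
            }
          }
        }
      }
    }
  }
  return x;
}
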