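#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Activations are column-major arrays of dim (C, H, W, N): channel fastest,
// so the C values at one pixel are contiguous and patch extraction is a
// sequence of memcpys. im2col unfolds receptive fields into a matrix with
// row index r = c + C*(kh + KH*kw) and column index j = oh + OH*(ow + OW*n);
// col2im is its accumulating adjoint. Zero padding, square stride.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int N,
                         int KH, int KW, int stride, int pad) {
  const int OH = (H + 2 * pad - KH) / stride + 1;
  const int OW = (W + 2 * pad - KW) / stride + 1;
  const int rows = C * KH * KW;
  NumericMatrix out(rows, OH * OW * N);
  const double *px = x.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n) {
    const double *img = px + (size_t)C * H * W * n;
    for (int ow = 0; ow < OW; ++ow) {
      const int x0 = ow * stride - pad;
      for (int oh = 0; oh < OH; ++oh) {
        const int y0 = oh * stride - pad;
        double *col = po + (size_t)rows * (oh + (size_t)OH * (ow + (size_t)OW * n));
        for (int kw = 0; kw < KW; ++kw) {
          const int xx = x0 + kw;
          for (int kh = 0; kh < KH; ++kh) {
            double *dst = col + (size_t)C * (kh + KH * kw);
            const int yy = y0 + kh;
            if (xx < 0 || xx >= W || yy < 0 || yy >= H) {
              std::memset(dst, 0, sizeof(double) * C);
            } else {
              std::memcpy(dst, img + (size_t)C * (yy + (size_t)H * xx),
                          sizeof(double) * C);
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int KH, int KW, int stride, int pad) {
  const int OH = (H + 2 * pad - KH) / stride + 1;
  const int OW = (W + 2 * pad - KW) / stride + 1;
  const int rows = C * KH * KW;
  NumericVector out((size_t)C * H * W * N);
  const double *pc = cols.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n) {
    double *img = po + (size_t)C * H * W * n;
    for (int ow = 0; ow < OW; ++ow) {
      const int x0 = ow * stride - pad;
      for (int oh = 0; oh < OH; ++oh) {
        const int y0 = oh * stride - pad;
        const double *col = pc + (size_t)rows * (oh + (size_t)OH * (ow + (size_t)OW * n));
        for (int kw = 0; kw < KW; ++kw) {
          const int xx = x0 + kw;
          if (xx < 0 || xx >= W) continue;
          for (int kh = 0; kh < KH; ++kh) {
            const int yy = y0 + kh;
            if (yy < 0 || yy >= H) continue;
            const double *src = col + (size_t)C * (kh + KH * kw);
            double *dst = img + (size_t)C * (yy + (size_t)H * xx);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, H, W, N);
  return out;
}
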