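#include <Rcpp.h>
using namespace Rcpp;

// Lower a H x W x C array (R column-major) into a (k*k*C) x (Ho*Wo) matrix.
// Column j corresponds to output pixel (ho, wo) with ho varying fastest, so a
// (Ho*Wo) x Cout result matrix reinterprets directly as an Ho x Wo x Cout
// array. Row index runs over (ki, kj, c) with ki fastest, matching an R
// kernel array of dim c(k, k, Cin, Cout) flattened to (k*k*Cin) x Cout.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, Ho * Wo);
  const double *px = x.begin();
  double *po = out.begin();
  const int rows = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      double *dst = po + (size_t)col * rows;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double *xc = px + (size_t)c * H * W;
        for (int kj = 0; kj < k; ++kj) {
          const int w = w0 + kj;
          const bool wok = (w >= 0 && w < W);
          const double *xcw = xc + (size_t)H * w;
          double *d2 = dst + k * kj + k * k * c;
          for (int ki = 0; ki < k; ++ki) {
            const int h = h0 + ki;
            d2[ki] = (wok && h >= 0 && h < H) ? xcw[h] : 0.0;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add columns back into a H x W x C array.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)H * W * C);
  double *po = out.begin();
  const double *pc = cols.begin();
  const int rows = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const double *src = pc + (size_t)col * rows;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double *oc = po + (size_t)c * H * W;
        for (int kj = 0; kj < k; ++kj) {
          const int w = w0 + kj;
          if (w < 0 || w >= W) continue;
          double *ocw = oc + (size_t)H * w;
          const double *s2 = src + k * kj + k * k * c;
          for (int ki = 0; ki < k; ++ki) {
            const int h = h0 + ki;
            if (h >= 0 && h < H) ocw[h] += s2[ki];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}
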