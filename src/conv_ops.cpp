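// Compiled kernels for the compact CNN: im2col/col2im gathers, channel
// permutations and 2x2 max-pooling. Matrix products stay in R (BLAS).
//
// Array layouts follow R column-major conventions:
//   images/activations: [H, W, C, N]
//   im2col patch matrix: (k*k*C) x (OH*OW*N), rows kh-fastest then kw then c,
//   columns oh-fastest then ow then image.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& x, int H, int W, int C, int N,
                         int k, int stride, int pad, int OH, int OW) {
  const int k2c = k * k * C;
  NumericMatrix out(k2c, (R_xlen_t)OH * OW * N);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* xn = px + (R_xlen_t)n * H * W * C;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        double* col = po + ((R_xlen_t)n * OW * OH + (R_xlen_t)ow * OH + oh) * k2c;
        int r0 = oh * stride - pad;
        int c0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (R_xlen_t)c * H * W;
          for (int kw = 0; kw < k; ++kw) {
            int cc = c0 + kw;
            double* dst = col + c * k * k + kw * k;
            if (cc < 0 || cc >= W) {
              for (int kh = 0; kh < k; ++kh) dst[kh] = 0.0;
            } else {
              const double* xcol = xc + (R_xlen_t)cc * H;
              for (int kh = 0; kh < k; ++kh) {
                int r = r0 + kh;
                dst[kh] = (r < 0 || r >= H) ? 0.0 : xcol[r];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add the patch-matrix gradient back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericMatrix& dcol, int H, int W, int C, int N,
                         int k, int stride, int pad, int OH, int OW) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double* pd = REAL(dcol);
  double* px = REAL(dx);
  const int k2c = k * k * C;
  for (int n = 0; n < N; ++n) {
    double* xn = px + (R_xlen_t)n * H * W * C;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double* col = pd + ((R_xlen_t)n * OW * OH + (R_xlen_t)ow * OH + oh) * k2c;
        int r0 = oh * stride - pad;
        int c0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          double* xc = xn + (R_xlen_t)c * H * W;
          for (int kw = 0; kw < k; ++kw) {
            int cc = c0 + kw;
            if (cc < 0 || cc >= W) continue;
            const double* src = col + c * k * k + kw * k;
            double* xcol = xc + (R_xlen_t)cc * H;
            for (int kh = 0; kh < k; ++kh) {
              int r = r0 + kh;
              if (r >= 0 && r < H) xcol[r] += src[kh];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// (Cout) x (OH*OW*N) GEMM output -> [OH, OW, Cout, N] activation array.
// [[Rcpp::export]]
NumericVector gemm_to_spatial_cpp(const NumericMatrix& out, int OH, int OW,
                                  int C, int N) {
  NumericVector y((R_xlen_t)OH * OW * C * N);
  const double* po = REAL(out);
  double* py = REAL(y);
  const R_xlen_t plane = (R_xlen_t)OH * OW;
  for (int n = 0; n < N; ++n)
    for (R_xlen_t p = 0; p < plane; ++p) {
      const double* src = po + (n * plane + p) * C;
      double* dst = py + (R_xlen_t)n * plane * C + p;
      for (int c = 0; c < C; ++c) dst[(R_xlen_t)c * plane] = src[c];
    }
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return y;
}

// [OH, OW, C, N] gradient -> (C) x (OH*OW*N) layout for the GEMM backward.
// [[Rcpp::export]]
NumericMatrix spatial_to_gemm_cpp(const NumericVector& dy, int OH, int OW,
                                  int C, int N) {
  NumericMatrix out(C, (R_xlen_t)OH * OW * N);
  const double* pd = REAL(dy);
  double* po = REAL(out);
  const R_xlen_t plane = (R_xlen_t)OH * OW;
  for (int n = 0; n < N; ++n)
    for (R_xlen_t p = 0; p < plane; ++p) {
      const double* src = pd + (R_xlen_t)n * plane * C + p;
      double* dst = po + (n * plane + p) * C;
      for (int c = 0; c < C; ++c) dst[c] = src[(R_xlen_t)c * plane];
    }
  return out;
}

// 2x2/stride-2 max pool; records the winning quadrant for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(const NumericVector& x, int H, int W, int C, int N) {
  const int OH = H / 2, OW = W / 2;
  NumericVector y((R_xlen_t)OH * OW * C * N);
  IntegerVector arg((R_xlen_t)OH * OW * C * N);
  const double* px = REAL(x);
  double* py = REAL(y);
  int* pa = INTEGER(arg);
  R_xlen_t o = 0;
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* plane = px + cn * H * W;
    for (int ow = 0; ow < OW; ++ow) {
      const double* colA = plane + (R_xlen_t)(2 * ow) * H;
      const double* colB = plane + (R_xlen_t)(2 * ow + 1) * H;
      for (int oh = 0; oh < OH; ++oh, ++o) {
        double v0 = colA[2 * oh], v1 = colA[2 * oh + 1];
        double v2 = colB[2 * oh], v3 = colB[2 * oh + 1];
        int a = 0; double v = v0;
        if (v1 > v) { v = v1; a = 1; }
        if (v2 > v) { v = v2; a = 2; }
        if (v3 > v) { v = v3; a = 3; }
        py[o] = v; pa[o] = a;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(const NumericVector& dy, const IntegerVector& arg,
                               int H, int W, int C, int N) {
  const int OH = H / 2, OW = W / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double* pd = REAL(dy);
  const int* pa = INTEGER(arg);
  double* px = REAL(dx);
  R_xlen_t o = 0;
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    double* plane = px + cn * H * W;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh, ++o) {
        int a = pa[o];
        int r = 2 * oh + (a & 1);
        int cc = 2 * ow + (a >> 1);
        plane[(R_xlen_t)cc * H + r] += pd[o];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
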