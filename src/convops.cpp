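#include <Rcpp.h>
using namespace Rcpp;

// Image tensors are R arrays of dim (H, W, C), column-major, so element
// (h, w, c) (0-based) lives at index h + H*w + H*W*c.
//
// im2col extracts k x k patches at the given stride with zero padding and
// returns a P x (k*k*C) matrix, P = Hout*Wout, rows ordered with the output
// row index fastest (p = ho + Hout*wo), columns ordered kh fastest, then kw,
// then channel (col = kh + k*kw + k*k*c).  A convolution is then
// cols %*% W with W of dim (k*k*Cin) x Cout, and the P x Cout result can be
// reshaped directly to an (Hout, Wout, Cout) array.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t P = (R_xlen_t)Hout * Wout;
  NumericMatrix cols(P, k * k * C);
  double *pc = REAL(cols);
  const double *px = REAL(x);
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (R_xlen_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = c * k * k + kw * k + kh;
        double *out = pc + (R_xlen_t)col * P;
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Hout; ++ho) out[(R_xlen_t)wo * Hout + ho] = 0.0;
            continue;
          }
          const double *xcol = xc + (R_xlen_t)wi * H;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + kh;
            out[(R_xlen_t)wo * Hout + ho] =
                (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-adds patch columns back into an (H, W, C) array.
// Used both for the gradient of a convolution w.r.t. its input and for the
// forward pass of a transpose convolution.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t P = (R_xlen_t)Hout * Wout;
  NumericVector x((R_xlen_t)H * W * C);
  double *px = REAL(x);
  const double *pc = REAL(cols);
  for (int c = 0; c < C; ++c) {
    double *xc = px + (R_xlen_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = c * k * k + kw * k + kh;
        const double *in = pc + (R_xlen_t)col * P;
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          double *xcol = xc + (R_xlen_t)wi * H;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi >= 0 && hi < H) xcol[hi] += in[(R_xlen_t)wo * Hout + ho];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// 2x2 max pooling with stride 2 (H and W must be even).  Returns the pooled
// array together with the 1-based linear argmax indices so the backward pass
// is a plain scatter.

// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x, int H, int W, int C) {
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y((R_xlen_t)H2 * W2 * C);
  IntegerVector idx((R_xlen_t)H2 * W2 * C);
  const double *px = REAL(x);
  double *py = REAL(y);
  int *pi = INTEGER(idx);
  for (int c = 0; c < C; ++c) {
    const R_xlen_t xo = (R_xlen_t)c * H * W;
    const R_xlen_t yo = (R_xlen_t)c * H2 * W2;
    for (int wo = 0; wo < W2; ++wo) {
      for (int ho = 0; ho < H2; ++ho) {
        R_xlen_t best = xo + (R_xlen_t)(2 * wo) * H + 2 * ho;
        double bv = px[best];
        const R_xlen_t cand[3] = {best + 1, best + H, best + H + 1};
        for (int t = 0; t < 3; ++t) {
          if (px[cand[t]] > bv) { bv = px[cand[t]]; best = cand[t]; }
        }
        py[yo + (R_xlen_t)wo * H2 + ho] = bv;
        pi[yo + (R_xlen_t)wo * H2 + ho] = (int)(best + 1);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H2, W2, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector gy, IntegerVector idx,
                               int H, int W, int C) {
  NumericVector gx((R_xlen_t)H * W * C);
  double *pg = REAL(gx);
  const double *pgy = REAL(gy);
  const int *pi = INTEGER(idx);
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) pg[pi[i] - 1] += pgy[i];
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}
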