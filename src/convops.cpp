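#include <Rcpp.h>
using namespace Rcpp;

// Image layout everywhere: numeric array dim (H, W, C), column-major as in R.
// im2col column layout: q = kh + k*kw + k*k*c (0-based), rows p = h_out + H_out*w_out.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo, k * k * C);
  double *xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int q = kh + k * kw + k * k * c;
        double *op = &out(0, q);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kw - pad;
          bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + kh - pad;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H)
              v = xp[hi + H * wi + H * W * c];
            op[ho + Ho * wo] = v;
          }
        }
      }
    }
  }
  return out;
}

// Accumulating inverse of cpp_im2col: scatter-add columns back into (H, W, C).
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out(H * W * C);
  double *op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int q = kh + k * kw + k * k * c;
        double *cp = &cols(0, q);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + kh - pad;
            if (hi < 0 || hi >= H) continue;
            op[hi + H * wi + H * W * c] += cp[ho + Ho * wo];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax
// indices into the flattened input (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, int H, int W, int C) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  double *xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int hbase = 2 * ho, wbase = 2 * wo;
        int best = hbase + H * wbase + H * W * c;
        double bv = xp[best];
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            int ii = (hbase + dh) + H * (wbase + dw) + H * W * c;
            if (xp[ii] > bv) { bv = xp[ii]; best = ii; }
          }
        }
        int oi = ho + Ho * wo + Ho * Wo * c;
        y[oi] = bv;
        idx[oi] = best + 1;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}
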