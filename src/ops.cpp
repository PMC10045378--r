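#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Unfold an H x W x C array (R column-major layout) into a matrix with one
// row per output spatial position (ho + Ho*wo) and one column per
// (kernel-row, kernel-col, channel) triple (dh + k*dw + k*k*c).  Zero padding.
// With this layout a convolution is `cols %*% Wmat` for a (k*k*C) x Cout
// weight matrix.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int k,
                         int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix cols(Ho * Wo, k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[(R_xlen_t)H * W * c];
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int colIdx = dh + k * dw + k * k * c;
        double* colPtr = &cols(0, colIdx);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + dw - pad;
          bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + dh - pad;
            colPtr[ho + Ho * wo] =
                (wok && hi >= 0 && hi < H) ? xc[hi + (R_xlen_t)H * wi] : 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-add column gradients back to input layout.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int k,
                         int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    double* xc = &x[(R_xlen_t)H * W * c];
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int colIdx = dh + k * dw + k * k * c;
        const double* colPtr = &cols(0, colIdx);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + dw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + dh - pad;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (R_xlen_t)H * wi] += colPtr[ho + Ho * wo];
          }
        }
      }
    }
  }
  return x;
}

// 4-connected component labelling of a binary matrix; labels 1..n, 0 = bg.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int w0 = 0; w0 < W; ++w0) {
    for (int h0 = 0; h0 < H; ++h0) {
      if (mask(h0, w0) == 0 || lab(h0, w0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(h0 + H * w0);
      lab(h0, w0) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int h = idx % H, w = idx / H;
        const int nh[4] = {h - 1, h + 1, h, h};
        const int nw[4] = {w, w, w - 1, w + 1};
        for (int t = 0; t < 4; ++t) {
          int a = nh[t], b = nw[t];
          if (a < 0 || a >= H || b < 0 || b >= W) continue;
          if (mask(a, b) != 0 && lab(a, b) == 0) {
            lab(a, b) = next;
            stack.push_back(a + H * b);
          }
        }
      }
    }
  }
  return lab;
}
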