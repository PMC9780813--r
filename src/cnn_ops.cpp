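// Convolution and max-pooling kernels for the compact CNN. Arrays use the
// R column-major layout (H, W, C, B); convolutions are "valid"
// cross-correlations computed per image via im2col + BLAS matrix multiply.
// ReLU is fused into the convolution forward; its backward mask is applied
// at the pooled positions (max of ReLU outputs is > 0 iff the winning
// pre-activation is).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat im2col(const double* x, int H, int W, int C,
                               int k, int oH, int oW) {
  arma::mat cols(oH * oW, k * k * C);  // transposed: pixels on rows
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int col = di + k * dj + k * k * c;
        double* dst = cols.colptr(col);
        for (int j = 0; j < oW; ++j) {
          const double* src = xc + (std::size_t)(j + dj) * H + di;
          std::memcpy(dst + (std::size_t)j * oH, src,
                      sizeof(double) * oH);
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector conv_forward(NumericVector x, NumericVector w,
                           NumericVector bias, bool relu = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  int oH = H - k + 1, oW = W - k + 1;
  if (oH < 1 || oW < 1) stop("input too small for valid convolution");
  int P = oH * oW;
  NumericVector out((R_xlen_t)P * Cout * B);
  out.attr("dim") = IntegerVector::create(oH, oW, Cout, B);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  std::size_t imIn = (std::size_t)H * W * C, imOut = (std::size_t)P * Cout;
  for (int b = 0; b < B; ++b) {
    arma::mat cols = im2col(x.begin() + b * imIn, H, W, C, k, oH, oW);
    arma::mat o = cols * Wm;          // P x Cout, channels contiguous
    double* dst = out.begin() + b * imOut;
    for (int c = 0; c < Cout; ++c) {
      const double* src = o.colptr(c);
      double* d = dst + (std::size_t)c * P;
      double bc = bias[c];
      if (relu)
        for (int p = 0; p < P; ++p) { double v = src[p] + bc;
          d[p] = v > 0 ? v : 0; }
      else
        for (int p = 0; p < P; ++p) d[p] = src[p] + bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv_backward(NumericVector x, NumericVector w, NumericVector dout) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  int oH = H - k + 1, oW = W - k + 1, P = oH * oW;
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericVector dw((R_xlen_t)k * k * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  arma::mat dWm(dw.begin(), k * k * Cin, Cout, false);
  std::size_t imIn = (std::size_t)H * W * C, imOut = (std::size_t)P * Cout;
  for (int b = 0; b < B; ++b) {
    arma::mat cols = im2col(x.begin() + b * imIn, H, W, C, k, oH, oW);
    // dout for this image, P x Cout: channels are contiguous already
    arma::mat domT(const_cast<double*>(dout.begin()) + b * imOut, P, Cout,
                   false);
    dWm += cols.t() * domT;
    for (int c = 0; c < Cout; ++c)
      db[c] += arma::accu(domT.col(c));
    arma::mat dcols = domT * Wm.t();  // P x (k*k*Cin)
    // col2im scatter-add
    double* dxb = dx.begin() + b * imIn;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxb + (std::size_t)c * H * W;
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          const double* src = dcols.colptr(di + k * dj + k * k * c);
          for (int j = 0; j < oW; ++j) {
            double* dst = dxc + (std::size_t)(j + dj) * H + di;
            const double* s = src + (std::size_t)j * oH;
            for (int i = 0; i < oH; ++i) dst[i] += s[i];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_forward(NumericVector x, int size) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int oH = H / size, oW = W / size;
  if (oH < 1 || oW < 1) stop("input too small for pooling");
  NumericVector out((R_xlen_t)oH * oW * C * B);
  out.attr("dim") = IntegerVector::create(oH, oW, C, B);
  IntegerVector idx((R_xlen_t)oH * oW * C * B);  // 1-based index into x
  idx.attr("dim") = IntegerVector::create(oH, oW, C, B);
  std::size_t plane = (std::size_t)H * W;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      std::size_t off = ((std::size_t)b * C + c) * plane;
      std::size_t ooff = ((std::size_t)b * C + c) * oH * oW;
      for (int j = 0; j < oW; ++j) {
        for (int i = 0; i < oH; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t bestIdx = 0;
          for (int dj = 0; dj < size; ++dj) {
            for (int di = 0; di < size; ++di) {
              std::size_t pos = off + (std::size_t)(j * size + dj) * H +
                i * size + di;
              if (x[pos] > best) { best = x[pos]; bestIdx = pos; }
            }
          }
          out[ooff + (std::size_t)j * oH + i] = best;
          idx[ooff + (std::size_t)j * oH + i] = (int)(bestIdx + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// Scatter pooled gradients back to the conv grid, applying the ReLU mask:
// positions whose pooled activation is zero pass no gradient.
// [[Rcpp::export]]
NumericVector maxpool_backward(IntegerVector idx, NumericVector dout,
                               NumericVector poolOut, IntegerVector xdim) {
  std::size_t n = (std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx((R_xlen_t)n);
  dx.attr("dim") = xdim;
  for (R_xlen_t p = 0; p < dout.size(); ++p)
    if (poolOut[p] > 0) dx[idx[p] - 1] += dout[p];
  return dx;
}
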