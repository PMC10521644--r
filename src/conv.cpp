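#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Valid (no-padding) strided 2-D convolution for small CNN backbones,
// implemented as im2col + GEMM. Layouts follow R's column-major arrays:
//   x   : H x W x C x B   (batch of images / feature stacks)
//   w   : kh x kw x C x F (filter bank)
//   out : Ho x Wo x F x B with Ho = (H-kh)/stride+1, Wo = (W-kw)/stride+1
// The im2col patch matrix orders one patch per row, columns in the same
// (kh, kw, C) order as the filter array, so filters can be used as a
// (kh*kw*C) x F matrix without copying.

static arma::mat im2col(const double *px, int H, int W, int C, int b,
                        int kh, int kw, int stride, int Ho, int Wo) {
  arma::mat patches(Ho * Wo, kh * kw * C);
  const double *base = px + (size_t)b * H * W * C;
  int col = 0;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki, ++col) {
        double *dst = patches.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          const double *src = base + (size_t)(wo * stride + kj) * H +
                              (size_t)c * H * W + ki;
          for (int ho = 0; ho < Ho; ++ho)
            dst[ho + wo * Ho] = src[ho * stride];
        }
      }
  return patches;
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("filter channel count does not match input");
  if (H < kh || W < kw) stop("input smaller than kernel");
  const int Ho = (H - kh) / stride + 1;
  const int Wo = (W - kw) / stride + 1;

  arma::mat wm(const_cast<double *>(w.begin()), kh * kw * C, F, false, true);
  arma::rowvec bv(const_cast<double *>(b.begin()), F, false, true);

  NumericVector out(R_xlen_t(Ho) * Wo * F * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, B);
  for (int bi = 0; bi < B; ++bi) {
    arma::mat res = im2col(x.begin(), H, W, C, bi, kh, kw, stride, Ho, Wo) * wm;
    res.each_row() += bv;
    std::copy(res.begin(), res.end(), out.begin() + (size_t)bi * Ho * Wo * F);
  }
  return out;
}

// Gradients of the same convolution. dout: Ho x Wo x F x B.
// Returns list(dx, dw, db).
// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w,
                         NumericVector dout, int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector od = dout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = od[0], Wo = od[1];
  if (od[2] != F || od[3] != B) stop("dout dimensions inconsistent");

  NumericVector dx(R_xlen_t(H) * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericVector dw(R_xlen_t(kh) * kw * C * F);
  dw.attr("dim") = IntegerVector::create(kh, kw, C, F);
  NumericVector db(F);

  arma::mat wm(const_cast<double *>(w.begin()), kh * kw * C, F, false, true);
  arma::mat dwm(dw.begin(), kh * kw * C, F, false, true);
  arma::rowvec dbv(db.begin(), F, false, true);

  for (int bi = 0; bi < B; ++bi) {
    arma::mat dres(const_cast<double *>(dout.begin()) +
                   (size_t)bi * Ho * Wo * F, Ho * Wo, F, false, true);
    arma::mat patches = im2col(x.begin(), H, W, C, bi, kh, kw, stride, Ho, Wo);
    dwm += patches.t() * dres;
    dbv += arma::sum(dres, 0);
    arma::mat dpatch = dres * wm.t();  // (Ho*Wo) x (kh*kw*C)
    // col2im accumulate
    double *pdx = dx.begin() + (size_t)bi * H * W * C;
    int col = 0;
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki, ++col) {
          const double *src = dpatch.colptr(col);
          for (int wo = 0; wo < Wo; ++wo) {
            double *dst = pdx + (size_t)(wo * stride + kj) * H +
                          (size_t)c * H * W + ki;
            for (int ho = 0; ho < Ho; ++ho)
              dst[ho * stride] += src[ho + wo * Ho];
          }
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
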