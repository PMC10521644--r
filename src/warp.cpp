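#include <Rcpp.h>
using namespace Rcpp;

// Inverse-mapped affine warp of an H x W x 3 image about its centre with
// bilinear sampling and reflective out-of-frame handling. `mat` is the
// 2 x 3 inverse map: source = mat %*% c(col, row, 1) (centre-relative).

static inline double reflect1(double x, int n) {
  if (n == 1) return 1.0;
  const double period = 2.0 * (n - 1);
  double t = x - 1.0;
  t -= period * std::floor(t / period);
  if (t > n - 1) t = period - t;
  return t + 1.0;
}

// [[Rcpp::export]]
NumericVector warp_affine_cpp(NumericVector img, NumericMatrix mat) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out(R_xlen_t(H) * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  const double cy = (H + 1) / 2.0, cx = (W + 1) / 2.0;
  const double a = mat(0, 0), b = mat(0, 1), tx = mat(0, 2);
  const double c = mat(1, 0), e = mat(1, 1), ty = mat(1, 2);
  const double *src = img.begin();
  double *dst = out.begin();
  for (int wj = 0; wj < W; ++wj) {
    const double gc = wj + 1 - cx;
    for (int hi = 0; hi < H; ++hi) {
      const double gr = hi + 1 - cy;
      double sc = reflect1(a * gc + b * gr + tx + cx, W);
      double sr = reflect1(c * gc + e * gr + ty + cy, H);
      int r0 = (int)std::floor(sr); if (r0 > H - 1) r0 = H - 1; if (r0 < 1) r0 = 1;
      int c0 = (int)std::floor(sc); if (c0 > W - 1) c0 = W - 1; if (c0 < 1) c0 = 1;
      const double fr = sr - r0, fc = sc - c0;
      const size_t i00 = (size_t)(r0 - 1) + (size_t)(c0 - 1) * H;
      for (int ch = 0; ch < C; ++ch) {
        const double *p = src + (size_t)ch * H * W + i00;
        const double v = (1 - fr) * (1 - fc) * p[0] + fr * (1 - fc) * p[1] +
                         (1 - fr) * fc * p[H] + fr * fc * p[H + 1];
        dst[(size_t)hi + (size_t)wj * H + (size_t)ch * H * W] = v;
      }
    }
  }
  return out;
}
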