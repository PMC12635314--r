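#include <Rcpp.h>
using namespace Rcpp;

// Dilated 3x3 im2col / col2im. Images are H x W x C arrays stored in R's
// column-major order (fastest index = row). Zero padding outside the image.
// The column matrix has one row per output pixel (row-major over (y, x) in
// R's native array order: pixel index p = y + H * x) and 9 * C columns
// ordered tap-major: column = t + 9 * c for tap t in 0..8, channel c.
// Tap t enumerates (dy, dx) in {-1,0,1}^2 with dy fastest:
//   t = (dy + 1) + 3 * (dx + 1), offsets scaled by the dilation rate.

// [[Rcpp::export]]
NumericMatrix im2col_dilated(NumericVector x, int H, int W, int C, int rate) {
  NumericMatrix out(H * W, 9 * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *chan = px + (size_t)c * H * W;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        int t = (dy + 1) + 3 * (dx + 1);
        int col = t + 9 * c;
        double *pout = &out(0, col);
        int oy = dy * rate, ox = dx * rate;
        for (int xx = 0; xx < W; ++xx) {
          int sx = xx + ox;
          if (sx < 0 || sx >= W) continue;
          const double *src = chan + (size_t)sx * H;
          double *dst = pout + (size_t)xx * H;
          int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
          for (int yy = y0; yy < y1; ++yy) dst[yy] = src[yy + oy];
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_dilated: scatter-add a column matrix back to an image.
// Used for the gradient with respect to the convolution input.

// [[Rcpp::export]]
NumericVector col2im_dilated(NumericMatrix cols, int H, int W, int C, int rate) {
  NumericVector out((size_t)H * W * C);
  double *px = out.begin();
  for (int c = 0; c < C; ++c) {
    double *chan = px + (size_t)c * H * W;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        int t = (dy + 1) + 3 * (dx + 1);
        int col = t + 9 * c;
        const double *pin = &cols(0, col);
        int oy = dy * rate, ox = dx * rate;
        for (int xx = 0; xx < W; ++xx) {
          int sx = xx + ox;
          if (sx < 0 || sx >= W) continue;
          double *dst = chan + (size_t)sx * H;
          const double *src = pin + (size_t)xx * H;
          int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
          for (int yy = y0; yy < y1; ++yy) dst[yy + oy] += src[yy];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}
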