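// Low-level numeric kernels: 2-D convolution (im2col + GEMM) with
// TensorFlow-style 'same' padding, and image resampling (bilinear,
// bicubic, rotation) with a configurable fill value.
//
// Images and feature maps are H x W x C arma::cubes (row = image row).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 'same' padding: out = ceil(in / s); pad split with the smaller half first.
static void same_pad(const int in, const int k, const int s,
                     int& out, int& pad_beg) {
  out = (in + s - 1) / s;
  int tot = (out - 1) * s + k - in;
  if (tot < 0) tot = 0;
  pad_beg = tot / 2;
}

// Column c*k*k + kj*k + ki holds input channel c at kernel offset (ki, kj);
// row oi + out_h*oj is the output cell (oi, oj) (column-major like arma).
static arma::mat im2col(const arma::cube& x, const int k, const int s,
                        const int out_h, const int out_w,
                        const int ph, const int pw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(static_cast<arma::uword>(out_h) * out_w,
                 static_cast<arma::uword>(k) * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword col = static_cast<arma::uword>(c) * k * k + kj * k + ki;
        for (int oj = 0; oj < out_w; ++oj) {
          const int jj = oj * s - pw + kj;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < out_h; ++oi) {
            const int ii = oi * s - ph + ki;
            if (ii < 0 || ii >= H) continue;
            cols(static_cast<arma::uword>(oi) +
                 static_cast<arma::uword>(out_h) * oj, col) = x(ii, jj, c);
          }
        }
      }
  return cols;
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, const int k, const int s) {
  int out_h, out_w, ph, pw;
  same_pad(x.n_rows, k, s, out_h, ph);
  same_pad(x.n_cols, k, s, out_w, pw);
  const arma::mat cols = im2col(x, k, s, out_h, out_w, ph, pw);
  arma::mat y = cols * w;
  y.each_row() += b.t();
  arma::cube out(out_h, out_w, w.n_cols);
  for (arma::uword c = 0; c < w.n_cols; ++c)
    out.slice(c) = arma::reshape(y.col(c), out_h, out_w);
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(const arma::cube& x, const arma::mat& w, const arma::cube& dy,
               const int k, const int s) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int out_h, out_w, ph, pw;
  same_pad(H, k, s, out_h, ph);
  same_pad(W, k, s, out_w, pw);
  const int cout = dy.n_slices;

  arma::mat dY(static_cast<arma::uword>(out_h) * out_w, cout);
  for (int c = 0; c < cout; ++c)
    dY.col(c) = arma::vectorise(dy.slice(c));

  const arma::mat cols = im2col(x, k, s, out_h, out_w, ph, pw);
  const arma::mat dW = cols.t() * dY;
  const arma::vec db = arma::sum(dY, 0).t();
  const arma::mat dcols = dY * w.t();

  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword col = static_cast<arma::uword>(c) * k * k + kj * k + ki;
        for (int oj = 0; oj < out_w; ++oj) {
          const int jj = oj * s - pw + kj;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < out_h; ++oi) {
            const int ii = oi * s - ph + ki;
            if (ii < 0 || ii >= H) continue;
            dx(ii, jj, c) += dcols(static_cast<arma::uword>(oi) +
                                   static_cast<arma::uword>(out_h) * oj, col);
          }
        }
      }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

static inline double clampd(const double v, const double lo, const double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Half-pixel-centre sampling; edges clamped.
// [[Rcpp::export]]
arma::cube resize_bilinear_cpp(const arma::cube& img,
                               const int out_h, const int out_w) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  const double sy = static_cast<double>(H) / out_h;
  const double sx = static_cast<double>(W) / out_w;
  arma::cube out(out_h, out_w, C);
  for (int i = 0; i < out_h; ++i) {
    const double y = clampd((i + 0.5) * sy - 0.5, 0.0, H - 1.0);
    const int y0 = static_cast<int>(std::floor(y));
    const int y1 = std::min(y0 + 1, H - 1);
    const double fy = y - y0;
    for (int j = 0; j < out_w; ++j) {
      const double x = clampd((j + 0.5) * sx - 0.5, 0.0, W - 1.0);
      const int x0 = static_cast<int>(std::floor(x));
      const int x1 = std::min(x0 + 1, W - 1);
      const double fx = x - x0;
      for (int c = 0; c < C; ++c) {
        const double top = img(y0, x0, c) * (1 - fx) + img(y0, x1, c) * fx;
        const double bot = img(y1, x0, c) * (1 - fx) + img(y1, x1, c) * fx;
        out(i, j, c) = top * (1 - fy) + bot * fy;
      }
    }
  }
  return out;
}

// Catmull-Rom cubic kernel (a = -0.5).
static inline double cubic_w(double t) {
  t = std::fabs(t);
  if (t <= 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0)  return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

// [[Rcpp::export]]
arma::mat resize_bicubic_cpp(const arma::mat& img,
                             const int out_h, const int out_w) {
  const int H = img.n_rows, W = img.n_cols;
  const double sy = static_cast<double>(H) / out_h;
  const double sx = static_cast<double>(W) / out_w;
  arma::mat out(out_h, out_w);
  for (int i = 0; i < out_h; ++i) {
    const double y = (i + 0.5) * sy - 0.5;
    const int y0 = static_cast<int>(std::floor(y));
    double wy[4];
    for (int m = 0; m < 4; ++m) wy[m] = cubic_w(y - (y0 - 1 + m));
    for (int j = 0; j < out_w; ++j) {
      const double x = (j + 0.5) * sx - 0.5;
      const int x0 = static_cast<int>(std::floor(x));
      double wx[4], acc = 0.0;
      for (int m = 0; m < 4; ++m) wx[m] = cubic_w(x - (x0 - 1 + m));
      for (int m = 0; m < 4; ++m) {
        const int yi = std::min(std::max(y0 - 1 + m, 0), H - 1);
        for (int n = 0; n < 4; ++n) {
          const int xi = std::min(std::max(x0 - 1 + n, 0), W - 1);
          acc += wy[m] * wx[n] * img(yi, xi);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Rotation about the image centre; output keeps the input extent and
// exposed area takes `fill` (white for slides).
// [[Rcpp::export]]
arma::cube rotate_bilinear_cpp(const arma::cube& img, const double deg,
                               const double fill) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  const double th = deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  arma::cube out(H, W, C);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      // inverse map destination -> source
      const double dy = i - cy, dx = j - cx;
      const double ys = ct * dy + st * dx + cy;
      const double xs = -st * dy + ct * dx + cx;
      if (ys < 0 || ys > H - 1 || xs < 0 || xs > W - 1) {
        for (int c = 0; c < C; ++c) out(i, j, c) = fill;
        continue;
      }
      const int y0 = static_cast<int>(std::floor(ys));
      const int y1 = std::min(y0 + 1, H - 1);
      const int x0 = static_cast<int>(std::floor(xs));
      const int x1 = std::min(x0 + 1, W - 1);
      const double fy = ys - y0, fx = xs - x0;
      for (int c = 0; c < C; ++c) {
        const double top = img(y0, x0, c) * (1 - fx) + img(y0, x1, c) * fx;
        const double bot = img(y1, x0, c) * (1 - fx) + img(y1, x1, c) * fx;
        out(i, j, c) = top * (1 - fy) + bot * fy;
      }
    }
  return out;
}
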