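#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pixel arrays are column-major with dim c(width, height[, channel]):
// element (x, y, k), 0-based, sits at x + W*y + W*H*k.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Render the smooth body scene on the 8-bit gray scale: a high-saturation
// ellipse (semi-axes a, b, rotated by theta radians about (cx, cy)) on a
// low-saturation background, with a ~edge_px soft anti-aliased rim.
// [[Rcpp::export]]
NumericVector cpp_render_body(int width, int height, double cx, double cy,
                              double a, double b, double theta,
                              NumericVector body_rgb, NumericVector bg_rgb,
                              double edge_px) {
  NumericVector out(static_cast<R_xlen_t>(width) * height * 3);
  out.attr("dim") = Dimension(width, height, 3);
  const double ct = std::cos(theta), st = std::sin(theta);
  const double plane = static_cast<double>(width) * height;
  for (int y = 0; y < height; ++y) {
    for (int x = 0; x < width; ++x) {
      const double dx = x - cx, dy = y - cy;
      const double ua = ct * dx + st * dy;   // along major axis
      const double vb = -st * dx + ct * dy;  // along minor axis
      const double rr = std::sqrt((ua / a) * (ua / a) + (vb / b) * (vb / b));
      double cov = (1.0 - rr) * b / edge_px;
      if (cov < 0.0) cov = 0.0;
      if (cov > 1.0) cov = 1.0;
      const R_xlen_t i = x + static_cast<R_xlen_t>(width) * y;
      for (int k = 0; k < 3; ++k)
        out[i + static_cast<R_xlen_t>(plane) * k] =
            bg_rgb[k] + (body_rgb[k] - bg_rgb[k]) * cov;
    }
  }
  return out;
}

// Scale an 8-bit-range scene to [0, vmax], add Gaussian read noise (R's RNG,
// so set.seed() governs the draw), round half up and clamp.
// [[Rcpp::export]]
IntegerVector cpp_finalize_raw(NumericVector scene, double scale,
                               double noise_sd, int vmax) {
  const R_xlen_t n = scene.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = scene[i] * scale;
    if (noise_sd > 0.0) v += R::rnorm(0.0, noise_sd);
    int iv = static_cast<int>(std::floor(v + 0.5));
    out[i] = clampi(iv, 0, vmax);
  }
  out.attr("dim") = scene.attr("dim");
  return out;
}

// Map [0, in_max] to [0, out_max], rounding half up.
// [[Rcpp::export]]
IntegerVector cpp_normalize_range(IntegerVector px, int in_max, int out_max) {
  const R_xlen_t n = px.size();
  IntegerVector out(n);
  const double f = static_cast<double>(out_max) / in_max;
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = static_cast<int>(std::floor(px[i] * f + 0.5));
  out.attr("dim") = px.attr("dim");
  return out;
}

// HSV saturation of an 8-bit RGB array, on the 0..255 integer scale:
// S = round(255 * (max - min) / max), 0 where max == 0.
// [[Rcpp::export]]
IntegerMatrix cpp_saturation(IntegerVector rgb8, int width, int height) {
  IntegerMatrix out(width, height);
  const R_xlen_t plane = static_cast<R_xlen_t>(width) * height;
  for (R_xlen_t i = 0; i < plane; ++i) {
    const int r = rgb8[i], g = rgb8[i + plane], b = rgb8[i + 2 * plane];
    int mx = r > g ? r : g; if (b > mx) mx = b;
    int mn = r < g ? r : g; if (b < mn) mn = b;
    out[i] = mx == 0 ? 0
                     : static_cast<int>(std::floor(255.0 * (mx - mn) / mx + 0.5));
  }
  return out;
}

// Separable bilinear resample with pixel centers at (i + 0.5) * n_in / n_out - 0.5.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int w_out, int h_out) {
  const int w_in = img.nrow(), h_in = img.ncol();
  std::vector<int> xi0(w_out), xi1(w_out);
  std::vector<double> xf(w_out);
  const double sx = static_cast<double>(w_in) / w_out;
  for (int x = 0; x < w_out; ++x) {
    const double src = (x + 0.5) * sx - 0.5;
    const int i0 = static_cast<int>(std::floor(src));
    xf[x] = src - i0;
    xi0[x] = clampi(i0, 0, w_in - 1);
    xi1[x] = clampi(i0 + 1, 0, w_in - 1);
  }
  NumericMatrix tmp(w_out, h_in);
  for (int y = 0; y < h_in; ++y)
    for (int x = 0; x < w_out; ++x)
      tmp(x, y) = img(xi0[x], y) * (1.0 - xf[x]) + img(xi1[x], y) * xf[x];
  NumericMatrix out(w_out, h_out);
  const double sy = static_cast<double>(h_in) / h_out;
  for (int y = 0; y < h_out; ++y) {
    const double src = (y + 0.5) * sy - 0.5;
    int j0 = static_cast<int>(std::floor(src));
    const double f = src - j0;
    const int j0c = clampi(j0, 0, h_in - 1), j1c = clampi(j0 + 1, 0, h_in - 1);
    for (int x = 0; x < w_out; ++x)
      out(x, y) = tmp(x, j0c) * (1.0 - f) + tmp(x, j1c) * f;
  }
  return out;
}

// Per-cell gray statistics over an exact cols x rows tiling (row-major,
// 1-based cell numbering): mean, sample sd, fraction of pixels strictly below
// max(0, mean - dark_k * sd), and co-occurrence contrast at horizontal offset
// 1 px after quantization to floor(g / 8) clamped to [0, 31].
// Returns an (cols*rows) x 4 matrix in cell-index order.
// [[Rcpp::export]]
NumericMatrix cpp_grid_stats(NumericMatrix img, int cols, int rows,
                             double dark_k) {
  const int W = img.nrow(), H = img.ncol();
  const int cw = W / cols, ch = H / rows;
  NumericMatrix out(cols * rows, 4);
  for (int r = 0; r < rows; ++r) {
    for (int c = 0; c < cols; ++c) {
      const int x0 = c * cw, y0 = r * ch;
      double s1 = 0.0, s2 = 0.0;
      for (int y = y0; y < y0 + ch; ++y)
        for (int x = x0; x < x0 + cw; ++x) {
          const double v = img(x, y);
          s1 += v; s2 += v * v;
        }
      const double n = static_cast<double>(cw) * ch;
      const double mean = s1 / n;
      double var = (s2 - n * mean * mean) / (n - 1.0);
      if (var < 0.0) var = 0.0;
      const double sd = std::sqrt(var);
      double thr = mean - dark_k * sd;
      if (thr < 0.0) thr = 0.0;
      long dark = 0;
      double csum = 0.0;
      for (int y = y0; y < y0 + ch; ++y) {
        int qprev = 0;
        for (int x = x0; x < x0 + cw; ++x) {
          const double v = img(x, y);
          if (v < thr) ++dark;
          int q = static_cast<int>(std::floor(v / 8.0));
          q = clampi(q, 0, 31);
          if (x > x0) {
            const double d = q - qprev;
            csum += d * d;
          }
          qprev = q;
        }
      }
      const int k = r * cols + c;  // 0-based row-major cell index
      out(k, 0) = mean;
      out(k, 1) = sd;
      out(k, 2) = dark / n;
      out(k, 3) = csum / (static_cast<double>(cw - 1) * ch);
    }
  }
  return out;
}
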