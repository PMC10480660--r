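// Low-level image primitives shared by the simulator, the localizer and the
// reconstruction pipeline. Coordinate convention throughout: continuous
// coordinates with origin at the corner of pixel (0,0); x runs along columns
// (rightwards), y along rows (downwards). Pixel (r,c) covers [c,c+1) x [r,r+1).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double erf_half(double z) { return 0.5 * std::erf(z); }

// Integrated-Gaussian deposit of one emitter into a frame. Expected photon
// count in pixel (r,c) is N * Ex(c) * Ey(r) with
// Ex(c) = 1/2 [erf((c+1-x)/(sqrt2 s)) - erf((c-x)/(sqrt2 s))].
static void deposit_emitter(arma::mat &img, double x, double y,
                            double photons, double sigma) {
  const int H = img.n_rows, W = img.n_cols;
  const double s2 = sigma * std::sqrt(2.0);
  const int r0 = std::max(0, (int)std::floor(y - 5.0 * sigma));
  const int r1 = std::min(H - 1, (int)std::ceil(y + 5.0 * sigma));
  const int c0 = std::max(0, (int)std::floor(x - 5.0 * sigma));
  const int c1 = std::min(W - 1, (int)std::ceil(x + 5.0 * sigma));
  if (r1 < r0 || c1 < c0) return;
  for (int c = c0; c <= c1; ++c) {
    const double ex = erf_half((c + 1 - x) / s2) - erf_half((c - x) / s2);
    for (int r = r0; r <= r1; ++r) {
      const double ey = erf_half((r + 1 - y) / s2) - erf_half((r - y) / s2);
      img(r, c) += photons * ex * ey;
    }
  }
}

// Render expected-photon frames for a set of emitter instances.
// frame: 0-based frame index per instance.
// [[Rcpp::export]]
arma::cube cpp_render_frames(const arma::ivec &frame, const arma::vec &x,
                             const arma::vec &y, const arma::vec &photons,
                             double sigma, int n_frames, int H, int W) {
  arma::cube out(H, W, n_frames, arma::fill::zeros);
  for (arma::uword i = 0; i < frame.n_elem; ++i) {
    int f = frame(i);
    if (f < 0 || f >= n_frames) continue;
    arma::mat slice(out.slice_memptr(f), H, W, false, true);
    deposit_emitter(slice, x(i), y(i), photons(i), sigma);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_render_spot(double x, double y, double photons, double sigma,
                          int H, int W) {
  arma::mat img(H, W, arma::fill::zeros);
  deposit_emitter(img, x, y, photons, sigma);
  return img;
}

// 2-D histogram of continuous coordinates on an H x W grid (bin = 1 unit).
// [[Rcpp::export]]
arma::mat cpp_hist2d(const arma::vec &x, const arma::vec &y, int H, int W,
                     const arma::vec &w) {
  arma::mat out(H, W, arma::fill::zeros);
  const bool weighted = w.n_elem == x.n_elem;
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    int c = (int)std::floor(x(i));
    int r = (int)std::floor(y(i));
    if (r < 0 || r >= H || c < 0 || c >= W) continue;
    out(r, c) += weighted ? w(i) : 1.0;
  }
  return out;
}

static arma::vec gauss_kernel(double sigma) {
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec k(2 * rad + 1);
  for (int i = -rad; i <= rad; ++i)
    k(i + rad) = std::exp(-0.5 * i * i / (sigma * sigma));
  return k / arma::accu(k);
}

static inline int reflect_idx(int i, int n) {
  // symmetric (reflect-101-free) boundary: ... 2 1 0 | 0 1 2 ... n-1 | n-1 ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static arma::mat conv_sep(const arma::mat &img, const arma::vec &k) {
  const int H = img.n_rows, W = img.n_cols, rad = ((int)k.n_elem - 1) / 2;
  arma::mat tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int d = -rad; d <= rad; ++d) s += k(d + rad) * img(reflect_idx(r + d, H), c);
      tmp(r, c) = s;
    }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double s = 0;
      for (int d = -rad; d <= rad; ++d) s += k(d + rad) * tmp(r, reflect_idx(c + d, W));
      out(r, c) = s;
    }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_gauss_blur(const arma::mat &img, double sigma) {
  if (sigma <= 0) return img;
  return conv_sep(img, gauss_kernel(sigma));
}

// k x k box (mean) filter with symmetric boundary.
// [[Rcpp::export]]
arma::mat cpp_mean_filter(const arma::mat &img, int k) {
  arma::vec ker(k, arma::fill::value(1.0 / k));
  return conv_sep(img, ker);
}

// Shift an image by (dx, dy) pixels with bilinear interpolation; content moves
// by +dx rightwards / +dy downwards. Out-of-field samples take the edge value.
// [[Rcpp::export]]
arma::mat cpp_shift_bilinear(const arma::mat &img, double dx, double dy) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat out(H, W);
  for (int r = 0; r < H; ++r) {
    double ys = r - dy;
    for (int c = 0; c < W; ++c) {
      double xs = c - dx;
      double xc = std::min(std::max(xs, 0.0), (double)(W - 1));
      double yc = std::min(std::max(ys, 0.0), (double)(H - 1));
      int c0 = (int)std::floor(xc), r0 = (int)std::floor(yc);
      int c1 = std::min(c0 + 1, W - 1), r1 = std::min(r0 + 1, H - 1);
      double fx = xc - c0, fy = yc - r0;
      out(r, c) = (1 - fy) * ((1 - fx) * img(r0, c0) + fx * img(r0, c1)) +
                  fy * ((1 - fx) * img(r1, c0) + fx * img(r1, c1));
    }
  }
  return out;
}

// Bilinear resize to (H2, W2); sample positions follow the half-pixel
// convention src = (dst + 0.5) * scale - 0.5.
// [[Rcpp::export]]
arma::mat cpp_resize_bilinear(const arma::mat &img, int H2, int W2) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat out(H2, W2);
  const double sy = (double)H / H2, sx = (double)W / W2;
  for (int r = 0; r < H2; ++r) {
    double ys = (r + 0.5) * sy - 0.5;
    ys = std::min(std::max(ys, 0.0), (double)(H - 1));
    int r0 = (int)std::floor(ys), r1 = std::min(r0 + 1, H - 1);
    double fy = ys - r0;
    for (int c = 0; c < W2; ++c) {
      double xs = (c + 0.5) * sx - 0.5;
      xs = std::min(std::max(xs, 0.0), (double)(W - 1));
      int c0 = (int)std::floor(xs), c1 = std::min(c0 + 1, W - 1);
      double fx = xs - c0;
      out(r, c) = (1 - fy) * ((1 - fx) * img(r0, c0) + fx * img(r0, c1)) +
                  fy * ((1 - fx) * img(r1, c0) + fx * img(r1, c1));
    }
  }
  return out;
}

// Net-gradient spot detection (Picasso-style): a candidate is a strict local
// maximum in its 3x3 neighbourhood whose summed inward gradient projection
// over the box exceeds min_ng. Returns columns (row, col, net_gradient),
// 0-based integer pixel positions, candidates >= box/2 from borders.
// [[Rcpp::export]]
arma::mat cpp_detect_net_gradient(const arma::mat &img, int box, double min_ng) {
  const int H = img.n_rows, W = img.n_cols, rad = box / 2;
  arma::mat gx(H, W, arma::fill::zeros), gy(H, W, arma::fill::zeros);
  for (int r = 1; r < H - 1; ++r)
    for (int c = 1; c < W - 1; ++c) {
      gx(r, c) = 0.5 * (img(r, c + 1) - img(r, c - 1));
      gy(r, c) = 0.5 * (img(r + 1, c) - img(r - 1, c));
    }
  std::vector<double> rows, cols, ngs;
  for (int r = rad; r < H - rad; ++r)
    for (int c = rad; c < W - rad; ++c) {
      const double v = img(r, c);
      bool ismax = true;
      for (int dr = -1; dr <= 1 && ismax; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (!dr && !dc) continue;
          double u = img(r + dr, c + dc);
          if (u > v || (u == v && (dr < 0 || (dr == 0 && dc < 0)))) { ismax = false; break; }
        }
      if (!ismax) continue;
      double ng = 0;
      for (int dr = -rad; dr <= rad; ++dr)
        for (int dc = -rad; dc <= rad; ++dc) {
          if (!dr && !dc) continue;
          double norm = std::sqrt((double)(dr * dr + dc * dc));
          ng += (-dc * gx(r + dr, c + dc) - dr * gy(r + dr, c + dc)) / norm;
        }
      if (ng > min_ng) { rows.push_back(r); cols.push_back(c); ngs.push_back(ng); }
    }
  arma::mat out(rows.size(), 3);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i]; out(i, 1) = cols[i]; out(i, 2) = ngs[i];
  }
  return out;
}

// Local maxima of a map with intensity-weighted centroid over an nb x nb
// window ("local averaging"). Returns (row, col, value, cx, cy, mass) with
// cx, cy continuous map coordinates (pixel centre at index + 0.5).
// Only maxima with value >= min_value are returned.
// [[Rcpp::export]]
arma::mat cpp_map_maxima(const arma::mat &img, double min_value, int nb) {
  const int H = img.n_rows, W = img.n_cols, rad = nb / 2;
  std::vector<std::array<double, 6>> hits;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      const double v = img(r, c);
      if (v < min_value || v <= 0) continue;
      bool ismax = true;
      for (int dr = -1; dr <= 1 && ismax; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (!dr && !dc) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          double u = img(rr, cc);
          if (u > v || (u == v && (dr < 0 || (dr == 0 && dc < 0)))) { ismax = false; break; }
        }
      if (!ismax) continue;
      double m = 0, mx = 0, my = 0;
      for (int dr = -rad; dr <= rad; ++dr)
        for (int dc = -rad; dc <= rad; ++dc) {
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          double u = img(rr, cc);
          if (u <= 0) continue;
          m += u; mx += u * (cc + 0.5); my += u * (rr + 0.5);
        }
      if (m <= 0) { m = v; mx = v * (c + 0.5); my = v * (r + 0.5); }
      hits.push_back({(double)r, (double)c, v, mx / m, my / m, m});
    }
  arma::mat out(hits.size(), 6);
  for (size_t i = 0; i < hits.size(); ++i)
    for (int j = 0; j < 6; ++j) out(i, j) = hits[i][j];
  return out;
}
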