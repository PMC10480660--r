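// Maximum-likelihood fitting of a pixel-integrated 2-D Gaussian under a
// Poisson noise model (Fisher-scoring coordinate updates). Model for pixel
// (r, c) of a box ROI:
//   mu = N * Ex(c; x, sx) * Ey(r; y, sy) + b
//   Ex(c) = 1/2 [ erf((c+1-x)/(sqrt2 sx)) - erf((c-x)/(sqrt2 sx)) ]
// Parameters: x, y (px, ROI coordinates), N (photons), b (photons/px),
// sx, sy (px). ROI values must already be in photon units.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double SQRT2 = 1.4142135623730951;
static const double SQRT2PI = 2.5066282746310002;

struct EdgeTerms {
  arma::vec E, dC, dS; // integral, d/dcentre, d/dsigma per index
};

static EdgeTerms edge_terms(int n, double centre, double sigma) {
  EdgeTerms t;
  t.E.set_size(n); t.dC.set_size(n); t.dS.set_size(n);
  for (int i = 0; i < n; ++i) {
    double u1 = (i + 1 - centre) / sigma, u0 = (i - centre) / sigma;
    double g1 = std::exp(-0.5 * u1 * u1), g0 = std::exp(-0.5 * u0 * u0);
    t.E(i) = 0.5 * (std::erf(u1 / SQRT2) - std::erf(u0 / SQRT2));
    t.dC(i) = -(g1 - g0) / (SQRT2PI * sigma);
    t.dS(i) = -(u1 * g1 - u0 * g0) / (SQRT2PI * sigma);
  }
  return t;
}

// Fisher-scoring update for one parameter: theta += sum((x/mu-1) dmu) / sum(dmu^2/mu)
static double fisher_step(const arma::mat &roi, const arma::mat &mu,
                          const arma::mat &dmu) {
  double num = 0, den = 0;
  for (arma::uword i = 0; i < roi.n_elem; ++i) {
    double m = std::max(mu(i), 1e-9);
    num += (roi(i) / m - 1.0) * dmu(i);
    den += dmu(i) * dmu(i) / m;
  }
  if (den <= 0) return 0;
  return num / den;
}

// [[Rcpp::export]]
arma::rowvec cpp_fit_roi(const arma::mat &roi, int max_iter, double tol,
                         bool fit_sigma, double sigma0) {
  const int H = roi.n_rows, W = roi.n_cols;
  // initial values: background from border minimum statistics, centroid start
  double b = std::max(roi.min(), 1e-3);
  double N = std::max(arma::accu(roi) - b * H * W, 10.0);
  double sx = sigma0, sy = sigma0;
  double x = 0, y = 0, m = 0;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double w = std::max(roi(r, c) - b, 0.0);
      m += w; x += w * (c + 0.5); y += w * (r + 0.5);
    }
  if (m > 0) { x /= m; y /= m; } else { x = W / 2.0; y = H / 2.0; }

  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    EdgeTerms tx = edge_terms(W, x, sx), ty = edge_terms(H, y, sy);
    arma::mat EyEx = ty.E * tx.E.t();           // H x W
    arma::mat mu = N * EyEx + b;
    arma::mat dmu_x = N * (ty.E * tx.dC.t());
    arma::mat dmu_y = N * (ty.dC * tx.E.t());
    double dx = fisher_step(roi, mu, dmu_x);
    double dy = fisher_step(roi, mu, dmu_y);
    double dN = fisher_step(roi, mu, EyEx);
    arma::mat ones(H, W, arma::fill::ones);
    double db = fisher_step(roi, mu, ones);
    double dsx = 0, dsy = 0;
    if (fit_sigma) {
      arma::mat dmu_sx = N * (ty.E * tx.dS.t());
      arma::mat dmu_sy = N * (ty.dS * tx.E.t());
      dsx = fisher_step(roi, mu, dmu_sx);
      dsy = fisher_step(roi, mu, dmu_sy);
    }
    // damped, clamped updates
    x = std::min(std::max(x + dx, 0.0), (double)W);
    y = std::min(std::max(y + dy, 0.0), (double)H);
    N = std::max(N + dN, 1.0);
    b = std::max(b + db, 1e-6);
    if (fit_sigma) {
      sx = std::min(std::max(sx + 0.5 * dsx, 0.25), 5.0);
      sy = std::min(std::max(sy + 0.5 * dsy, 0.25), 5.0);
    }
    // convergence on the location/shape increments; the photon and
    // background coordinates settle more slowly but do not gate validity
    if (std::fabs(dx) < tol && std::fabs(dy) < tol &&
        std::fabs(dsx) < 10 * tol && std::fabs(dsy) < 10 * tol) {
      converged = true; break;
    }
  }
  arma::rowvec out(7);
  out(0) = x; out(1) = y; out(2) = N; out(3) = b; out(4) = sx; out(5) = sy;
  out(6) = converged ? 1.0 : 0.0;
  return out;
}

// Fit a stack of equally-sized ROIs; returns one row per ROI.
// [[Rcpp::export]]
arma::mat cpp_fit_rois(const arma::cube &rois, int max_iter, double tol,
                       bool fit_sigma, double sigma0) {
  arma::mat out(rois.n_slices, 7);
  for (arma::uword i = 0; i < rois.n_slices; ++i)
    out.row(i) = cpp_fit_roi(rois.slice(i), max_iter, tol, fit_sigma, sigma0);
  return out;
}
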