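// Fully convolutional encoder-decoder for high-density localization map
// prediction, with native training (Adam on a Gaussian-blurred MSE + L1
// sparsity loss). Layout: input already bilinearly resized to the upsampled
// grid and standardized. Architecture:
//   [conv3x3 -> BN -> ReLU -> maxpool2] x 3   (widths c1, c2, c3)
//   [nearest-up2 -> conv3x3 -> BN -> ReLU] x 3 (widths c2, c1, c1)
//   conv1x1 -> ReLU  (single nonnegative channel)
// Images are arma column-major (H x W); channel cubes are (H, W, C).
// Hot paths use fused raw-pointer loops: at these narrow channel widths the
// computation is memory-bound, not BLAS-bound.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BN_EPS = 1e-5;

// ------------------------------------------------------- 3x3 convolution ----
// Direct shifted-submatrix accumulation (zero padding). Weight layout:
// W(ci*9 + k, co), k = (dr+1) + 3*(dc+1).
// Column-blocked: one output column (all Cout channels) is accumulated in a
// cache-resident buffer while the three contributing input columns stay hot,
// so each plane is streamed once rather than 9 x Cin times.
static void conv3_fwd(const arma::cube &X, const arma::mat &Wt,
                      const arma::vec &b, arma::cube &Y) {
  const int H = X.n_rows, W = X.n_cols;
  const int Cin = X.n_slices, Cout = Wt.n_cols;
  Y.set_size(H, W, Cout);
  arma::mat acc(H, Cout);
  for (int c = 0; c < W; ++c) {
    for (int co = 0; co < Cout; ++co) acc.col(co).fill(b(co));
    for (int ci = 0; ci < Cin; ++ci)
      for (int dc = -1; dc <= 1; ++dc) {
        const int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        const double *xp = X.slice(ci).colptr(cc);
        for (int co = 0; co < Cout; ++co) {
          double *ap = acc.colptr(co);
          for (int dr = -1; dr <= 1; ++dr) {
            const double w =
                Wt((arma::uword)ci * 9 + (dr + 1) + 3 * (dc + 1), co);
            const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
            const double *xq = xp + dr;
            for (int r = r0; r <= r1; ++r) ap[r] += w * xq[r];
          }
        }
      }
    for (int co = 0; co < Cout; ++co)
      std::copy(acc.colptr(co), acc.colptr(co) + H, Y.slice(co).colptr(c));
  }
}

// Accumulates dW, db; writes dX (grad w.r.t. conv input). dX is the
// correlation of dY with the flipped kernel; dW needs column dot products.
static void conv3_bwd(const arma::cube &X, const arma::mat &Wt,
                      const arma::cube &dY, arma::mat &dW, arma::vec &db,
                      arma::cube &dX) {
  const int H = X.n_rows, W = X.n_cols;
  const int Cin = X.n_slices, Cout = Wt.n_cols;
  dX.set_size(H, W, Cin);
  for (int co = 0; co < Cout; ++co) db(co) += arma::accu(dY.slice(co));
  arma::mat acc(H, Cin);
  for (int c = 0; c < W; ++c) {
    acc.zeros();
    for (int co = 0; co < Cout; ++co)
      for (int dc = -1; dc <= 1; ++dc) {
        const int cc = c + dc; // dY column feeding dX column c (dc = -shift)
        if (cc < 0 || cc >= W) continue;
        const double *dp = dY.slice(co).colptr(cc);
        for (int ci = 0; ci < Cin; ++ci) {
          double *ap = acc.colptr(ci);
          for (int dr = -1; dr <= 1; ++dr) {
            // dX(r, c) += w(k(dr, dc_o)) * dY(r - dr, c - dc_o) with
            // dc_o = -dc (cc = c + dc is the dY column, i.e. c - dc_o)
            const double w =
                Wt((arma::uword)ci * 9 + (dr + 1) + 3 * (1 - dc), co);
            const int rlo = std::max(0, dr), rhi = H - 1 + std::min(0, dr);
            const double *dq = dp - dr;
            for (int r = rlo; r <= rhi; ++r) ap[r] += w * dq[r];
          }
        }
      }
    for (int ci = 0; ci < Cin; ++ci)
      std::copy(acc.colptr(ci), acc.colptr(ci) + H, dX.slice(ci).colptr(c));
  }
  // dW(ci*9 + k, co) += sum_r,c X(r + dr, c + dc) dY(r, c)
  for (int c = 0; c < W; ++c)
    for (int co = 0; co < Cout; ++co) {
      const double *dp = dY.slice(co).colptr(c);
      for (int ci = 0; ci < Cin; ++ci)
        for (int dc = -1; dc <= 1; ++dc) {
          const int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          const double *xp = X.slice(ci).colptr(cc);
          for (int dr = -1; dr <= 1; ++dr) {
            const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
            const double *xq = xp + dr;
            double s = 0;
            for (int r = r0; r <= r1; ++r) s += xq[r] * dp[r];
            dW((arma::uword)ci * 9 + (dr + 1) + 3 * (dc + 1), co) += s;
          }
        }
    }
}

// ------------------------------------------------------------- pooling ------
static void pool2_fwd(const arma::cube &X, arma::cube &Y, arma::ucube &idx) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  const int HX = X.n_rows;
  Y.set_size(H, W, C);
  idx.set_size(H, W, C);
  for (int ch = 0; ch < C; ++ch) {
    const arma::mat &Xs = X.slice(ch);
    for (int c = 0; c < W; ++c) {
      const double *x0 = Xs.colptr(2 * c), *x1 = Xs.colptr(2 * c + 1);
      double *yp = Y.slice(ch).colptr(c);
      arma::uword *ip = idx.slice(ch).colptr(c);
      for (int r = 0; r < H; ++r) {
        double best = x0[2 * r];
        arma::uword bi = 2 * r + (arma::uword)(2 * c) * HX;
        if (x0[2 * r + 1] > best) { best = x0[2 * r + 1]; bi = 2 * r + 1 + (arma::uword)(2 * c) * HX; }
        if (x1[2 * r] > best) { best = x1[2 * r]; bi = 2 * r + (arma::uword)(2 * c + 1) * HX; }
        if (x1[2 * r + 1] > best) { best = x1[2 * r + 1]; bi = 2 * r + 1 + (arma::uword)(2 * c + 1) * HX; }
        yp[r] = best; ip[r] = bi;
      }
    }
  }
}

static void pool2_bwd(const arma::cube &dY, const arma::ucube &idx,
                      int H, int W, arma::cube &dX) {
  dX.set_size(H, W, dY.n_slices);
  dX.zeros();
  for (arma::uword ch = 0; ch < dY.n_slices; ++ch) {
    double *base = dX.slice(ch).memptr();
    const arma::mat &dYs = dY.slice(ch);
    const arma::umat &is = idx.slice(ch);
    for (arma::uword c = 0; c < dY.n_cols; ++c)
      for (arma::uword r = 0; r < dY.n_rows; ++r)
        base[is(r, c)] += dYs(r, c);
  }
}

static void up2_fwd(const arma::cube &X, arma::cube &Y) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  Y.set_size(2 * H, 2 * W, C);
  for (int ch = 0; ch < C; ++ch) {
    const arma::mat &Xs = X.slice(ch);
    arma::mat &Ys = Y.slice(ch);
    for (int c = 0; c < W; ++c) {
      const double *xp = Xs.colptr(c);
      double *y0 = Ys.colptr(2 * c), *y1 = Ys.colptr(2 * c + 1);
      for (int r = 0; r < H; ++r) {
        const double v = xp[r];
        y0[2 * r] = v; y0[2 * r + 1] = v; y1[2 * r] = v; y1[2 * r + 1] = v;
      }
    }
  }
}

static void up2_bwd(const arma::cube &dY, arma::cube &dX) {
  const int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  dX.set_size(H, W, C);
  for (int ch = 0; ch < C; ++ch) {
    const arma::mat &dYs = dY.slice(ch);
    arma::mat &dXs = dX.slice(ch);
    for (int c = 0; c < W; ++c) {
      const double *y0 = dYs.colptr(2 * c), *y1 = dYs.colptr(2 * c + 1);
      double *xp = dXs.colptr(c);
      for (int r = 0; r < H; ++r)
        xp[r] = y0[2 * r] + y0[2 * r + 1] + y1[2 * r] + y1[2 * r + 1];
    }
  }
}

// ---------------------------------------------------------------- blur ------
static arma::vec gauss_kernel1d(double sigma) {
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec k(2 * rad + 1);
  for (int i = -rad; i <= rad; ++i)
    k(i + rad) = std::exp(-0.5 * i * i / (sigma * sigma));
  return k / arma::accu(k);
}

static arma::mat blur_same(const arma::mat &img, const arma::vec &k) {
  const int H = img.n_rows, W = img.n_cols, rad = ((int)k.n_elem - 1) / 2;
  arma::mat tmp(H, W, arma::fill::zeros), out(H, W, arma::fill::zeros);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int d = -rad; d <= rad; ++d) {
        int rr = r + d;
        if (rr >= 0 && rr < H) s += k(d + rad) * img(rr, c);
      }
      tmp(r, c) = s;
    }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double s = 0;
      for (int d = -rad; d <= rad; ++d) {
        int cc = c + d;
        if (cc >= 0 && cc < W) s += k(d + rad) * tmp(r, cc);
      }
      out(r, c) = s;
    }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_blur_zero(const arma::mat &img, double sigma) {
  if (sigma <= 0) return img;
  return blur_same(img, gauss_kernel1d(sigma));
}

// ------------------------------------------------------------- model --------
struct BNLayer { arma::vec g, be, rm, rv; };
struct ConvLayer { arma::mat W; arma::vec b; BNLayer bn; };

struct Net {
  std::array<ConvLayer, 6> L; // e1 e2 e3 d1 d2 d3
  arma::vec oW; double ob;
  arma::ivec widths;
};

static Net net_from_list(const List &p) {
  Net n;
  const char *nm[6] = {"e1", "e2", "e3", "d1", "d2", "d3"};
  for (int i = 0; i < 6; ++i) {
    std::string s(nm[i]);
    n.L[i].W = as<arma::mat>(p[s + "_W"]);
    n.L[i].b = as<arma::vec>(p[s + "_b"]);
    n.L[i].bn.g = as<arma::vec>(p[s + "_g"]);
    n.L[i].bn.be = as<arma::vec>(p[s + "_be"]);
    n.L[i].bn.rm = as<arma::vec>(p[s + "_rm"]);
    n.L[i].bn.rv = as<arma::vec>(p[s + "_rv"]);
  }
  n.oW = as<arma::vec>(p["o_W"]);
  n.ob = as<double>(p["o_b"]);
  n.widths = as<arma::ivec>(p["widths"]);
  return n;
}

static List net_to_list(const Net &n) {
  List p;
  const char *nm[6] = {"e1", "e2", "e3", "d1", "d2", "d3"};
  for (int i = 0; i < 6; ++i) {
    std::string s(nm[i]);
    p[s + "_W"] = n.L[i].W; p[s + "_b"] = n.L[i].b;
    p[s + "_g"] = n.L[i].bn.g; p[s + "_be"] = n.L[i].bn.be;
    p[s + "_rm"] = n.L[i].bn.rm; p[s + "_rv"] = n.L[i].bn.rv;
  }
  p["o_W"] = n.oW; p["o_b"] = n.ob; p["widths"] = n.widths;
  return p;
}

// Single 3x3 convolution layer (zero padding), exposed for oracle tests.
// [[Rcpp::export]]
arma::cube cpp_conv3(const arma::cube &X, const arma::mat &Wt,
                     const arma::vec &b) {
  arma::cube Y;
  conv3_fwd(X, Wt, b, Y);
  return Y;
}

// He-normal initialization, deterministic in seed.
// [[Rcpp::export]]
List cpp_cnn_init(const arma::ivec &widths, int seed) {
  std::mt19937 rng(seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  Net n; n.widths = widths;
  const int c1 = widths(0), c2 = widths(1), c3 = widths(2);
  int cin[6] = {1, c1, c2, c3, c2, c1};
  int cout[6] = {c1, c2, c3, c2, c1, c1};
  for (int i = 0; i < 6; ++i) {
    const int fan_in = cin[i] * 9;
    n.L[i].W.set_size(fan_in, cout[i]);
    const double sd = std::sqrt(2.0 / fan_in);
    for (arma::uword j = 0; j < n.L[i].W.n_elem; ++j) n.L[i].W(j) = sd * nd(rng);
    n.L[i].b.zeros(cout[i]);
    n.L[i].bn.g.ones(cout[i]); n.L[i].bn.be.zeros(cout[i]);
    n.L[i].bn.rm.zeros(cout[i]); n.L[i].bn.rv.ones(cout[i]);
  }
  n.oW.set_size(c1);
  const double sd = std::sqrt(2.0 / c1);
  for (int j = 0; j < c1; ++j) n.oW(j) = sd * nd(rng);
  n.ob = 0.01; // keep output ReLU initially alive
  return net_to_list(n);
}

// per-layer forward caches for one batch (buffers reused across batches)
struct LayerCache {
  std::vector<arma::cube> z;      // conv output, pre-BN
  std::vector<arma::cube> a;      // post BN+ReLU
  std::vector<arma::cube> upin;   // decoder: upsampled conv input
  std::vector<arma::cube> pooled; // encoder: pooled output
  std::vector<arma::ucube> poolidx;
  arma::vec mean, invstd;
};

// Fused BN (+ ReLU) over a batch; reads z, writes a.
static void bn_relu_fwd(LayerCache &cc, BNLayer &bn, int B, bool training,
                        double momentum) {
  const int C = cc.z[0].n_slices;
  const arma::uword n_px = cc.z[0].n_rows * cc.z[0].n_cols;
  const double M = (double)n_px * B;
  cc.mean.set_size(C); cc.invstd.set_size(C);
  for (int i = 0; i < B; ++i)
    cc.a[i].set_size(cc.z[i].n_rows, cc.z[i].n_cols, cc.z[i].n_slices);
  for (int ch = 0; ch < C; ++ch) {
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int i = 0; i < B; ++i) {
        const double *zp = cc.z[i].slice_memptr(ch);
        for (arma::uword j = 0; j < n_px; ++j) { s += zp[j]; s2 += zp[j] * zp[j]; }
      }
      mu = s / M; var = s2 / M - mu * mu;
      if (var < 0) var = 0;
      bn.rm(ch) = (1 - momentum) * bn.rm(ch) + momentum * mu;
      bn.rv(ch) = (1 - momentum) * bn.rv(ch) + momentum * var;
    } else {
      mu = bn.rm(ch); var = bn.rv(ch);
    }
    const double is = 1.0 / std::sqrt(var + BN_EPS);
    cc.mean(ch) = mu; cc.invstd(ch) = is;
    const double g = bn.g(ch), be = bn.be(ch);
    for (int i = 0; i < B; ++i) {
      const double *zp = cc.z[i].slice_memptr(ch);
      double *ap = cc.a[i].slice_memptr(ch);
      for (arma::uword j = 0; j < n_px; ++j) {
        const double v = (zp[j] - mu) * is * g + be;
        ap[j] = v > 0 ? v : 0.0;
      }
    }
  }
}

// Fused BN+ReLU backward: dout (grad w.r.t. a) is rewritten to grad w.r.t. z.
static void bn_relu_bwd(const LayerCache &cc, const BNLayer &bn, int B,
                        std::vector<arma::cube> &dout, arma::vec &dg,
                        arma::vec &dbe) {
  const int C = cc.z[0].n_slices;
  const arma::uword n_px = cc.z[0].n_rows * cc.z[0].n_cols;
  const double M = (double)n_px * B;
  for (int ch = 0; ch < C; ++ch) {
    const double g = bn.g(ch), mu = cc.mean(ch), is = cc.invstd(ch);
    double sum_dy = 0, sum_dyx = 0;
    for (int i = 0; i < B; ++i) {
      double *dp = dout[i].slice_memptr(ch);
      const double *ap = cc.a[i].slice_memptr(ch);
      const double *zp = cc.z[i].slice_memptr(ch);
      for (arma::uword j = 0; j < n_px; ++j) {
        if (ap[j] <= 0) { dp[j] = 0; continue; }
        sum_dy += dp[j];
        sum_dyx += dp[j] * (zp[j] - mu) * is;
      }
    }
    dg(ch) += sum_dyx; dbe(ch) += sum_dy;
    const double sdy = sum_dy / M, sdyx = sum_dyx / M, gis = g * is;
    for (int i = 0; i < B; ++i) {
      double *dp = dout[i].slice_memptr(ch);
      const double *zp = cc.z[i].slice_memptr(ch);
      for (arma::uword j = 0; j < n_px; ++j)
        dp[j] = gis * (dp[j] - sdy - (zp[j] - mu) * is * sdyx);
    }
  }
}

struct AdamState {
  std::vector<arma::mat> mW, vW;
  std::vector<arma::vec> mb, vb, mg, vg, mbe, vbe;
  arma::vec moW, voW; double mob = 0, vob = 0;
  long t = 0;
};

static void adam_upd_mat(arma::mat &w, const arma::mat &g, arma::mat &m,
                         arma::mat &v, double lr, double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8);
}
static void adam_upd_vec(arma::vec &w, const arma::vec &g, arma::vec &m,
                         arma::vec &v, double lr, double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8);
}

struct FwdState {
  std::array<LayerCache, 6> cache;
  std::vector<arma::cube> x0;        // 1-channel aliases of the inputs
  std::vector<arma::mat> pre_out, out;
};

// conv input of layer l for sample i (x0 and caches must be filled)
static const arma::cube *conv_input(FwdState &st, int l, int i) {
  if (l == 0) return &st.x0[i];
  if (l < 3) return &st.cache[l - 1].pooled[i];
  return &st.cache[l].upin[i];
}

// Full forward for one batch of equally-sized images.
static void net_forward(Net &net, const std::vector<arma::mat> &x,
                        bool training, double momentum, FwdState &st) {
  const int B = x.size();
  st.x0.resize(B);
  for (int i = 0; i < B; ++i) { // 1-channel copy of x[i] (owned memory)
    st.x0[i].set_size(x[i].n_rows, x[i].n_cols, 1);
    st.x0[i].slice(0) = x[i];
  }
  for (int l = 0; l < 6; ++l) {
    LayerCache &cc = st.cache[l];
    cc.z.resize(B); cc.a.resize(B);
    const bool enc = l < 3;
    if (!enc) {
      cc.upin.resize(B);
      for (int i = 0; i < B; ++i)
        up2_fwd(l == 3 ? st.cache[2].pooled[i] : st.cache[l - 1].a[i],
                cc.upin[i]);
    }
    for (int i = 0; i < B; ++i)
      conv3_fwd(*conv_input(st, l, i), net.L[l].W, net.L[l].b, cc.z[i]);
    bn_relu_fwd(cc, net.L[l].bn, B, training, momentum);
    if (enc) {
      cc.pooled.resize(B); cc.poolidx.resize(B);
      for (int i = 0; i < B; ++i)
        pool2_fwd(cc.a[i], cc.pooled[i], cc.poolidx[i]);
    }
  }
  // 1x1 output conv + ReLU
  st.pre_out.resize(B); st.out.resize(B);
  for (int i = 0; i < B; ++i) {
    const arma::cube &A = st.cache[5].a[i];
    arma::mat o(A.n_rows, A.n_cols, arma::fill::value(net.ob));
    for (arma::uword ch = 0; ch < A.n_slices; ++ch) o += net.oW(ch) * A.slice(ch);
    st.pre_out[i] = o;
    st.out[i] = arma::clamp(o, 0.0, arma::datum::inf);
  }
}

// [[Rcpp::export]]
List cpp_cnn_train(List params, const arma::cube &x, const arma::cube &y,
                   List cfg) {
  Net net = net_from_list(params);
  const int epochs = as<int>(cfg["epochs"]);
  const int batch = as<int>(cfg["batch_size"]);
  const double lr = as<double>(cfg["learning_rate"]);
  const double l1w = as<double>(cfg["l1_weight"]);
  const double vs = as<double>(cfg["val_split"]);
  const double blur_sigma = as<double>(cfg["loss_blur_sigma_px"]);
  const int seed = as<int>(cfg["seed"]);
  const bool verbose = as<bool>(cfg["verbose"]);
  const int N = x.n_slices;
  const arma::vec bk = gauss_kernel1d(blur_sigma);

  std::mt19937 rng(seed);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::shuffle(idx.begin(), idx.end(), rng);
  int n_val = (int)std::floor(vs * N);
  if (n_val >= N) n_val = N - 1;
  std::vector<int> val(idx.end() - n_val, idx.end());
  std::vector<int> train(idx.begin(), idx.end() - n_val);

  AdamState st;
  st.mW.resize(6); st.vW.resize(6); st.mb.resize(6); st.vb.resize(6);
  st.mg.resize(6); st.vg.resize(6); st.mbe.resize(6); st.vbe.resize(6);
  for (int l = 0; l < 6; ++l) {
    st.mW[l].zeros(arma::size(net.L[l].W)); st.vW[l].zeros(arma::size(net.L[l].W));
    st.mb[l].zeros(net.L[l].b.n_elem); st.vb[l].zeros(net.L[l].b.n_elem);
    st.mg[l].zeros(net.L[l].bn.g.n_elem); st.vg[l].zeros(net.L[l].bn.g.n_elem);
    st.mbe[l].zeros(net.L[l].bn.be.n_elem); st.vbe[l].zeros(net.L[l].bn.be.n_elem);
  }
  st.moW.zeros(net.oW.n_elem); st.voW.zeros(net.oW.n_elem);

  FwdState fs;
  arma::vec hist_train(epochs, arma::fill::zeros), hist_val(epochs, arma::fill::zeros);
  std::vector<arma::cube> dcur, dtmp;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(train.begin(), train.end(), rng);
    double ep_loss = 0; int n_batches = 0;
    for (size_t b0 = 0; b0 < train.size(); b0 += batch) {
      const int B = std::min((size_t)batch, train.size() - b0);
      std::vector<arma::mat> xb(B);
      for (int i = 0; i < B; ++i) xb[i] = x.slice(train[b0 + i]);
      net_forward(net, xb, true, 0.1, fs);
      // loss + gradient at output (1/B batch averaging enters here once)
      const double npix = fs.out[0].n_elem;
      double loss = 0;
      std::vector<arma::mat> dout(B);
      for (int i = 0; i < B; ++i) {
        const arma::mat yb = y.slice(train[b0 + i]); // blurred by caller
        arma::mat gp = blur_same(fs.out[i], bk);
        arma::mat resid = gp - yb;
        loss += arma::accu(resid % resid) / npix + l1w * arma::accu(fs.out[i]) / npix;
        arma::mat d = blur_same(resid, bk) * (2.0 / npix);
        d += l1w / npix;
        d %= arma::conv_to<arma::mat>::from(fs.pre_out[i] > 0); // output ReLU
        dout[i] = d / B;
      }
      loss /= B;
      if (!std::isfinite(loss))
        stop("training diverged: non-finite loss at epoch %d", ep + 1);
      ep_loss += loss; ++n_batches;

      // backward through output 1x1 conv
      arma::vec doW(net.oW.n_elem, arma::fill::zeros); double dob = 0;
      dcur.resize(B);
      for (int i = 0; i < B; ++i) {
        const arma::cube &A = fs.cache[5].a[i];
        dcur[i].set_size(A.n_rows, A.n_cols, A.n_slices);
        for (arma::uword ch = 0; ch < A.n_slices; ++ch) {
          doW(ch) += arma::accu(dout[i] % A.slice(ch));
          dcur[i].slice(ch) = net.oW(ch) * dout[i];
        }
        dob += arma::accu(dout[i]);
      }
      // backward through conv blocks
      std::array<arma::mat, 6> dW; std::array<arma::vec, 6> db, dg, dbe;
      dtmp.resize(B);
      for (int l = 5; l >= 0; --l) {
        LayerCache &cc = fs.cache[l];
        dW[l].zeros(arma::size(net.L[l].W)); db[l].zeros(net.L[l].b.n_elem);
        dg[l].zeros(net.L[l].bn.g.n_elem); dbe[l].zeros(net.L[l].bn.be.n_elem);
        const bool enc = l < 3;
        if (enc) { // incoming dcur refers to the pooled output
          for (int i = 0; i < B; ++i) {
            pool2_bwd(dcur[i], cc.poolidx[i], cc.a[i].n_rows, cc.a[i].n_cols,
                      dtmp[i]);
            std::swap(dcur[i], dtmp[i]);
          }
        }
        bn_relu_bwd(cc, net.L[l].bn, B, dcur, dg[l], dbe[l]);
        for (int i = 0; i < B; ++i) {
          conv3_bwd(*conv_input(fs, l, i), net.L[l].W, dcur[i], dW[l], db[l],
                    dtmp[i]);
          std::swap(dcur[i], dtmp[i]);
        }
        if (!enc) { // undo the upsample that fed this layer
          for (int i = 0; i < B; ++i) {
            up2_bwd(dcur[i], dtmp[i]);
            std::swap(dcur[i], dtmp[i]);
          }
        }
      }
      // Adam step (dcur already carried the 1/B factor)
      st.t += 1;
      const double bc1 = 1.0 - std::pow(0.9, (double)st.t);
      const double bc2 = 1.0 - std::pow(0.999, (double)st.t);
      for (int l = 0; l < 6; ++l) {
        adam_upd_mat(net.L[l].W, dW[l], st.mW[l], st.vW[l], lr, bc1, bc2);
        adam_upd_vec(net.L[l].b, db[l], st.mb[l], st.vb[l], lr, bc1, bc2);
        adam_upd_vec(net.L[l].bn.g, dg[l], st.mg[l], st.vg[l], lr, bc1, bc2);
        adam_upd_vec(net.L[l].bn.be, dbe[l], st.mbe[l], st.vbe[l], lr, bc1, bc2);
      }
      adam_upd_vec(net.oW, doW, st.moW, st.voW, lr, bc1, bc2);
      st.mob = 0.9 * st.mob + 0.1 * dob;
      st.vob = 0.999 * st.vob + 0.001 * dob * dob;
      net.ob -= lr * (st.mob / bc1) / (std::sqrt(st.vob / bc2) + 1e-8);
    }
    hist_train(ep) = ep_loss / std::max(1, n_batches);
    // validation loss with running statistics
    if (!val.empty()) {
      double vloss = 0;
      for (size_t b0 = 0; b0 < val.size(); b0 += batch) {
        const int B = std::min((size_t)batch, val.size() - b0);
        std::vector<arma::mat> xb(B);
        for (int i = 0; i < B; ++i) xb[i] = x.slice(val[b0 + i]);
        net_forward(net, xb, false, 0.0, fs);
        const double npix = fs.out[0].n_elem;
        for (int i = 0; i < B; ++i) {
          const arma::mat yb = y.slice(val[b0 + i]);
          arma::mat resid = blur_same(fs.out[i], bk) - yb;
          vloss += arma::accu(resid % resid) / npix +
                   l1w * arma::accu(fs.out[i]) / npix;
        }
      }
      hist_val(ep) = vloss / val.size();
    }
    if (verbose)
      Rprintf("epoch %3d/%d  train %.6g  val %.6g\n", ep + 1, epochs,
              hist_train(ep), hist_val(ep));
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = net_to_list(net),
                      _["train_loss"] = hist_train, _["val_loss"] = hist_val,
                      _["n_train"] = (int)train.size(), _["n_val"] = (int)val.size());
}

// Predict maps for a stack of already-resized, standardized frames.
// [[Rcpp::export]]
arma::cube cpp_cnn_predict(List params, const arma::cube &x) {
  Net net = net_from_list(params);
  FwdState fs;
  arma::cube out(x.n_rows, x.n_cols, x.n_slices);
  for (arma::uword i = 0; i < x.n_slices; ++i) {
    std::vector<arma::mat> xb(1, x.slice(i));
    net_forward(net, xb, false, 0.0, fs);
    out.slice(i) = fs.out[0];
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
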