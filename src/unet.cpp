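// A compact CPU implementation of the asymmetric UNet used for the
// nuclei/cytoplasm/background pixel classifier, written directly on top of
// single-precision BLAS (RcppArmadillo). Feature maps are stored as
// (channels x pixels) matrices with column-major pixel index p = r + H*c;
// 3x3 convolutions use im2col + sgemm with mirror (reflect-101) padding, so
// a constant input propagates to an exactly constant output. Upsampling is
// a stride-2 2x2 transposed convolution; odd encoder sizes are handled by
// ceil-mode pooling and crop-to-target after each upsampling. Training is
// Adam on the weighted per-channel RMSD loss evaluated on the central core
// of each tile; dropout masks and weight initialization draw from R's RNG,
// so runs are reproducible under set.seed().
//
// Encoder widths 32/64/128/128/256 (3x3 conv + ReLU, 2x2 ceil max-pool after
// each), three 0.5-dropout sites (bottleneck and the two deepest skip
// concatenations), skip concatenations at the 1/2, 1/4 and 1/8 resolutions
// (channel sums 160/192/256), and a 1x1 sigmoid head with 3 channels.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
#include <vector>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;

static const int NCONV3 = 13;   // 5 encoder + 8 decoder 3x3 convs
static const int NDECONV = 5;
static const int NPAR = NCONV3 + NDECONV + 1;  // + 1x1 output conv

// (cin, cout) per parameterized layer, in storage order:
// 0-4 encoder convs, 5-12 decoder convs, 13-17 deconvs, 18 output 1x1.
static const int CIN[NPAR]  = {1, 32, 64, 128, 128,
                               256, 128, 256, 128, 192, 128, 160, 64,
                               256, 128, 128, 128, 64,
                               64};
static const int COUT[NPAR] = {32, 64, 128, 128, 256,
                               128, 128, 128, 128, 128, 128, 64, 64,
                               256, 128, 128, 128, 64,
                               3};

struct UNet {
  std::vector<fmat> W, dW, mW, vW;
  std::vector<fvec> b, db, mb, vb;
  long adam_t = 0;
  // cached im2col neighbor indices per (H, W): 9 vectors of pixel indices
  std::map<long long, std::vector<arma::uvec>> idxcache;

  const std::vector<arma::uvec> &neighbors(int H, int Wd) {
    long long key = (long long)H * 1000000LL + Wd;
    auto it = idxcache.find(key);
    if (it != idxcache.end()) return it->second;
    std::vector<arma::uvec> v(9);
    int n = H * Wd, k = 0;
    for (int dc = -1; dc <= 1; ++dc) for (int dr = -1; dr <= 1; ++dr, ++k) {
      arma::uvec idx(n);
      for (int c = 0; c < Wd; ++c) {
        int cc = c + dc;
        if (cc < 0) cc = (Wd == 1) ? 0 : -cc;
        if (cc >= Wd) cc = (Wd == 1) ? 0 : 2 * Wd - 2 - cc;
        for (int r = 0; r < H; ++r) {
          int rr = r + dr;
          if (rr < 0) rr = (H == 1) ? 0 : -rr;
          if (rr >= H) rr = (H == 1) ? 0 : 2 * H - 2 - rr;
          idx[r + H * c] = rr + H * cc;
        }
      }
      v[k] = std::move(idx);
    }
    return idxcache.emplace(key, std::move(v)).first->second;
  }
};

static void im2col3(UNet &net, const fmat &A, int H, int Wd, fmat &K) {
  const int cin = A.n_rows, n = H * Wd;
  K.set_size(9 * cin, n);
  const auto &nb = net.neighbors(H, Wd);
  for (int k = 0; k < 9; ++k) {
    const arma::uvec &idx = nb[k];
    for (int p = 0; p < n; ++p)
      std::memcpy(K.colptr(p) + k * cin, A.colptr(idx[p]),
                  cin * sizeof(float));
  }
}

static void col2im3_add(UNet &net, const fmat &G, int H, int Wd, fmat &dA) {
  const int cin = dA.n_rows, n = H * Wd;
  const auto &nb = net.neighbors(H, Wd);
  for (int k = 0; k < 9; ++k) {
    const arma::uvec &idx = nb[k];
    const float *src;
    for (int p = 0; p < n; ++p) {
      src = G.colptr(p) + k * cin;
      float *dst = dA.colptr(idx[p]);
      for (int c = 0; c < cin; ++c) dst[c] += src[c];
    }
  }
}

// ceil-mode 2x2 stride-2 max pooling; records winner pixel index per cell
static void maxpool(const fmat &A, int H, int Wd, fmat &out, arma::umat &win) {
  const int C = A.n_rows, Ho = (H + 1) / 2, Wo = (Wd + 1) / 2;
  out.set_size(C, Ho * Wo);
  win.set_size(C, Ho * Wo);
  for (int co = 0; co < Wo; ++co) for (int ro = 0; ro < Ho; ++ro) {
    int po = ro + Ho * co;
    int r0 = 2 * ro, c0 = 2 * co;
    int nr = std::min(2, H - r0), nc = std::min(2, Wd - c0);
    float *o = out.colptr(po);
    uword *wv = win.colptr(po);
    const float *first = A.colptr(r0 + H * c0);
    uword pfirst = r0 + H * c0;
    for (int ch = 0; ch < C; ++ch) { o[ch] = first[ch]; wv[ch] = pfirst; }
    for (int dc = 0; dc < nc; ++dc) for (int dr = 0; dr < nr; ++dr) {
      if (dr == 0 && dc == 0) continue;
      uword p = (r0 + dr) + H * (c0 + dc);
      const float *a = A.colptr(p);
      for (int ch = 0; ch < C; ++ch)
        if (a[ch] > o[ch]) { o[ch] = a[ch]; wv[ch] = p; }
    }
  }
}

static void maxpool_back(const fmat &dOut, const arma::umat &win, fmat &dA) {
  const int C = dOut.n_rows;
  for (uword po = 0; po < dOut.n_cols; ++po) {
    const float *g = dOut.colptr(po);
    const uword *wv = win.colptr(po);
    for (int ch = 0; ch < C; ++ch) dA(ch, wv[ch]) += g[ch];
  }
}

// 2x2 stride-2 transposed convolution, then crop to (Ht, Wt)
static void deconv_fwd(const fmat &Wt4, const fvec &bb, const fmat &A, int H,
                       int Wd, int Hcrop, int Wcrop, fmat &out) {
  const int cout = Wt4.n_rows / 4;
  fmat Z = Wt4 * A;  // (4*cout) x (H*Wd)
  out.set_size(cout, Hcrop * Wcrop);
  out.zeros();
  for (int c = 0; c < Wd; ++c) for (int r = 0; r < H; ++r) {
    const float *z = Z.colptr(r + H * c);
    for (int dc = 0; dc < 2; ++dc) for (int dr = 0; dr < 2; ++dr) {
      int ro = 2 * r + dr, co = 2 * c + dc;
      if (ro >= Hcrop || co >= Wcrop) continue;
      float *o = out.colptr(ro + Hcrop * co);
      const float *zb = z + (dr + 2 * dc) * cout;
      for (int ch = 0; ch < cout; ++ch) o[ch] = zb[ch] + bb[ch];
    }
  }
}

static void deconv_back(const fmat &Wt4, const fmat &A, const fmat &dOut,
                        int H, int Wd, int Hcrop, int Wcrop, fmat &dWt4,
                        fvec &dbb, fmat &dA) {
  const int cout = Wt4.n_rows / 4;
  fmat dZ(4 * cout, H * Wd, arma::fill::zeros);
  for (int c = 0; c < Wd; ++c) for (int r = 0; r < H; ++r) {
    float *z = dZ.colptr(r + H * c);
    for (int dc = 0; dc < 2; ++dc) for (int dr = 0; dr < 2; ++dr) {
      int ro = 2 * r + dr, co = 2 * c + dc;
      if (ro >= Hcrop || co >= Wcrop) continue;
      const float *g = dOut.colptr(ro + Hcrop * co);
      float *zb = z + (dr + 2 * dc) * cout;
      for (int ch = 0; ch < cout; ++ch) zb[ch] = g[ch];
    }
  }
  dWt4 += dZ * A.t();
  for (int ch = 0; ch < cout; ++ch) dbb[ch] += arma::accu(dOut.row(ch));
  dA = Wt4.t() * dZ;
}

struct Caches {
  int H[6], Wd[6];                 // pyramid sizes, level 0 = input
  fmat A0, x[5], p[5];             // encoder conv outputs and pooled maps
  arma::umat win[5];
  fmat drop0, u1, c1, u2, c2, k1, d1, c3, u3, c4, k2, d2, c5, u4, c6, k3, c7,
      u5, c8, P;
  fmat m0, m1, m2;                 // dropout masks
  std::vector<fmat> K;             // im2col of each conv input (for backward)
  Caches() : K(NCONV3) {}
};

static void dropout_mask(fmat &m, uword nr, uword nc, double rate) {
  m.set_size(nr, nc);
  float scale = 1.0f / (1.0f - (float)rate);
  for (uword i = 0; i < m.n_elem; ++i)
    m[i] = (unif_rand() < rate) ? 0.0f : scale;
}

static fmat conv3(UNet &net, int li, const fmat &A, int H, int Wd, fmat &K,
                  bool relu) {
  im2col3(net, A, H, Wd, K);
  fmat Z = net.W[li] * K;
  Z.each_col() += net.b[li];
  if (relu) Z.transform([](float v) { return v > 0 ? v : 0.0f; });
  return Z;
}

// Gradient through a conv3+ReLU: dOut is the gradient at the (post-ReLU)
// output `out`; returns gradient w.r.t. the layer input.
static fmat conv3_back(UNet &net, int li, const fmat &out, const fmat &K,
                       fmat dOut, int H, int Wd, bool relu, int cin) {
  if (relu)
    for (uword i = 0; i < dOut.n_elem; ++i)
      if (out[i] <= 0) dOut[i] = 0;
  net.dW[li] += dOut * K.t();
  net.db[li] += arma::sum(dOut, 1);
  fmat G = net.W[li].t() * dOut;  // (9*cin) x n
  fmat dA(cin, H * Wd, arma::fill::zeros);
  col2im3_add(net, G, H, Wd, dA);
  return dA;
}

static void forward(UNet &net, Caches &cc, const fmat &input, int H, int Wd,
                    bool training, double dropout_rate) {
  cc.H[0] = H; cc.Wd[0] = Wd;
  for (int l = 1; l <= 5; ++l) {
    cc.H[l] = (cc.H[l - 1] + 1) / 2;
    cc.Wd[l] = (cc.Wd[l - 1] + 1) / 2;
  }
  cc.A0 = input;
  const fmat *in = &cc.A0;
  for (int l = 0; l < 5; ++l) {
    cc.x[l] = conv3(net, l, *in, cc.H[l], cc.Wd[l], cc.K[l], true);
    maxpool(cc.x[l], cc.H[l], cc.Wd[l], cc.p[l], cc.win[l]);
    in = &cc.p[l];
  }
  if (training) {
    dropout_mask(cc.m0, cc.p[4].n_rows, cc.p[4].n_cols, dropout_rate);
    cc.drop0 = cc.p[4] % cc.m0;
  } else cc.drop0 = cc.p[4];

  deconv_fwd(net.W[13], net.b[13], cc.drop0, cc.H[5], cc.Wd[5], cc.H[4],
             cc.Wd[4], cc.u1);
  cc.c1 = conv3(net, 5, cc.u1, cc.H[4], cc.Wd[4], cc.K[5], true);
  deconv_fwd(net.W[14], net.b[14], cc.c1, cc.H[4], cc.Wd[4], cc.H[3],
             cc.Wd[3], cc.u2);
  cc.c2 = conv3(net, 6, cc.u2, cc.H[3], cc.Wd[3], cc.K[6], true);
  cc.k1 = arma::join_cols(cc.c2, cc.p[2]);  // 128 + 128 @ 1/8
  if (training) {
    dropout_mask(cc.m1, cc.k1.n_rows, cc.k1.n_cols, dropout_rate);
    cc.d1 = cc.k1 % cc.m1;
  } else cc.d1 = cc.k1;
  cc.c3 = conv3(net, 7, cc.d1, cc.H[3], cc.Wd[3], cc.K[7], true);
  deconv_fwd(net.W[15], net.b[15], cc.c3, cc.H[3], cc.Wd[3], cc.H[2],
             cc.Wd[2], cc.u3);
  cc.c4 = conv3(net, 8, cc.u3, cc.H[2], cc.Wd[2], cc.K[8], true);
  cc.k2 = arma::join_cols(cc.c4, cc.p[1]);  // 128 + 64 @ 1/4
  if (training) {
    dropout_mask(cc.m2, cc.k2.n_rows, cc.k2.n_cols, dropout_rate);
    cc.d2 = cc.k2 % cc.m2;
  } else cc.d2 = cc.k2;
  cc.c5 = conv3(net, 9, cc.d2, cc.H[2], cc.Wd[2], cc.K[9], true);
  deconv_fwd(net.W[16], net.b[16], cc.c5, cc.H[2], cc.Wd[2], cc.H[1],
             cc.Wd[1], cc.u4);
  cc.c6 = conv3(net, 10, cc.u4, cc.H[1], cc.Wd[1], cc.K[10], true);
  cc.k3 = arma::join_cols(cc.c6, cc.p[0]);  // 128 + 32 @ 1/2
  cc.c7 = conv3(net, 11, cc.k3, cc.H[1], cc.Wd[1], cc.K[11], true);
  deconv_fwd(net.W[17], net.b[17], cc.c7, cc.H[1], cc.Wd[1], cc.H[0],
             cc.Wd[0], cc.u5);
  cc.c8 = conv3(net, 12, cc.u5, cc.H[0], cc.Wd[0], cc.K[12], true);
  cc.P = net.W[18] * cc.c8;
  cc.P.each_col() += net.b[18];
  cc.P.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
}

static void backward(UNet &net, Caches &cc, const fmat &dP_post) {
  // Gradient at the sigmoid input. The exact chain factor p(1-p) vanishes
  // for saturated pixels, which under Adam's normalized steps freezes
  // wrongly-saturated predictions permanently (the classic sigmoid +
  // squared-error pathology). Flooring the factor preserves the loss's
  // stationary points (dz = 0 still requires dP = 0, i.e. p = l) while
  // keeping corrective gradient flowing out of saturation.
  fmat sg = cc.P % (1.0f - cc.P);
  sg.transform([](float v) { return v < 0.05f ? 0.05f : v; });
  fmat dZ = dP_post % sg;
  net.dW[18] += dZ * cc.c8.t();
  net.db[18] += arma::sum(dZ, 1);
  fmat g = net.W[18].t() * dZ;  // at c8
  g = conv3_back(net, 12, cc.c8, cc.K[12], g, cc.H[0], cc.Wd[0], true, 64);
  fmat gu;
  deconv_back(net.W[17], cc.c7, g, cc.H[1], cc.Wd[1], cc.H[0], cc.Wd[0],
              net.dW[17], net.db[17], gu);
  g = conv3_back(net, 11, cc.c7, cc.K[11], gu, cc.H[1], cc.Wd[1], true, 160);
  fmat g_c6 = g.rows(0, 127), g_p0 = g.rows(128, 159);
  g = conv3_back(net, 10, cc.c6, cc.K[10], g_c6, cc.H[1], cc.Wd[1], true, 128);
  deconv_back(net.W[16], cc.c5, g, cc.H[2], cc.Wd[2], cc.H[1], cc.Wd[1],
              net.dW[16], net.db[16], gu);
  g = conv3_back(net, 9, cc.c5, cc.K[9], gu, cc.H[2], cc.Wd[2], true, 192);
  if (cc.m2.n_elem) g %= cc.m2;
  fmat g_c4 = g.rows(0, 127), g_p1 = g.rows(128, 191);
  g = conv3_back(net, 8, cc.c4, cc.K[8], g_c4, cc.H[2], cc.Wd[2], true, 128);
  deconv_back(net.W[15], cc.c3, g, cc.H[3], cc.Wd[3], cc.H[2], cc.Wd[2],
              net.dW[15], net.db[15], gu);
  g = conv3_back(net, 7, cc.c3, cc.K[7], gu, cc.H[3], cc.Wd[3], true, 256);
  if (cc.m1.n_elem) g %= cc.m1;
  fmat g_c2 = g.rows(0, 127), g_p2 = g.rows(128, 255);
  g = conv3_back(net, 6, cc.c2, cc.K[6], g_c2, cc.H[3], cc.Wd[3], true, 128);
  deconv_back(net.W[14], cc.c1, g, cc.H[4], cc.Wd[4], cc.H[3], cc.Wd[3],
              net.dW[14], net.db[14], gu);
  g = conv3_back(net, 5, cc.c1, cc.K[5], gu, cc.H[4], cc.Wd[4], true, 256);
  fmat g_p4;
  deconv_back(net.W[13], cc.drop0, g, cc.H[5], cc.Wd[5], cc.H[4], cc.Wd[4],
              net.dW[13], net.db[13], g_p4);
  if (cc.m0.n_elem) g_p4 %= cc.m0;

  // propagate through the encoder, adding the skip gradients where they join
  fmat dp[5];
  dp[4] = g_p4;
  dp[2] = g_p2; dp[1] = g_p1; dp[0] = g_p0;
  dp[3].zeros(128, cc.H[4] * cc.Wd[4]);
  for (int l = 4; l >= 0; --l) {
    fmat dx(cc.x[l].n_rows, cc.H[l] * cc.Wd[l], arma::fill::zeros);
    maxpool_back(dp[l], cc.win[l], dx);
    fmat dA = conv3_back(net, l, cc.x[l], cc.K[l], dx, cc.H[l], cc.Wd[l],
                         true, CIN[l]);
    if (l > 0) dp[l - 1] += dA;
  }
}

static void zero_grads(UNet &net) {
  for (int i = 0; i < NPAR; ++i) { net.dW[i].zeros(); net.db[i].zeros(); }
}

static void adam_step(UNet &net, double lr) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  net.adam_t += 1;
  float c1 = 1.0f - std::pow(b1, (float)net.adam_t);
  float c2 = 1.0f - std::pow(b2, (float)net.adam_t);
  for (int i = 0; i < NPAR; ++i) {
    net.mW[i] = b1 * net.mW[i] + (1 - b1) * net.dW[i];
    net.vW[i] = b2 * net.vW[i] + (1 - b2) * arma::square(net.dW[i]);
    net.W[i] -= (float)lr * (net.mW[i] / c1) /
                (arma::sqrt(net.vW[i] / c2) + eps);
    net.mb[i] = b1 * net.mb[i] + (1 - b1) * net.db[i];
    net.vb[i] = b2 * net.vb[i] + (1 - b2) * arma::square(net.db[i]);
    net.b[i] -= (float)lr * (net.mb[i] / c1) /
                (arma::sqrt(net.vb[i] / c2) + eps);
  }
}

// [[Rcpp::export]]
SEXP unet_create() {
  UNet *net = new UNet();
  net->W.resize(NPAR); net->dW.resize(NPAR);
  net->mW.resize(NPAR); net->vW.resize(NPAR);
  net->b.resize(NPAR); net->db.resize(NPAR);
  net->mb.resize(NPAR); net->vb.resize(NPAR);
  for (int i = 0; i < NPAR; ++i) {
    int nr, ncol;
    if (i < NCONV3) { nr = COUT[i]; ncol = 9 * CIN[i]; }
    else if (i < NCONV3 + NDECONV) { nr = 4 * COUT[i]; ncol = CIN[i]; }
    else { nr = COUT[i]; ncol = CIN[i]; }
    // He scaling after ReLU layers; variance-preserving 1/fan_in for the
    // linear transposed convs and the sigmoid head (keeps the head in its
    // responsive range at init)
    float sd = (i < NCONV3) ? std::sqrt(2.0f / (float)ncol)
                            : std::sqrt(1.0f / (float)ncol);
    net->W[i].set_size(nr, ncol);
    if (i >= NCONV3 && i < NCONV3 + NDECONV) {
      // ICNR-style init: the four sub-pixel blocks of a transposed conv
      // start identical, so upsampling is free of checkerboard patterning
      // (and a constant input yields an exactly constant output) at init
      fmat base(COUT[i], ncol);
      for (uword j = 0; j < base.n_elem; ++j)
        base[j] = (float)(norm_rand() * sd);
      for (int k = 0; k < 4; ++k)
        net->W[i].rows(k * COUT[i], (k + 1) * COUT[i] - 1) = base;
    } else {
      for (uword j = 0; j < net->W[i].n_elem; ++j)
        net->W[i][j] = (float)(norm_rand() * sd);
    }
    net->b[i].zeros(COUT[i]);
    net->dW[i].zeros(nr, ncol); net->mW[i].zeros(nr, ncol);
    net->vW[i].zeros(nr, ncol);
    net->db[i].zeros(COUT[i]); net->mb[i].zeros(COUT[i]);
    net->vb[i].zeros(COUT[i]);
  }
  XPtr<UNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
double unet_nparams(SEXP handle) {
  XPtr<UNet> net(handle);
  double n = 0;
  for (int i = 0; i < NPAR; ++i) n += net->W[i].n_elem + net->b[i].n_elem;
  return n;
}

// [[Rcpp::export]]
List unet_get_weights(SEXP handle) {
  XPtr<UNet> net(handle);
  List out(2 * NPAR);
  for (int i = 0; i < NPAR; ++i) {
    NumericMatrix w(net->W[i].n_rows, net->W[i].n_cols);
    for (uword j = 0; j < net->W[i].n_elem; ++j) w[j] = net->W[i][j];
    NumericVector bb(net->b[i].n_elem);
    for (uword j = 0; j < net->b[i].n_elem; ++j) bb[j] = net->b[i][j];
    out[2 * i] = w;
    out[2 * i + 1] = bb;
  }
  return out;
}

// [[Rcpp::export]]
void unet_set_weights(SEXP handle, List weights) {
  XPtr<UNet> net(handle);
  if (weights.size() != 2 * NPAR) stop("weight list has wrong length");
  for (int i = 0; i < NPAR; ++i) {
    NumericMatrix w = weights[2 * i];
    NumericVector bb = weights[2 * i + 1];
    if ((int)net->W[i].n_rows != w.nrow() ||
        (int)net->W[i].n_cols != w.ncol())
      stop("weight matrix %d has wrong shape", i + 1);
    for (uword j = 0; j < net->W[i].n_elem; ++j) net->W[i][j] = (float)w[j];
    for (uword j = 0; j < net->b[i].n_elem; ++j) net->b[i][j] = (float)bb[j];
  }
}

// x: (H, W, B) tiles; y: (H, W, 3, B) label triplets (n, c, b channel order).
// The loss is evaluated on the core region [core_off, core_off + core_h) x
// [core_off, core_off + core_w).
// [[Rcpp::export]]
double unet_train_batch(SEXP handle, NumericVector x, NumericVector y,
                        double lr, double dropout_rate, NumericVector wts,
                        int core_off, int core_h, int core_w) {
  XPtr<UNet> net(handle);
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], Wd = xd[1], B = xd[2];
  const int n = H * Wd, ncore = core_h * core_w;
  zero_grads(*net);
  double total_loss = 0;
  Caches cc;
  arma::uvec core_idx(ncore);
  {
    int q = 0;
    for (int c = 0; c < core_w; ++c) for (int r = 0; r < core_h; ++r)
      core_idx[q++] = (core_off + r) + H * (core_off + c);
  }
  for (int s = 0; s < B; ++s) {
    fmat A0(1, n);
    const double *xs = x.begin() + (R_xlen_t)s * n;
    for (int p = 0; p < n; ++p) A0[p] = (float)xs[p];
    forward(*net, cc, A0, H, Wd, true, dropout_rate);
    const double *ys = y.begin() + (R_xlen_t)s * 3 * n;
    fmat dP(3, n, arma::fill::zeros);
    double loss = 0;
    arma::fvec lsum(ncore, arma::fill::zeros);
    for (int ch = 0; ch < 3; ++ch) {
      double ss = 0;
      for (int q = 0; q < ncore; ++q) {
        int p = core_idx[q];
        double d = cc.P(ch, p) - ys[p + (R_xlen_t)ch * n];
        ss += d * d;
        lsum[q] += (float)ys[p + (R_xlen_t)ch * n];
      }
      double rmsd = std::sqrt(ss / ncore);
      loss += wts[ch] * rmsd;
      if (rmsd > 0) {
        double scale = wts[ch] / (ncore * rmsd);
        for (int q = 0; q < ncore; ++q) {
          int p = core_idx[q];
          dP(ch, p) = (float)(scale * (cc.P(ch, p) - ys[p + (R_xlen_t)ch * n]));
        }
      }
    }
    // label-partition penalty RMSD(l_n + l_c + l_b, 1): depends on labels
    // only, contributes to the reported loss but has no weight gradient
    double ss = 0;
    for (int q = 0; q < ncore; ++q) { double d = lsum[q] - 1.0; ss += d * d; }
    loss += wts[3] * std::sqrt(ss / ncore);
    total_loss += loss;
    backward(*net, cc, dP);
  }
  for (int i = 0; i < NPAR; ++i) {
    net->dW[i] /= (float)B;
    net->db[i] /= (float)B;
  }
  adam_step(*net, lr);
  return total_loss / B;
}

// [[Rcpp::export]]
NumericVector unet_predict(SEXP handle, NumericMatrix x) {
  XPtr<UNet> net(handle);
  const int H = x.nrow(), Wd = x.ncol(), n = H * Wd;
  fmat A0(1, n);
  for (int p = 0; p < n; ++p) A0[p] = (float)x[p];
  Caches cc;
  forward(*net, cc, A0, H, Wd, false, 0.0);
  NumericVector out(Dimension(H, Wd, 3));
  for (int ch = 0; ch < 3; ++ch)
    for (int p = 0; p < n; ++p) out[p + (R_xlen_t)ch * n] = cc.P(ch, p);
  return out;
}

// Gradients of the most recent unet_train_batch call (for verification)
// [[Rcpp::export]]
List unet_last_grads(SEXP handle) {
  XPtr<UNet> net(handle);
  List out(2 * NPAR);
  for (int i = 0; i < NPAR; ++i) {
    NumericMatrix w(net->dW[i].n_rows, net->dW[i].n_cols);
    for (uword j = 0; j < net->dW[i].n_elem; ++j) w[j] = net->dW[i][j];
    NumericVector bb(net->db[i].n_elem);
    for (uword j = 0; j < net->db[i].n_elem; ++j) bb[j] = net->db[i][j];
    out[2 * i] = w;
    out[2 * i + 1] = bb;
  }
  return out;
}
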