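// Convolutional network with CBAM attention and a bilayer LSTM for
// subsequence-matrix classification. Forward pass, hand-derived
// backpropagation and inference are implemented here; parameter
// initialization and the Adam loop live on the R side so that all
// randomness flows through R's RNG.
//
// Activations use a flat batched layout: a layer's output is one matrix
// [P*B x C] where P = H*W spatial positions (column-major, p = y + x*H),
// B = batch (sample-major row blocks) and C = channels, so convolutions
// become a single im2col + GEMM per layer and batch norm reduces to
// column statistics. Conv weights arrive as [C_out x C_in*kh*kw] with
// im2col row order (c, dx, dy).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-5;

// ---------------------------------------------------------------- im2col

// same-padding geometry: pt = (kh-1)/2 rows on top, pl = (kw-1)/2 on the
// left (the remainder pads bottom/right), so output size equals input size.
static mat im2col(const mat& A, int B, int H, int W, int kh, int kw) {
  const int P = H * W, C = A.n_cols;
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  mat cols(P * B, C * kh * kw, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    for (int dx = 0; dx < kw; ++dx) {
      for (int dy = 0; dy < kh; ++dy) {
        double* dst = cols.colptr(c * kh * kw + dx * kh + dy);
        const int y0 = std::max(0, pt - dy);
        const int y1 = std::min(H - 1, H - 1 + pt - dy);
        const int len = y1 - y0 + 1;
        if (len <= 0) continue;
        const int x0 = std::max(0, pl - dx);
        const int x1 = std::min(W - 1, W - 1 + pl - dx);
        for (int n = 0; n < B; ++n) {
          const int base = n * P;
          for (int xp = x0; xp <= x1; ++xp) {
            const int sx = xp + dx - pl;
            const int sy0 = y0 + dy - pt;
            std::memcpy(dst + base + xp * H + y0,
                        src + base + sx * H + sy0, len * sizeof(double));
          }
        }
      }
    }
  }
  return cols;
}

static mat col2im(const mat& dcols, int B, int H, int W, int C,
                  int kh, int kw) {
  const int P = H * W;
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  mat dA(P * B, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = dA.colptr(c);
    for (int dx = 0; dx < kw; ++dx) {
      for (int dy = 0; dy < kh; ++dy) {
        const double* src = dcols.colptr(c * kh * kw + dx * kh + dy);
        const int y0 = std::max(0, pt - dy);
        const int y1 = std::min(H - 1, H - 1 + pt - dy);
        const int len = y1 - y0 + 1;
        if (len <= 0) continue;
        const int x0 = std::max(0, pl - dx);
        const int x1 = std::min(W - 1, W - 1 + pl - dx);
        for (int n = 0; n < B; ++n) {
          const int base = n * P;
          for (int xp = x0; xp <= x1; ++xp) {
            const int sx = xp + dx - pl;
            const int sy0 = y0 + dy - pt;
            double* d = dst + base + sx * H + sy0;
            const double* s = src + base + xp * H + y0;
            for (int i = 0; i < len; ++i) d[i] += s[i];
          }
        }
      }
    }
  }
  return dA;
}

// ------------------------------------------------------------ conv layer

static mat conv_fwd(const mat& A, int B, int H, int W, const mat& Wt,
                    const vec& b, int kh, int kw, mat* keep_cols) {
  mat cols = im2col(A, B, H, W, kh, kw);
  mat out = cols * Wt.t();
  out.each_row() += b.t();
  if (keep_cols) *keep_cols = std::move(cols);
  return out;
}

// dW/db from cached cols; returns gradient w.r.t. the layer input
static mat conv_bwd(const mat& cols, const mat& dout, const mat& Wt,
                    int B, int H, int W, int Cin, int kh, int kw,
                    mat& dW, vec& db) {
  dW = dout.t() * cols;
  db = sum(dout, 0).t();
  return col2im(dout * Wt, B, H, W, Cin, kh, kw);
}

// ---------------------------------------------------------- batch norm

struct BNCache { mat xhat; vec invstd; vec mean_, var_; };

static mat bn_fwd_train(const mat& A, const vec& g, const vec& bb,
                        BNCache& K) {
  const double M = A.n_rows;
  rowvec mu = mean(A, 0);
  rowvec var = sum(square(A.each_row() - mu), 0) / M;
  K.mean_ = mu.t(); K.var_ = var.t();
  K.invstd = 1.0 / sqrt(K.var_ + BN_EPS);
  K.xhat = A.each_row() - mu;
  K.xhat.each_row() %= K.invstd.t();
  mat out = K.xhat.each_row() % g.t();
  out.each_row() += bb.t();
  return out;
}

static mat bn_fwd_eval(const mat& A, const vec& g, const vec& bb,
                       const vec& rmean, const vec& rvar) {
  rowvec scale = (g / sqrt(rvar + BN_EPS)).t();
  mat out = A.each_row() - rmean.t();
  out.each_row() %= scale;
  out.each_row() += bb.t();
  return out;
}

// EMA-frozen training mode: normalize with running statistics treated as
// constants in backprop (samples stay independent; train matches eval),
// while batch moments are still collected for the EMA update.
static mat bn_fwd_frozen(const mat& A, const vec& g, const vec& bb,
                         const vec& rmean, const vec& rvar, BNCache& K) {
  const double M = A.n_rows;
  rowvec mu = mean(A, 0);
  K.mean_ = mu.t();
  K.var_ = (sum(square(A.each_row() - mu), 0) / M).t();
  K.invstd = 1.0 / sqrt(rvar + BN_EPS);
  K.xhat = A.each_row() - rmean.t();
  K.xhat.each_row() %= K.invstd.t();
  mat out = K.xhat.each_row() % g.t();
  out.each_row() += bb.t();
  return out;
}

static mat bn_bwd_frozen(const mat& dout, const BNCache& K, const vec& g,
                         vec& dg, vec& dbb) {
  dg = sum(dout % K.xhat, 0).t();
  dbb = sum(dout, 0).t();
  return dout.each_row() % (g % K.invstd).t();
}

static mat bn_bwd(const mat& dout, const BNCache& K, const vec& g,
                  vec& dg, vec& dbb) {
  const double M = dout.n_rows;
  dg = sum(dout % K.xhat, 0).t();
  dbb = sum(dout, 0).t();
  // dxhat = dout * g;   dx = invstd/M * (M*dxhat - sum - xhat*sum(dxhat*xhat))
  rowvec s1 = (g % dbb).t();          // sum of dxhat per channel
  rowvec s2 = (g % dg).t();           // sum of dxhat*xhat per channel
  mat dx = dout.each_row() % (M * g.t());
  dx.each_row() -= s1;
  dx -= K.xhat.each_row() % s2;
  dx.each_row() %= (K.invstd.t() / M);
  return dx;
}

// --------------------------------------------------------------- ReLU

static mat relu(const mat& A) {
  mat out = A;
  out.transform([](double v) { return v > 0 ? v : 0.0; });
  return out;
}

static mat relu_bwd(const mat& dout, const mat& act) {
  return dout % conv_to<mat>::from(act > 0);
}

// --------------------------------------------------------- max pooling

struct PoolCache { umat argmax; int Hin, Win; };

static mat pool_fwd(const mat& A, int B, int H, int W, PoolCache& K) {
  const int Ho = H / 2, Wo = W / 2, P = H * W, Po = Ho * Wo, C = A.n_cols;
  K.Hin = H; K.Win = W;
  K.argmax.set_size(Po * B, C);
  mat out(Po * B, C);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    double* dst = out.colptr(c);
    uword* am = K.argmax.colptr(c);
    for (int n = 0; n < B; ++n) {
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo) {
          double best = -datum::inf; int bi = 0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy) {
              const int p = (2 * yo + dy) + (2 * xo + dx) * H + n * P;
              if (src[p] > best) { best = src[p]; bi = p; }
            }
          dst[yo + xo * Ho + n * Po] = best;
          am[yo + xo * Ho + n * Po] = bi;
        }
      }
    }
  }
  return out;
}

static mat pool_bwd(const mat& dout, const PoolCache& K, int B) {
  const int C = dout.n_cols;
  mat din(K.Hin * K.Win * B, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = din.colptr(c);
    const double* src = dout.colptr(c);
    const uword* am = K.argmax.colptr(c);
    for (uword i = 0; i < dout.n_rows; ++i) dst[am[i]] += src[i];
  }
  return din;
}

// ----------------------------------------------------------------- CBAM

struct CBAMParams { mat m1_W, m2_W, sp_W; vec m1_b, m2_b, sp_b; };

struct CBAMCache {
  mat apool, mpool;        // C x B pooled descriptors
  umat marg;               // spatial argmax per (channel, sample)
  mat ha, hm, Mc;          // MLP activations and channel gate (C x B)
  mat X1;                  // channel-gated map (P*B x C)
  vec savg, smax, Ms;      // channel-pooled maps and spatial gate (P*B)
  uvec sarg;               // channel argmax per position
  mat sp_cols;             // im2col of the 2-channel spatial input
};

static mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

static mat cbam_fwd(const mat& A, int B, int H, int W, const CBAMParams& P,
                    CBAMCache& K, bool training) {
  const int C = A.n_cols, Pp = H * W;
  K.apool.set_size(C, B); K.mpool.set_size(C, B); K.marg.set_size(C, B);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    for (int n = 0; n < B; ++n) {
      double s = 0, m = -datum::inf; int mi = 0;
      for (int p = 0; p < Pp; ++p) {
        const double v = src[n * Pp + p];
        s += v;
        if (v > m) { m = v; mi = p; }
      }
      K.apool(c, n) = s / Pp;
      K.mpool(c, n) = m;
      K.marg(c, n) = mi;
    }
  }
  mat za = P.m1_W * K.apool; za.each_col() += P.m1_b;
  mat zm = P.m1_W * K.mpool; zm.each_col() += P.m1_b;
  K.ha = relu(za);
  K.hm = relu(zm);
  mat s = P.m2_W * (K.ha + K.hm);
  s.each_col() += 2.0 * P.m2_b;
  K.Mc = sigmoid(s);
  K.X1 = A;
  for (int c = 0; c < C; ++c) {
    double* col = K.X1.colptr(c);
    for (int n = 0; n < B; ++n) {
      const double g = K.Mc(c, n);
      for (int p = 0; p < Pp; ++p) col[n * Pp + p] *= g;
    }
  }
  K.savg = mean(K.X1, 1);
  K.smax = max(K.X1, 1);
  K.sarg = index_max(K.X1, 1);
  mat sp = join_rows(K.savg, K.smax);
  mat z = conv_fwd(sp, B, H, W, P.sp_W, P.sp_b, 3, 3,
                   training ? &K.sp_cols : nullptr);
  K.Ms = vec(sigmoid(z));
  mat out = K.X1.each_col() % K.Ms;
  return out;
}

static mat cbam_bwd(const mat& A, const mat& dout, int B, int H, int W,
                    const CBAMParams& P, const CBAMCache& K, CBAMParams& G) {
  const int C = A.n_cols, Pp = H * W;
  // spatial gate
  vec dMs = sum(dout % K.X1, 1);
  mat dX1 = dout.each_col() % K.Ms;
  vec dz = dMs % K.Ms % (1.0 - K.Ms);
  mat dW; vec db;
  mat dsp = conv_bwd(K.sp_cols, mat(dz), P.sp_W, B, H, W, 2, 3, 3, dW, db);
  G.sp_W = dW; G.sp_b = db;
  dX1.each_col() += dsp.col(0) / C;
  {
    const double* s = dsp.colptr(1);
    for (uword i = 0; i < K.sarg.n_elem; ++i) dX1(i, K.sarg(i)) += s[i];
  }
  // channel gate
  mat din(size(A));
  mat dMc(C, B);
  for (int c = 0; c < C; ++c) {
    const double* dx1 = dX1.colptr(c);
    const double* a = A.colptr(c);
    double* d = din.colptr(c);
    for (int n = 0; n < B; ++n) {
      const double g = K.Mc(c, n);
      double acc = 0;
      for (int p = 0; p < Pp; ++p) {
        const int i = n * Pp + p;
        d[i] = dx1[i] * g;
        acc += dx1[i] * a[i];
      }
      dMc(c, n) = acc;
    }
  }
  mat ds = dMc % K.Mc % (1.0 - K.Mc);
  G.m2_b = 2.0 * sum(ds, 1);
  G.m2_W = ds * K.ha.t() + ds * K.hm.t();
  mat dha = (P.m2_W.t() * ds) % conv_to<mat>::from(K.ha > 0);
  mat dhm = (P.m2_W.t() * ds) % conv_to<mat>::from(K.hm > 0);
  G.m1_W = dha * K.apool.t() + dhm * K.mpool.t();
  G.m1_b = sum(dha, 1) + sum(dhm, 1);
  mat da = P.m1_W.t() * dha;
  mat dm = P.m1_W.t() * dhm;
  for (int c = 0; c < C; ++c) {
    double* d = din.colptr(c);
    for (int n = 0; n < B; ++n) {
      const double inc = da(c, n) / Pp;
      for (int p = 0; p < Pp; ++p) d[n * Pp + p] += inc;
      d[n * Pp + K.marg(c, n)] += dm(c, n);
    }
  }
  return din;
}

// ----------------------------------------------------------------- LSTM

struct LSTMParams { mat Wx, Wh; vec b; };

struct LSTMCache { std::vector<mat> i, f, g, o, c, tc, h, x; };

static void lstm_fwd(const std::vector<mat>& x, const LSTMParams& P,
                     LSTMCache& K) {
  const int T = x.size(), Hd = P.Wh.n_cols, N = x[0].n_cols;
  K.i.resize(T); K.f.resize(T); K.g.resize(T); K.o.resize(T);
  K.c.resize(T); K.tc.resize(T); K.h.resize(T); K.x = x;
  mat h_prev(Hd, N, fill::zeros), c_prev(Hd, N, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat z = P.Wx * x[t] + P.Wh * h_prev;
    z.each_col() += P.b;
    K.i[t] = sigmoid(z.rows(0, Hd - 1));
    K.f[t] = sigmoid(z.rows(Hd, 2 * Hd - 1));
    K.g[t] = tanh(z.rows(2 * Hd, 3 * Hd - 1));
    K.o[t] = sigmoid(z.rows(3 * Hd, 4 * Hd - 1));
    K.c[t] = K.f[t] % c_prev + K.i[t] % K.g[t];
    K.tc[t] = tanh(K.c[t]);
    K.h[t] = K.o[t] % K.tc[t];
    h_prev = K.h[t]; c_prev = K.c[t];
  }
}

static std::vector<mat> lstm_bwd(const LSTMParams& P, const LSTMCache& K,
                                 const std::vector<mat>& dh_ext,
                                 LSTMParams& G) {
  const int T = K.h.size(), Hd = P.Wh.n_cols, N = K.h[0].n_cols;
  G.Wx.zeros(size(P.Wx)); G.Wh.zeros(size(P.Wh)); G.b.zeros(P.b.n_elem);
  std::vector<mat> dx(T);
  mat dh_next(Hd, N, fill::zeros), dc_next(Hd, N, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    mat dh = dh_ext[t] + dh_next;
    mat dc = dc_next + dh % K.o[t] % (1.0 - square(K.tc[t]));
    mat do_ = dh % K.tc[t] % K.o[t] % (1.0 - K.o[t]);
    mat c_prev = (t > 0) ? K.c[t - 1] : mat(Hd, N, fill::zeros);
    mat h_prev = (t > 0) ? K.h[t - 1] : mat(Hd, N, fill::zeros);
    mat di = dc % K.g[t] % K.i[t] % (1.0 - K.i[t]);
    mat df = dc % c_prev % K.f[t] % (1.0 - K.f[t]);
    mat dg = dc % K.i[t] % (1.0 - square(K.g[t]));
    mat dz = join_cols(di, df, dg, do_);
    G.Wx += dz * K.x[t].t();
    G.Wh += dz * h_prev.t();
    G.b += sum(dz, 1);
    dx[t] = P.Wx.t() * dz;
    dh_next = P.Wh.t() * dz;
    dc_next = dc % K.f[t];
  }
  return dx;
}

// ------------------------------------------------------ param plumbing

static mat getm(const Rcpp::List& L, const std::string& nm) {
  return Rcpp::as<mat>(L[nm]);
}
static vec getv(const Rcpp::List& L, const std::string& nm) {
  return Rcpp::as<vec>(L[nm]);
}

struct Net {
  bool block_bn;
  mat stem_W; vec stem_b, stem_g, stem_bb;
  mat bc_W[3][2]; vec bc_b[3][2], bc_g[3][2], bc_bb[3][2];
  CBAMParams cb[3];
  mat red1_W, red2_W; vec red1_b, red2_b;
  bool use_lstm;
  LSTMParams l1, l2;
  mat flat_W; vec flat_b;
  mat fc1_W, fc2_W, out_W; vec fc1_b, fc2_b, out_b;
};

static Net load_net(const Rcpp::List& P, bool use_lstm, bool block_bn) {
  Net N;
  N.use_lstm = use_lstm;
  N.block_bn = block_bn;
  N.stem_W = getm(P, "stem_W"); N.stem_b = getv(P, "stem_b");
  N.stem_g = getv(P, "stem_g"); N.stem_bb = getv(P, "stem_bb");
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 2; ++j) {
      std::string p = "b" + std::to_string(i + 1) + "c" + std::to_string(j + 1);
      N.bc_W[i][j] = getm(P, p + "_W");
      N.bc_b[i][j] = getv(P, p + "_b");
      if (block_bn) {
        N.bc_g[i][j] = getv(P, p + "_g");
        N.bc_bb[i][j] = getv(P, p + "_bb");
      }
    }
    std::string c = "cb" + std::to_string(i + 1);
    N.cb[i].m1_W = getm(P, c + "_m1_W"); N.cb[i].m1_b = getv(P, c + "_m1_b");
    N.cb[i].m2_W = getm(P, c + "_m2_W"); N.cb[i].m2_b = getv(P, c + "_m2_b");
    N.cb[i].sp_W = getm(P, c + "_sp_W"); N.cb[i].sp_b = getv(P, c + "_sp_b");
  }
  N.red1_W = getm(P, "red1_W"); N.red1_b = getv(P, "red1_b");
  N.red2_W = getm(P, "red2_W"); N.red2_b = getv(P, "red2_b");
  if (use_lstm) {
    N.l1.Wx = getm(P, "lstm1_Wx"); N.l1.Wh = getm(P, "lstm1_Wh");
    N.l1.b = getv(P, "lstm1_b");
    N.l2.Wx = getm(P, "lstm2_Wx"); N.l2.Wh = getm(P, "lstm2_Wh");
    N.l2.b = getv(P, "lstm2_b");
  } else {
    N.flat_W = getm(P, "flat_W"); N.flat_b = getv(P, "flat_b");
  }
  N.fc1_W = getm(P, "fc1_W"); N.fc1_b = getv(P, "fc1_b");
  N.fc2_W = getm(P, "fc2_W"); N.fc2_b = getv(P, "fc2_b");
  N.out_W = getm(P, "out_W"); N.out_b = getv(P, "out_b");
  return N;
}

// final feature map [Pf*B x C] read as a width-wise sequence of
// F = C*Hf features: x[t](c*Hf + y, n) = A(y + t*Hf + n*Pf, c)
static std::vector<mat> to_sequence(const mat& A, int B, int H, int W) {
  const int C = A.n_cols, P = H * W, F = C * H;
  std::vector<mat> x(W, mat(F, B));
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    for (int n = 0; n < B; ++n)
      for (int t = 0; t < W; ++t)
        for (int y = 0; y < H; ++y)
          x[t](c * H + y, n) = src[y + t * H + n * P];
  }
  return x;
}

static mat from_sequence_grad(const std::vector<mat>& dx, int B, int H,
                              int W, int C) {
  const int P = H * W;
  mat d(P * B, C);
  for (int c = 0; c < C; ++c) {
    double* dst = d.colptr(c);
    for (int n = 0; n < B; ++n)
      for (int t = 0; t < W; ++t)
        for (int y = 0; y < H; ++y)
          dst[y + t * H + n * P] = dx[t](c * H + y, n);
  }
  return d;
}

// per-sample flatten of the final map: flat(c*P + p, n) = A(p + n*P, c)
static mat flatten_map(const mat& A, int B) {
  const int P = A.n_rows / B, C = A.n_cols;
  mat out(P * C, B);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    for (int n = 0; n < B; ++n)
      std::memcpy(out.colptr(n) + c * P, src + n * P, P * sizeof(double));
  }
  return out;
}

static mat unflatten_grad(const mat& dflat, int B, int P, int C) {
  mat d(P * B, C);
  for (int c = 0; c < C; ++c) {
    double* dst = d.colptr(c);
    for (int n = 0; n < B; ++n)
      std::memcpy(dst + n * P, dflat.colptr(n) + c * P, P * sizeof(double));
  }
  return d;
}

static mat softmax_cols(mat z) {
  z.each_row() -= max(z, 0);
  mat e = exp(z);
  e.each_row() /= sum(e, 0);
  return e;
}

// ------------------------------------------------- forward (shared part)

struct FwdCache {
  int B, H0, W0, Hp[4], Wp[4];       // Hp[0]/Wp[0]: after stem (= input)
  mat stem_cols, stem_act;
  BNCache stem_bn;
  mat c1_cols[3], c2_cols[3], c1_act[3], c2_act[3], cb_out[3], pooled[3];
  BNCache bn1[3], bn2[3];
  CBAMCache cbk[3];
  PoolCache pk[3];
  mat red1_cols, red2_cols, red1_act, red2_act;
  std::vector<mat> seq;
  LSTMCache k1, k2;
  mat flat_in, flat_act;
  mat feat, fc1_act, fc2_act, fc2_drop, logits, probs;
};

static void forward(const Net& N, const mat& x0, int B, int H0, int W0,
                    bool training, bool frozen_bn,
                    const Rcpp::List* bn_mean,
                    const Rcpp::List* bn_var, const mat* dropout_mask,
                    FwdCache& K) {
  K.B = B; K.H0 = H0; K.W0 = W0;
  mat h = conv_fwd(x0, B, H0, W0, N.stem_W, N.stem_b, 3, 4,
                   training ? &K.stem_cols : nullptr);
  if (training && frozen_bn) {
    h = bn_fwd_frozen(h, N.stem_g, N.stem_bb, Rcpp::as<vec>((*bn_mean)[0]),
                      Rcpp::as<vec>((*bn_var)[0]), K.stem_bn);
  } else if (training) {
    h = bn_fwd_train(h, N.stem_g, N.stem_bb, K.stem_bn);
  } else {
    h = bn_fwd_eval(h, N.stem_g, N.stem_bb, Rcpp::as<vec>((*bn_mean)[0]),
                    Rcpp::as<vec>((*bn_var)[0]));
  }
  K.stem_act = relu(h);
  h = K.stem_act;
  int H = H0, W = W0;
  for (int i = 0; i < 3; ++i) {
    K.Hp[i] = H; K.Wp[i] = W;
    mat t = conv_fwd(h, B, H, W, N.bc_W[i][0], N.bc_b[i][0], 3, 3,
                     training ? &K.c1_cols[i] : nullptr);
    if (N.block_bn) {
      if (training && frozen_bn) {
        t = bn_fwd_frozen(t, N.bc_g[i][0], N.bc_bb[i][0],
                          Rcpp::as<vec>((*bn_mean)[1 + 2 * i]),
                          Rcpp::as<vec>((*bn_var)[1 + 2 * i]), K.bn1[i]);
      } else if (training) {
        t = bn_fwd_train(t, N.bc_g[i][0], N.bc_bb[i][0], K.bn1[i]);
      } else {
        t = bn_fwd_eval(t, N.bc_g[i][0], N.bc_bb[i][0],
                        Rcpp::as<vec>((*bn_mean)[1 + 2 * i]),
                        Rcpp::as<vec>((*bn_var)[1 + 2 * i]));
      }
    }
    K.c1_act[i] = relu(t);
    t = conv_fwd(K.c1_act[i], B, H, W, N.bc_W[i][1], N.bc_b[i][1], 3, 3,
                 training ? &K.c2_cols[i] : nullptr);
    if (N.block_bn) {
      if (training && frozen_bn) {
        t = bn_fwd_frozen(t, N.bc_g[i][1], N.bc_bb[i][1],
                          Rcpp::as<vec>((*bn_mean)[2 + 2 * i]),
                          Rcpp::as<vec>((*bn_var)[2 + 2 * i]), K.bn2[i]);
      } else if (training) {
        t = bn_fwd_train(t, N.bc_g[i][1], N.bc_bb[i][1], K.bn2[i]);
      } else {
        t = bn_fwd_eval(t, N.bc_g[i][1], N.bc_bb[i][1],
                        Rcpp::as<vec>((*bn_mean)[2 + 2 * i]),
                        Rcpp::as<vec>((*bn_var)[2 + 2 * i]));
      }
    }
    K.c2_act[i] = relu(t);
    K.cb_out[i] = cbam_fwd(K.c2_act[i], B, H, W, N.cb[i], K.cbk[i], training);
    K.pooled[i] = pool_fwd(K.cb_out[i], B, H, W, K.pk[i]);
    H /= 2; W /= 2;
    h = K.pooled[i];
  }
  K.Hp[3] = H; K.Wp[3] = W;
  mat r = conv_fwd(h, B, H, W, N.red1_W, N.red1_b, 3, 3,
                   training ? &K.red1_cols : nullptr);
  K.red1_act = relu(r);
  r = conv_fwd(K.red1_act, B, H, W, N.red2_W, N.red2_b, 3, 3,
               training ? &K.red2_cols : nullptr);
  K.red2_act = relu(r);

  if (N.use_lstm) {
    K.seq = to_sequence(K.red2_act, B, H, W);
    lstm_fwd(K.seq, N.l1, K.k1);
    lstm_fwd(K.k1.h, N.l2, K.k2);
    K.feat = K.k2.h.back();
  } else {
    K.flat_in = flatten_map(K.red2_act, B);
    mat z = N.flat_W * K.flat_in;
    z.each_col() += N.flat_b;
    K.flat_act = relu(z);
    K.feat = K.flat_act;
  }
  mat z1 = N.fc1_W * K.feat; z1.each_col() += N.fc1_b;
  K.fc1_act = relu(z1);
  mat z2 = N.fc2_W * K.fc1_act; z2.each_col() += N.fc2_b;
  K.fc2_act = relu(z2);
  K.fc2_drop = (training && dropout_mask) ? mat(K.fc2_act % (*dropout_mask))
                                          : K.fc2_act;
  K.logits = N.out_W * K.fc2_drop;
  K.logits.each_col() += N.out_b;
  K.probs = softmax_cols(K.logits);
}

// ---------------------------------------------------------- entry points

// [[Rcpp::export]]
Rcpp::List cpp_net_grad(Rcpp::List params, arma::cube X,
                        Rcpp::IntegerVector y, bool use_lstm,
                        bool block_bn, bool frozen_bn, Rcpp::List bn_mean,
                        Rcpp::List bn_var, arma::mat dropout_mask) {
  Net N = load_net(params, use_lstm, block_bn);
  const int H0 = X.n_rows, W0 = X.n_cols, B = X.n_slices;
  // cube memory (y + x*H + n*H*W) matches the flat layout directly
  mat x0(X.memptr(), H0 * W0 * B, 1);
  FwdCache K;
  forward(N, x0, B, H0, W0, true, frozen_bn, &bn_mean, &bn_var,
          &dropout_mask, K);

  // cross-entropy; row 0 = barnyard_grass (y == 0), row 1 = rice
  double loss = 0;
  mat dlogits = K.probs;
  for (int n = 0; n < B; ++n) {
    loss -= std::log(std::max(K.probs(y[n], n), 1e-12));
    dlogits(y[n], n) -= 1.0;
  }
  loss /= B;
  dlogits /= B;

  Rcpp::List G;
  G["out_W"] = mat(dlogits * K.fc2_drop.t());
  G["out_b"] = vec(sum(dlogits, 1));
  mat dfc2 = N.out_W.t() * dlogits;
  dfc2 = dfc2 % dropout_mask;
  dfc2 = dfc2 % conv_to<mat>::from(K.fc2_act > 0);
  G["fc2_W"] = mat(dfc2 * K.fc1_act.t());
  G["fc2_b"] = vec(sum(dfc2, 1));
  mat dfc1 = N.fc2_W.t() * dfc2;
  dfc1 = dfc1 % conv_to<mat>::from(K.fc1_act > 0);
  G["fc1_W"] = mat(dfc1 * K.feat.t());
  G["fc1_b"] = vec(sum(dfc1, 1));
  mat dfeat = N.fc1_W.t() * dfc1;

  const int Hf = K.Hp[3], Wf = K.Wp[3], Cf = K.red2_act.n_cols;
  mat dred2;
  if (use_lstm) {
    const int T = K.seq.size(), Hd = N.l2.Wh.n_cols;
    std::vector<mat> dh2(T, mat(Hd, B, fill::zeros));
    dh2[T - 1] = dfeat;
    LSTMParams G2;
    std::vector<mat> dh1 = lstm_bwd(N.l2, K.k2, dh2, G2);
    G["lstm2_Wx"] = G2.Wx; G["lstm2_Wh"] = G2.Wh; G["lstm2_b"] = G2.b;
    LSTMParams G1;
    std::vector<mat> dseq = lstm_bwd(N.l1, K.k1, dh1, G1);
    G["lstm1_Wx"] = G1.Wx; G["lstm1_Wh"] = G1.Wh; G["lstm1_b"] = G1.b;
    dred2 = from_sequence_grad(dseq, B, Hf, Wf, Cf);
  } else {
    mat dflat = dfeat % conv_to<mat>::from(K.flat_act > 0);
    G["flat_W"] = mat(dflat * K.flat_in.t());
    G["flat_b"] = vec(sum(dflat, 1));
    dred2 = unflatten_grad(N.flat_W.t() * dflat, B, Hf * Wf, Cf);
  }

  dred2 = relu_bwd(dred2, K.red2_act);
  mat dW; vec db;
  mat d = conv_bwd(K.red2_cols, dred2, N.red2_W, B, Hf, Wf,
                   N.red2_W.n_cols / 9, 3, 3, dW, db);
  G["red2_W"] = dW; G["red2_b"] = db;
  d = relu_bwd(d, K.red1_act);
  mat dpool = conv_bwd(K.red1_cols, d, N.red1_W, B, Hf, Wf,
                       N.red1_W.n_cols / 9, 3, 3, dW, db);
  G["red1_W"] = dW; G["red1_b"] = db;

  Rcpp::List bn_mean_out(block_bn ? 7 : 1),
      bn_var_out(block_bn ? 7 : 1);
  for (int i = 2; i >= 0; --i) {
    const int H = K.Hp[i], W = K.Wp[i];
    mat dcb = pool_bwd(dpool, K.pk[i], B);
    CBAMParams Gc;
    mat dc2 = cbam_bwd(K.c2_act[i], dcb, B, H, W, N.cb[i], K.cbk[i], Gc);
    std::string c = "cb" + std::to_string(i + 1);
    G[c + "_m1_W"] = Gc.m1_W; G[c + "_m1_b"] = Gc.m1_b;
    G[c + "_m2_W"] = Gc.m2_W; G[c + "_m2_b"] = Gc.m2_b;
    G[c + "_sp_W"] = Gc.sp_W; G[c + "_sp_b"] = Gc.sp_b;
    dc2 = relu_bwd(dc2, K.c2_act[i]);
    vec dg, dbb;
    std::string p = "b" + std::to_string(i + 1);
    if (N.block_bn) {
      dc2 = frozen_bn ? bn_bwd_frozen(dc2, K.bn2[i], N.bc_g[i][1], dg, dbb)
                      : bn_bwd(dc2, K.bn2[i], N.bc_g[i][1], dg, dbb);
      G[p + "c2_g"] = dg; G[p + "c2_bb"] = dbb;
    }
    mat dc1 = conv_bwd(K.c2_cols[i], dc2, N.bc_W[i][1], B, H, W,
                       N.bc_W[i][1].n_cols / 9, 3, 3, dW, db);
    G[p + "c2_W"] = dW; G[p + "c2_b"] = db;
    dc1 = relu_bwd(dc1, K.c1_act[i]);
    if (N.block_bn) {
      dc1 = frozen_bn ? bn_bwd_frozen(dc1, K.bn1[i], N.bc_g[i][0], dg, dbb)
                      : bn_bwd(dc1, K.bn1[i], N.bc_g[i][0], dg, dbb);
      G[p + "c1_g"] = dg; G[p + "c1_bb"] = dbb;
    }
    dpool = conv_bwd(K.c1_cols[i], dc1, N.bc_W[i][0], B, H, W,
                     N.bc_W[i][0].n_cols / 9, 3, 3, dW, db);
    G[p + "c1_W"] = dW; G[p + "c1_b"] = db;
    if (N.block_bn) {
      bn_mean_out[1 + 2 * i] = K.bn1[i].mean_;
      bn_var_out[1 + 2 * i] = K.bn1[i].var_;
      bn_mean_out[2 + 2 * i] = K.bn2[i].mean_;
      bn_var_out[2 + 2 * i] = K.bn2[i].var_;
    }
  }
  mat dstem = relu_bwd(dpool, K.stem_act);
  vec dg, dbb;
  dstem = frozen_bn ? bn_bwd_frozen(dstem, K.stem_bn, N.stem_g, dg, dbb)
                    : bn_bwd(dstem, K.stem_bn, N.stem_g, dg, dbb);
  G["stem_g"] = dg; G["stem_bb"] = dbb;
  conv_bwd(K.stem_cols, dstem, N.stem_W, B, K.H0, K.W0, 1, 3, 4, dW, db);
  G["stem_W"] = dW; G["stem_b"] = db;
  bn_mean_out[0] = K.stem_bn.mean_;
  bn_var_out[0] = K.stem_bn.var_;

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("prob_pos") = vec(K.probs.row(0).t()),
      Rcpp::Named("grads") = G,
      Rcpp::Named("bn_mean") = bn_mean_out,
      Rcpp::Named("bn_var") = bn_var_out);
}

// [[Rcpp::export]]
arma::vec cpp_net_predict(Rcpp::List params, arma::cube X, bool use_lstm,
                          bool block_bn, Rcpp::List bn_mean,
                          Rcpp::List bn_var) {
  Net N = load_net(params, use_lstm, block_bn);
  const int H0 = X.n_rows, W0 = X.n_cols, B = X.n_slices;
  mat x0(X.memptr(), H0 * W0 * B, 1);
  FwdCache K;
  forward(N, x0, B, H0, W0, false, false, &bn_mean, &bn_var, nullptr, K);
  return K.probs.row(0).t();
}

// Standalone CBAM application for inspection/testing: x is (H x W x C),
// returns the gated map plus the channel and spatial attention gates.
// [[Rcpp::export]]
Rcpp::List cpp_cbam(arma::cube x, arma::mat m1_W, arma::vec m1_b,
                    arma::mat m2_W, arma::vec m2_b, arma::mat sp_W,
                    arma::vec sp_b) {
  CBAMParams P;
  P.m1_W = m1_W; P.m1_b = m1_b; P.m2_W = m2_W; P.m2_b = m2_b;
  P.sp_W = sp_W; P.sp_b = sp_b;
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat A(H * W, C);
  for (int c = 0; c < C; ++c) A.col(c) = vectorise(x.slice(c));
  CBAMCache K;
  mat out = cbam_fwd(A, 1, H, W, P, K, false);
  cube oc(H, W, C);
  for (int c = 0; c < C; ++c) oc.slice(c) = reshape(out.col(c), H, W);
  return Rcpp::List::create(Rcpp::Named("out") = oc,
                            Rcpp::Named("channel_gate") = vec(K.Mc.col(0)),
                            Rcpp::Named("spatial_gate") =
                                mat(reshape(mat(K.Ms), H, W)));
}

// Diagnostic: across-sample variation at each stage of an eval-mode
// forward pass. For each stage, reports the standard deviation (across
// samples) of the per-sample mean activation, and the overall mean
// absolute activation.
// [[Rcpp::export]]
Rcpp::List cpp_net_inspect(Rcpp::List params, arma::cube X, bool use_lstm,
                           bool block_bn, Rcpp::List bn_mean,
                           Rcpp::List bn_var) {
  Net N = load_net(params, use_lstm, block_bn);
  const int H0 = X.n_rows, W0 = X.n_cols, B = X.n_slices;
  mat x0(X.memptr(), H0 * W0 * B, 1);
  FwdCache K;
  forward(N, x0, B, H0, W0, false, false, &bn_mean, &bn_var, nullptr, K);
  auto stat_flat = [B](const mat& A) {
    const int P = A.n_rows / B;
    vec m(B);
    for (int n = 0; n < B; ++n)
      m(n) = accu(A.rows(n * P, (n + 1) * P - 1)) / (P * A.n_cols);
    return Rcpp::NumericVector::create(stddev(m), accu(abs(A)) / A.n_elem);
  };
  auto stat_cols = [](const mat& A) {   // columns = samples
    rowvec m = mean(A, 0);
    return Rcpp::NumericVector::create(stddev(m.t()), accu(abs(A)) / A.n_elem);
  };
  Rcpp::List out;
  out["stem_act"] = stat_flat(K.stem_act);
  out["pool1"] = stat_flat(K.pooled[0]);
  out["pool2"] = stat_flat(K.pooled[1]);
  out["pool3"] = stat_flat(K.pooled[2]);
  out["red2_act"] = stat_flat(K.red2_act);
  if (use_lstm) {
    out["lstm1_hT"] = stat_cols(K.k1.h.back());
    out["feat"] = stat_cols(K.feat);
  } else {
    out["feat"] = stat_cols(K.feat);
  }
  out["fc1_act"] = stat_cols(K.fc1_act);
  out["fc2_act"] = stat_cols(K.fc2_act);
  out["logit_diff_sd"] = stddev(vec((K.logits.row(0) - K.logits.row(1)).t()));
  return out;
}
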