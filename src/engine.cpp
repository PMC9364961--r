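// Single-precision CNN-LSTM training/inference engine.
//
// Semantics match the double-precision reference forward pass in R/model.R:
// parallel branches over a (T x C) epoch -- a stacked LSTM (gate order
// input/forget/candidate/output, final hidden state pooled) and a
// convolutional stack (valid convolution, batch normalization, ReLU,
// dropout, max pooling) -- concatenated and passed through ReLU fully
// connected layers to a softmax.  Training is plain minibatch SGD on
// cross-entropy with a step-decayed learning rate.
//
// Batched tensors are stored time-major: a batch of B epochs of length T
// occupies a (B*T x C) matrix whose row t*B + b is sample t of epoch b.
// Per-timestep slices are then row blocks at a fixed leading dimension, so
// the recurrence can GEMM straight into the stored gate matrix without
// intermediate copies (sgemm_ is called directly with strided outputs).

#include <RcppArmadillo.h>
#include <random>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

// Denormal single-precision values (tiny activations/gradients late in
// training) incur large microcode penalties; flush them to zero.
static inline void flush_denormals() {
#if defined(__SSE2__) || defined(__x86_64__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

using namespace arma;

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* A, const int* lda, const float* B,
                       const int* ldb, const float* beta, float* C,
                       const int* ldc);

static inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                         const float* A, int lda, const float* B, int ldb,
                         float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

#include <chrono>
static double g_t[8] = {0,0,0,0,0,0,0,0};
struct ScopedTimer {
  int slot; std::chrono::steady_clock::time_point t0;
  ScopedTimer(int s) : slot(s), t0(std::chrono::steady_clock::now()) {}
  ~ScopedTimer() {
    g_t[slot] += std::chrono::duration<double>(
      std::chrono::steady_clock::now() - t0).count();
  }
};
// [[Rcpp::export]]
Rcpp::NumericVector cpp_timings(bool reset = false) {
  Rcpp::NumericVector out(8);
  for (int i = 0; i < 8; ++i) { out[i] = g_t[i]; if (reset) g_t[i] = 0; }
  out.attr("names") = Rcpp::CharacterVector::create(
    "lstm_fwd_inproj","lstm_fwd_steps","lstm_bwd_steps","lstm_bwd_bulk",
    "conv_fwd","conv_bwd","head_fwd","other");
  return out;
}

static const float BN_EPS = 1e-5f;

// fast deterministic generator for dropout masks (xorshift128+)
struct MaskRng {
  uint64_t s0, s1;
  explicit MaskRng(uint64_t seed) {
    // splitmix64 expansion of the seed
    auto mix = [](uint64_t& z) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      return x ^ (x >> 31);
    };
    uint64_t z = seed;
    s0 = mix(z); s1 = mix(z);
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline float unif() {            // in [0, 1)
    return (next() >> 40) * (1.0f / 16777216.0f);
  }
};

struct LstmLayer { fmat Wx, Uh; frowvec b; };
struct ConvLayer {
  fmat K; frowvec b, gamma, beta, rmean, rvar;
  int klen, Cin, F, Lout, Pout;
};
struct FcLayer   { fmat W; frowvec b; };

struct Cfg {
  int T, C, U, NL, pool, K;       // K = n_classes
  double dropout_conv, dropout_fc;
};

struct Model {
  std::vector<LstmLayer> lstm;
  std::vector<ConvLayer> conv;
  std::vector<FcLayer> fc;
  fmat out_W; frowvec out_b;
};

static fmat getM(const Rcpp::List& p, const std::string& nm) {
  return conv_to<fmat>::from(Rcpp::as<arma::mat>(p[nm]));
}
static frowvec getV(const Rcpp::List& p, const std::string& nm) {
  return conv_to<frowvec>::from(Rcpp::as<arma::rowvec>(p[nm]));
}

static Model load_model(const Rcpp::List& params, const Cfg& cfg,
                        const Rcpp::IntegerVector& conv_filters,
                        const Rcpp::IntegerVector& conv_kernels,
                        const Rcpp::IntegerVector& fc_sizes) {
  Model m;
  char nm[64];
  for (int l = 1; l <= cfg.NL; ++l) {
    LstmLayer L;
    snprintf(nm, 64, "lstm%d_Wx", l); L.Wx = getM(params, nm);
    snprintf(nm, 64, "lstm%d_Uh", l); L.Uh = getM(params, nm);
    snprintf(nm, 64, "lstm%d_b", l);  L.b  = getV(params, nm);
    m.lstm.push_back(std::move(L));
  }
  int cin = cfg.C, len = cfg.T;
  for (int i = 1; i <= conv_filters.size(); ++i) {
    ConvLayer L;
    snprintf(nm, 64, "conv%d_K", i);     L.K     = getM(params, nm);
    snprintf(nm, 64, "conv%d_b", i);     L.b     = getV(params, nm);
    snprintf(nm, 64, "conv%d_gamma", i); L.gamma = getV(params, nm);
    snprintf(nm, 64, "conv%d_beta", i);  L.beta  = getV(params, nm);
    snprintf(nm, 64, "conv%d_rmean", i); L.rmean = getV(params, nm);
    snprintf(nm, 64, "conv%d_rvar", i);  L.rvar  = getV(params, nm);
    L.klen = conv_kernels[i - 1]; L.Cin = cin; L.F = conv_filters[i - 1];
    L.Lout = len - L.klen + 1;
    L.Pout = L.Lout / cfg.pool;
    len = L.Pout; cin = L.F;
    m.conv.push_back(std::move(L));
  }
  for (int i = 1; i <= fc_sizes.size(); ++i) {
    FcLayer L;
    snprintf(nm, 64, "fc%d_W", i); L.W = getM(params, nm);
    snprintf(nm, 64, "fc%d_b", i); L.b = getV(params, nm);
    m.fc.push_back(std::move(L));
  }
  m.out_W = getM(params, "out_W");
  m.out_b = getV(params, "out_b");
  return m;
}

static void store_model(Rcpp::List& params, const Model& m, const Cfg& cfg) {
  char nm[64];
  auto putM = [&](const std::string& n, const fmat& M) {
    params[n] = Rcpp::wrap(conv_to<arma::mat>::from(M));
  };
  auto putV = [&](const std::string& n, const frowvec& v) {
    Rcpp::NumericVector out(v.n_elem);
    for (uword i = 0; i < v.n_elem; ++i) out[i] = v[i];
    params[n] = out;
  };
  for (int l = 1; l <= cfg.NL; ++l) {
    snprintf(nm, 64, "lstm%d_Wx", l); putM(nm, m.lstm[l-1].Wx);
    snprintf(nm, 64, "lstm%d_Uh", l); putM(nm, m.lstm[l-1].Uh);
    snprintf(nm, 64, "lstm%d_b", l);  putV(nm, m.lstm[l-1].b);
  }
  for (size_t i = 1; i <= m.conv.size(); ++i) {
    snprintf(nm, 64, "conv%d_K", (int)i);     putM(nm, m.conv[i-1].K);
    snprintf(nm, 64, "conv%d_b", (int)i);     putV(nm, m.conv[i-1].b);
    snprintf(nm, 64, "conv%d_gamma", (int)i); putV(nm, m.conv[i-1].gamma);
    snprintf(nm, 64, "conv%d_beta", (int)i);  putV(nm, m.conv[i-1].beta);
    snprintf(nm, 64, "conv%d_rmean", (int)i); putV(nm, m.conv[i-1].rmean);
    snprintf(nm, 64, "conv%d_rvar", (int)i);  putV(nm, m.conv[i-1].rvar);
  }
  for (size_t i = 1; i <= m.fc.size(); ++i) {
    snprintf(nm, 64, "fc%d_W", (int)i); putM(nm, m.fc[i-1].W);
    snprintf(nm, 64, "fc%d_b", (int)i); putV(nm, m.fc[i-1].b);
  }
  putM("out_W", m.out_W);
  putV("out_b", m.out_b);
}

// gather a batch into time-major (B*T x C)
static fmat make_batch(const double* xp, int T, int C,
                       const std::vector<int>& idx) {
  int B = idx.size();
  fmat Z(B * T, C);
  for (int b = 0; b < B; ++b) {
    const double* base = xp + (size_t)idx[b] * T * C;
    for (int c = 0; c < C; ++c) {
      const double* col = base + (size_t)c * T;
      float* zc = Z.colptr(c);
      for (int t = 0; t < T; ++t) zc[(size_t)t * B + b] = (float)col[t];
    }
  }
  return Z;
}

// Rational tanh approximation (13/6-degree odd/even polynomials, clamped;
// max error ~1e-7, below single-precision accumulation noise).
// Branch-free and vectorizable, unlike libm tanhf/expf.
static inline float fast_tanh(float x) {
  x = std::max(-9.0f, std::min(9.0f, x));
  const float x2 = x * x;
  float np = -2.76076847742355e-16f;
  np = np * x2 + 2.00018790482477e-13f;
  np = np * x2 + -8.60467152213735e-11f;
  np = np * x2 + 5.12229709037114e-08f;
  np = np * x2 + 1.48572235717979e-05f;
  np = np * x2 + 6.37261928875436e-04f;
  np = np * x2 + 4.89352455891786e-03f;
  np = np * x;
  float dq = 1.19825839466702e-06f;
  dq = dq * x2 + 1.18534705686654e-04f;
  dq = dq * x2 + 2.26843463243900e-03f;
  dq = dq * x2 + 4.89352518554385e-03f;
  return np / dq;
}

static inline float sigf(float x) {
  return 0.5f * (1.0f + fast_tanh(0.5f * x));
}

// ---------------------------------------------------------------------
// LSTM layer, training path: all step tensors live in (B*T x .) matrices
// with leading dimension B*T; the recurrence GEMMs straight into them.

struct LstmCache { fmat A, Cs, TC, H; };   // gates, cell, tanh(cell), hidden

static void lstm_forward_train(const LstmLayer& L, const fmat& Z, int B,
                               int T, LstmCache& ca) {
  const int U = L.Uh.n_rows, G = 4 * U, D = Z.n_cols, BT = B * T;
  ca.A.set_size(BT, G); ca.Cs.set_size(BT, U);
  ca.TC.set_size(BT, U); ca.H.set_size(BT, U);
  // input contribution for every step in one GEMM
  { ScopedTimer st(0);
  sgemm('N', 'N', BT, G, D, 1.0f, Z.memptr(), BT, L.Wx.memptr(), D, 0.0f,
        ca.A.memptr(), BT); }
  ScopedTimer st1(1);
  const float* bi = L.b.memptr();
  const float* bf = bi + U;
  const float* bg = bi + 2 * U;
  const float* bo = bi + 3 * U;
  for (int t = 0; t < T; ++t) {
    if (t > 0)
      sgemm('N', 'N', B, G, U, 1.0f, ca.H.memptr() + (t - 1) * B, BT,
            L.Uh.memptr(), U, 1.0f, ca.A.memptr() + t * B, BT);
    for (int u = 0; u < U; ++u) {
      float* pi = ca.A.colptr(u) + t * B;
      float* pf = ca.A.colptr(U + u) + t * B;
      float* pg = ca.A.colptr(2 * U + u) + t * B;
      float* po = ca.A.colptr(3 * U + u) + t * B;
      float* pc = ca.Cs.colptr(u) + t * B;
      float* ptc = ca.TC.colptr(u) + t * B;
      float* ph = ca.H.colptr(u) + t * B;
      const float* pcprev = pc - B;
      for (int b = 0; b < B; ++b) {
        float ig = sigf(pi[b] + bi[u]);
        float fg = sigf(pf[b] + bf[u]);
        float gg = fast_tanh(pg[b] + bg[u]);
        float og = sigf(po[b] + bo[u]);
        pi[b] = ig; pf[b] = fg; pg[b] = gg; po[b] = og;
        float cv = ig * gg + (t > 0 ? fg * pcprev[b] : 0.0f);
        pc[b] = cv;
        float tc = fast_tanh(cv);
        ptc[b] = tc;
        ph[b] = og * tc;
      }
    }
  }
}

// Backward; dH holds the gradient on the full hidden sequence.  The gate
// matrix ca.A is overwritten in place with pre-activation gradients.
// Returns the input gradient when wanted.
static fmat lstm_backward(LstmLayer& L, const fmat& Z, LstmCache& ca,
                          const fmat& dH, int B, int T, float lr,
                          bool want_dZ) {
  const int U = L.Uh.n_rows, G = 4 * U, D = Z.n_cols, BT = B * T;
  fmat dh(B, U), dc(B, U, fill::zeros);
  dh = dH.rows((T - 1) * B, BT - 1);
  { ScopedTimer st(2);
  for (int t = T - 1; t >= 0; --t) {
    if (t < T - 1) dh += dH.rows(t * B, t * B + B - 1);
    for (int u = 0; u < U; ++u) {
      float* pi = ca.A.colptr(u) + t * B;
      float* pf = ca.A.colptr(U + u) + t * B;
      float* pg = ca.A.colptr(2 * U + u) + t * B;
      float* po = ca.A.colptr(3 * U + u) + t * B;
      const float* ptc = ca.TC.colptr(u) + t * B;
      const float* pcprev = ca.Cs.colptr(u) + (t - 1) * B;
      float* pdh = dh.colptr(u);
      float* pdc = dc.colptr(u);
      for (int b = 0; b < B; ++b) {
        float ig = pi[b], fg = pf[b], gg = pg[b], og = po[b];
        float tc = ptc[b];
        float dout = pdh[b];
        float dcc = pdc[b] + dout * og * (1.0f - tc * tc);
        float cpv = (t > 0) ? pcprev[b] : 0.0f;
        pdc[b] = dcc * fg;
        pi[b] = (dcc * gg) * ig * (1.0f - ig);
        pf[b] = (dcc * cpv) * fg * (1.0f - fg);
        pg[b] = (dcc * ig) * (1.0f - gg * gg);
        po[b] = (dout * tc) * og * (1.0f - og);
      }
    }
    if (t > 0)
      sgemm('N', 'T', B, U, G, 1.0f, ca.A.memptr() + t * B, BT,
            L.Uh.memptr(), U, 0.0f, dh.memptr(), B);
  }
  }
  ScopedTimer st3(3);
  // bulk parameter gradients: dWx = Z' dG; dUh = H[0..T-2]' dG[1..T-1]
  fmat dWx(D, G), dUh(U, G);
  sgemm('T', 'N', D, G, BT, 1.0f, Z.memptr(), BT, ca.A.memptr(), BT, 0.0f,
        dWx.memptr(), D);
  if (T > 1)
    sgemm('T', 'N', U, G, B * (T - 1), 1.0f, ca.H.memptr(), BT,
          ca.A.memptr() + B, BT, 0.0f, dUh.memptr(), U);
  else dUh.zeros();
  frowvec db = sum(ca.A, 0);
  fmat dZ;
  if (want_dZ) {
    dZ.set_size(BT, D);
    sgemm('N', 'T', BT, D, G, 1.0f, ca.A.memptr(), BT, L.Wx.memptr(), D,
          0.0f, dZ.memptr(), BT);
  }
  L.Wx -= lr * dWx;
  L.Uh -= lr * dUh;
  L.b  -= lr * db;
  return dZ;
}

// inference-only forward (no cache; bounded memory)
static void lstm_forward_infer(const LstmLayer& L, const fmat& Z, int B,
                               int T, fmat& Hout) {
  const int U = L.Uh.n_rows, G = 4 * U, D = Z.n_cols, BT = B * T;
  fmat Gin = Z * L.Wx;
  Gin.each_row() += L.b;
  fmat h(B, U, fill::zeros), c(B, U, fill::zeros), Gt(B, G);
  Hout.set_size(BT, U);
  for (int t = 0; t < T; ++t) {
    Gt = Gin.rows(t * B, t * B + B - 1);
    if (t > 0)
      sgemm('N', 'N', B, G, U, 1.0f, h.memptr(), B, L.Uh.memptr(), U, 1.0f,
            Gt.memptr(), B);
    float* g = Gt.memptr();
    float* cp = c.memptr();
    float* hp = h.memptr();
    const int n = B * U;
    for (int j = 0; j < n; ++j) {
      float ig = sigf(g[j]);
      float fg = sigf(g[n + j]);
      float gg = fast_tanh(g[2 * n + j]);
      float og = sigf(g[3 * n + j]);
      cp[j] = fg * cp[j] + ig * gg;
      hp[j] = og * fast_tanh(cp[j]);
    }
    Hout.rows(t * B, t * B + B - 1) = h;
  }
}

// ---------------------------------------------------------------------
// convolutional layer

// im2col for time-major batches: output (B*Lout x klen*Cin)
static fmat im2col(const fmat& Z, int B, int klen, int Cin, int Lout) {
  fmat M(B * Lout, klen * Cin);
  for (int m = 0; m < klen; ++m)
    M.cols(m * Cin, m * Cin + Cin - 1) = Z.rows(m * B, (m + Lout) * B - 1);
  return M;
}

struct ConvCache {
  fmat M;          // im2col input
  fmat Xhat;       // batch-normalized pre-activation
  frowvec istd;    // 1/sqrt(var+eps)
  fmat Act;        // post ReLU+dropout (pre-pool)
  fmat Drop;       // dropout mask (scaled), empty if none
  umat ArgM;       // pooling argmax offsets
};

static fmat conv_forward(ConvLayer& L, const fmat& Z, int B, int pool,
                         bool training, float drop_p, MaskRng* rng,
                         float bn_momentum, ConvCache* ca) {
  ScopedTimer st(4);
  fmat M = im2col(Z, B, L.klen, L.Cin, L.Lout);
  fmat Zc = M * L.K;
  Zc.each_row() += L.b;
  frowvec mu, var, istd;
  if (training) {
    mu = mean(Zc, 0);
    var = mean(square(Zc.each_row() - mu), 0);
    L.rmean = (1.0f - bn_momentum) * L.rmean + bn_momentum * mu;
    L.rvar  = (1.0f - bn_momentum) * L.rvar  + bn_momentum * var;
  } else {
    mu = L.rmean; var = L.rvar;
  }
  istd = 1.0f / sqrt(var + BN_EPS);
  fmat Xhat = (Zc.each_row() - mu).each_row() % istd;
  fmat Y = (Xhat.each_row() % L.gamma).each_row() + L.beta;
  Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fmat Drop;
  if (training && drop_p > 0.0f) {
    Drop.set_size(Y.n_rows, Y.n_cols);
    const float scale = 1.0f / (1.0f - drop_p);
    float* dp = Drop.memptr();
    for (uword j = 0; j < Drop.n_elem; ++j)
      dp[j] = (rng->unif() < drop_p) ? 0.0f : scale;
    Y %= Drop;
  }
  fmat P(B * L.Pout, L.F);
  umat AM(B * L.Pout, L.F);
  for (int p = 0; p < L.Pout; ++p) {
    fmat best = Y.rows(p * pool * B, p * pool * B + B - 1);
    umat am(B, L.F, fill::zeros);
    for (int o = 1; o < pool; ++o) {
      fmat cand = Y.rows((p * pool + o) * B, (p * pool + o) * B + B - 1);
      uvec upd = find(cand > best);
      best(upd) = cand(upd);
      am(upd).fill(o);
    }
    P.rows(p * B, p * B + B - 1) = best;
    AM.rows(p * B, p * B + B - 1) = am;
  }
  if (ca) {
    ca->M = std::move(M); ca->Xhat = std::move(Xhat); ca->istd = istd;
    ca->Act = std::move(Y); ca->Drop = std::move(Drop);
    ca->ArgM = std::move(AM);
  }
  return P;
}

static fmat conv_backward(ConvLayer& L, const ConvCache& ca, const fmat& dP,
                          int B, int pool, float lr, bool want_dZ, int Tin) {
  ScopedTimer st(5);
  fmat dY(ca.Act.n_rows, ca.Act.n_cols, fill::zeros);
  for (int p = 0; p < L.Pout; ++p) {
    const fmat dPr = dP.rows(p * B, p * B + B - 1);
    const umat am = ca.ArgM.rows(p * B, p * B + B - 1);
    for (int f = 0; f < L.F; ++f)
      for (int b = 0; b < B; ++b)
        dY((p * pool + am(b, f)) * B + b, f) += dPr(b, f);
  }
  if (!ca.Drop.is_empty()) dY %= ca.Drop;
  dY %= conv_to<fmat>::from(ca.Act > 0.0f);
  // batch-norm backward
  const float Nr = (float)dY.n_rows;
  frowvec dgamma = sum(dY % ca.Xhat, 0);
  frowvec dbeta = sum(dY, 0);
  fmat dXhat = dY.each_row() % L.gamma;
  frowvec s1 = sum(dXhat, 0);
  frowvec s2 = sum(dXhat % ca.Xhat, 0);
  fmat dZc = dXhat * Nr;
  dZc.each_row() -= s1;
  dZc -= ca.Xhat.each_row() % s2;
  dZc.each_row() %= (ca.istd / Nr);
  fmat dK = ca.M.t() * dZc;
  frowvec db = sum(dZc, 0);
  fmat dZ;
  if (want_dZ) {
    fmat dM = dZc * L.K.t();
    dZ.zeros(B * Tin, L.Cin);
    for (int m = 0; m < L.klen; ++m)
      dZ.rows(m * B, (m + L.Lout) * B - 1) +=
        dM.cols(m * L.Cin, m * L.Cin + L.Cin - 1);
  }
  L.K -= lr * dK;
  L.b -= lr * db;
  L.gamma -= lr * dgamma;
  L.beta -= lr * dbeta;
  return dZ;
}

// ---------------------------------------------------------------------
// full-network batch forward/backward

struct BatchCache {
  fmat Z;
  std::vector<LstmCache> lstm;
  std::vector<fmat> conv_in;
  std::vector<ConvCache> conv;
  fmat Concat;
  std::vector<fmat> fc_pre;
  std::vector<fmat> fc_out;
  std::vector<fmat> fc_drop;
  fmat Probs;
};

static fmat forward_batch(Model& m, const Cfg& cfg, const fmat& Z, int B,
                          bool training, MaskRng* rng, float bn_momentum,
                          BatchCache* ca) {
  const int T = cfg.T;
  fmat feat_lstm;
  if (training) {
    ca->Z = Z;
    ca->lstm.resize(cfg.NL);
    const fmat* in = &ca->Z;
    for (int l = 0; l < cfg.NL; ++l) {
      lstm_forward_train(m.lstm[l], *in, B, T, ca->lstm[l]);
      in = &ca->lstm[l].H;
    }
    feat_lstm = in->rows((T - 1) * B, B * T - 1);
  } else {
    fmat H, Hin = Z;
    for (int l = 0; l < cfg.NL; ++l) {
      lstm_forward_infer(m.lstm[l], Hin, B, T, H);
      Hin = H;
    }
    feat_lstm = H.rows((T - 1) * B, B * T - 1);
  }
  // conv branch
  fmat A = Z;
  if (ca) ca->conv.resize(m.conv.size());
  for (size_t i = 0; i < m.conv.size(); ++i) {
    if (ca) ca->conv_in.push_back(A);
    A = conv_forward(m.conv[i], A, B, cfg.pool, training,
                     (float)cfg.dropout_conv, rng, bn_momentum,
                     ca ? &ca->conv[i] : nullptr);
  }
  ScopedTimer sth(6);
  const ConvLayer& last = m.conv.back();
  const int P = last.Pout, F = last.F;
  fmat flat(B, P * F);   // col p*F + f  <-  A(p*B + b, f)
  for (int p = 0; p < P; ++p)
    flat.cols(p * F, p * F + F - 1) = A.rows(p * B, (p + 1) * B - 1);
  fmat X = join_rows(feat_lstm, flat);
  if (ca) ca->Concat = X;
  for (size_t i = 0; i < m.fc.size(); ++i) {
    fmat Zf = X * m.fc[i].W;
    Zf.each_row() += m.fc[i].b;
    if (ca) ca->fc_pre.push_back(Zf);
    Zf.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    fmat Dm;
    if (training && cfg.dropout_fc > 0) {
      const float p = (float)cfg.dropout_fc, s = 1.0f / (1.0f - p);
      Dm.set_size(Zf.n_rows, Zf.n_cols);
      float* dp = Dm.memptr();
      for (uword j = 0; j < Dm.n_elem; ++j)
        dp[j] = (rng->unif() < p) ? 0.0f : s;
      Zf %= Dm;
    }
    if (ca) { ca->fc_out.push_back(Zf); ca->fc_drop.push_back(Dm); }
    X = Zf;
  }
  fmat logits = X * m.out_W;
  logits.each_row() += m.out_b;
  for (int b = 0; b < B; ++b) {
    frowvec r = logits.row(b);
    r -= r.max();
    r = exp(r);
    logits.row(b) = r / accu(r);
  }
  if (ca) ca->Probs = logits;
  return logits;
}

static void backward_batch(Model& m, const Cfg& cfg, BatchCache& ca,
                           const Rcpp::IntegerVector& y,
                           const std::vector<int>& idx, float lr) {
  const int B = idx.size(), T = cfg.T, U = cfg.U;
  fmat dlog = ca.Probs;
  for (int b = 0; b < B; ++b) dlog(b, y[idx[b]]) -= 1.0f;
  dlog /= (float)B;
  fmat dX = dlog * m.out_W.t();
  {
    const fmat& last = ca.fc_out.empty() ? ca.Concat : ca.fc_out.back();
    fmat dWo = last.t() * dlog;
    frowvec dbo = sum(dlog, 0);
    m.out_W -= lr * dWo;
    m.out_b -= lr * dbo;
  }
  for (int i = (int)m.fc.size() - 1; i >= 0; --i) {
    if (!ca.fc_drop[i].is_empty()) dX %= ca.fc_drop[i];
    dX %= conv_to<fmat>::from(ca.fc_pre[i] > 0.0f);
    const fmat& in = (i == 0) ? ca.Concat : ca.fc_out[i - 1];
    fmat dW = in.t() * dX;
    frowvec db = sum(dX, 0);
    fmat dIn = dX * m.fc[i].W.t();
    m.fc[i].W -= lr * dW;
    m.fc[i].b -= lr * db;
    dX = dIn;
  }
  fmat dLstmLast = dX.cols(0, U - 1);
  const ConvLayer& last = m.conv.back();
  const int P = last.Pout, F = last.F;
  fmat dPool(B * P, F);
  for (int p = 0; p < P; ++p)
    dPool.rows(p * B, (p + 1) * B - 1) = dX.cols(U + p * F, U + p * F + F - 1);
  fmat dA = dPool;
  for (int i = (int)m.conv.size() - 1; i >= 0; --i) {
    const int Tin = ca.conv_in[i].n_rows / B;
    dA = conv_backward(m.conv[i], ca.conv[i], dA, B, cfg.pool, lr, i > 0,
                       Tin);
  }
  // LSTM branch: gradient arrives only at the last step of the top layer
  fmat dH(B * T, U, fill::zeros);
  dH.rows((T - 1) * B, T * B - 1) = dLstmLast;
  for (int l = cfg.NL - 1; l >= 0; --l) {
    const fmat& in = (l == 0) ? ca.Z : ca.lstm[l - 1].H;
    fmat dZ = lstm_backward(m.lstm[l], in, ca.lstm[l], dH, B, T, lr, l > 0);
    dH = dZ;
  }
}

// ---------------------------------------------------------------------
// exported entry points

static Cfg read_cfg(const Rcpp::List& cfg) {
  Cfg c;
  c.T = cfg["input_len"]; c.C = cfg["input_channels"];
  c.U = cfg["lstm_units"]; c.NL = cfg["lstm_layers"];
  c.pool = cfg["pool_size"]; c.K = cfg["n_classes"];
  c.dropout_conv = cfg["dropout_conv"]; c.dropout_fc = cfg["dropout_fc"];
  return c;
}

static double eval_set(Model& m, const Cfg& cfg, const double* xp, int N,
                       const Rcpp::IntegerVector& y, double* acc_out) {
  double loss = 0; int correct = 0;
  const int chunk = 256;
  for (int s = 0; s < N; s += chunk) {
    int B = std::min(chunk, N - s);
    std::vector<int> idx(B);
    for (int b = 0; b < B; ++b) idx[b] = s + b;
    fmat Z = make_batch(xp, cfg.T, cfg.C, idx);
    fmat P = forward_batch(m, cfg, Z, B, false, nullptr, 0.0f, nullptr);
    for (int b = 0; b < B; ++b) {
      loss += -std::log(std::max(P(b, y[s + b]), 1e-12f));
      if ((int)P.row(b).index_max() == y[s + b]) ++correct;
    }
  }
  if (acc_out) *acc_out = (double)correct / N;
  return loss / N;
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List params, Rcpp::NumericVector x,
                     Rcpp::IntegerVector y, Rcpp::List cfg_list,
                     Rcpp::IntegerVector conv_filters,
                     Rcpp::IntegerVector conv_kernels,
                     Rcpp::IntegerVector fc_sizes, int epochs, int batch,
                     double lr_init, double lr_decay_factor,
                     int lr_decay_every, double bn_momentum, int seed,
                     Rcpp::Nullable<Rcpp::NumericVector> xval_ = R_NilValue,
                     Rcpp::Nullable<Rcpp::IntegerVector> yval_ = R_NilValue,
                     bool verbose = false) {
  flush_denormals();
  Cfg cfg = read_cfg(cfg_list);
  Rcpp::IntegerVector xdim = x.attr("dim");
  const int N = xdim[2];
  if (xdim[0] != cfg.T || xdim[1] != cfg.C)
    Rcpp::stop("input tensor does not match the model configuration");
  Model m = load_model(params, cfg, conv_filters, conv_kernels, fc_sizes);
  std::mt19937 shuffler(seed);
  MaskRng mask_rng(0x5EEDull * (uint64_t)(seed + 1));
  const double* xp = x.begin();
  bool has_val = xval_.isNotNull();
  Rcpp::NumericVector xval;
  Rcpp::IntegerVector yval;
  int Nval = 0;
  if (has_val) {
    xval = xval_.get(); yval = yval_.get();
    Rcpp::IntegerVector vd = xval.attr("dim");
    Nval = vd[2];
  }
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  Rcpp::NumericVector ep_v(epochs), lr_v(epochs), tl_v(epochs), ta_v(epochs),
    vl_v(epochs), va_v(epochs);
  BatchCache ca;
  for (int e = 0; e < epochs; ++e) {
    float lr = (float)(lr_init *
                       std::pow(lr_decay_factor, e / lr_decay_every));
    std::shuffle(order.begin(), order.end(), shuffler);
    double loss = 0; int correct = 0;
    for (int s = 0; s < N; s += batch) {
      int B = std::min(batch, N - s);
      std::vector<int> idx(order.begin() + s, order.begin() + s + B);
      fmat Z = make_batch(xp, cfg.T, cfg.C, idx);
      ca.conv_in.clear(); ca.fc_pre.clear(); ca.fc_out.clear();
      ca.fc_drop.clear();
      fmat P = forward_batch(m, cfg, Z, B, true, &mask_rng,
                             (float)bn_momentum, &ca);
      for (int b = 0; b < B; ++b) {
        loss += -std::log(std::max(P(b, y[idx[b]]), 1e-12f));
        if ((int)P.row(b).index_max() == y[idx[b]]) ++correct;
      }
      backward_batch(m, cfg, ca, y, idx, lr);
      if ((s / batch) % 64 == 0) Rcpp::checkUserInterrupt();
    }
    loss /= N;
    if (!std::isfinite(loss))
      Rcpp::stop("training diverged: non-finite loss at epoch %d", e + 1);
    ep_v[e] = e + 1; lr_v[e] = lr; tl_v[e] = loss;
    ta_v[e] = (double)correct / N;
    if (has_val) {
      double vacc;
      vl_v[e] = eval_set(m, cfg, xval.begin(), Nval, yval, &vacc);
      va_v[e] = vacc;
    } else {
      vl_v[e] = NA_REAL; va_v[e] = NA_REAL;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (e + 1) << " lr " << lr << " loss " << loss
                  << " acc " << ta_v[e] << "\n";
  }
  Rcpp::List out_params = Rcpp::clone(params);
  store_model(out_params, m, cfg);
  return Rcpp::List::create(
    Rcpp::Named("params") = out_params,
    Rcpp::Named("history") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = ep_v, Rcpp::Named("lr") = lr_v,
      Rcpp::Named("train_loss") = tl_v, Rcpp::Named("train_acc") = ta_v,
      Rcpp::Named("val_loss") = vl_v, Rcpp::Named("val_acc") = va_v));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_predict(Rcpp::List params, Rcpp::NumericVector x,
                                Rcpp::List cfg_list,
                                Rcpp::IntegerVector conv_filters,
                                Rcpp::IntegerVector conv_kernels,
                                Rcpp::IntegerVector fc_sizes) {
  flush_denormals();
  Cfg cfg = read_cfg(cfg_list);
  Rcpp::IntegerVector xdim = x.attr("dim");
  const int N = xdim[2];
  if (xdim[0] != cfg.T || xdim[1] != cfg.C)
    Rcpp::stop("input tensor does not match the model configuration");
  Model m = load_model(params, cfg, conv_filters, conv_kernels, fc_sizes);
  Rcpp::NumericMatrix out(N, cfg.K);
  const int chunk = 256;
  const double* xp = x.begin();
  for (int s = 0; s < N; s += chunk) {
    int B = std::min(chunk, N - s);
    std::vector<int> idx(B);
    for (int b = 0; b < B; ++b) idx[b] = s + b;
    fmat Z = make_batch(xp, cfg.T, cfg.C, idx);
    fmat P = forward_batch(m, cfg, Z, B, false, nullptr, 0.0f, nullptr);
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < cfg.K; ++k) out(s + b, k) = P(b, k);
  }
  return out;
}
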