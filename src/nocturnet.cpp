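// Two-branch attention CNN for sleep staging: float32 forward/backward,
// gradient-gated transitive training, Adam. Activations are stored as
// C x (T*B) matrices with per-instance column blocks; convolutions are
// realised as im2col + GEMM. Loss scalars accumulate in double.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <random>
#include <cstring>
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "unroll-loops")
#endif

// Large activation buffers are allocated afresh every iteration; raising
// the mmap threshold lets glibc recycle them from the heap instead of
// returning zeroed pages to the kernel each time.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
}
using arma::fmat;
using arma::fvec;
using arma::uvec;

static const int N_CLS = 5;

// ---------------------------------------------------------------- config
struct Cfg {
  int Cin, Tin, k, pad, nctx, red;
  std::vector<int> ch;
  std::vector<std::pair<int, int>> strides;
  std::vector<int> elb_hidden, slb_hidden;
  int nb() const { return (int)ch.size(); }
  int fdim() const { return ch.back(); }
  int win() const { return 2 * nctx + 1; }
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.Cin = as<int>(cfg["in_channels"]);
  c.Tin = as<int>(cfg["in_samples"]);
  c.k = as<int>(cfg["kernel_width"]);
  c.pad = c.k / 2;
  c.nctx = as<int>(cfg["n_context"]);
  c.red = as<int>(cfg["mlp_reduction_ratio"]);
  c.ch = as<std::vector<int>>(cfg["block_channels"]);
  IntegerMatrix st = cfg["block_strides"];
  for (int i = 0; i < st.nrow(); ++i) c.strides.push_back({st(i, 0), st(i, 1)});
  c.elb_hidden = as<std::vector<int>>(cfg["elb_hidden"]);
  c.slb_hidden = as<std::vector<int>>(cfg["slb_hidden"]);
  return c;
}

// ---------------------------------------------------------------- params
struct Params {
  std::vector<std::string> names;
  std::vector<fmat> vals;
  std::unordered_map<std::string, int> idx;
  fmat& get(const std::string& n) {
    auto it = idx.find(n);
    if (it == idx.end()) stop("missing parameter: " + n);
    return vals[it->second];
  }
  void add(const std::string& n, fmat v) {
    idx[n] = (int)names.size();
    names.push_back(n);
    vals.push_back(std::move(v));
  }
};

static Params params_from_list(const List& pl) {
  Params p;
  CharacterVector nm = pl.names();
  for (int i = 0; i < pl.size(); ++i) {
    NumericMatrix m = as<NumericMatrix>(pl[i]);
    fmat f(m.nrow(), m.ncol());
    for (int c = 0; c < m.ncol(); ++c)
      for (int r = 0; r < m.nrow(); ++r) f(r, c) = (float)m(r, c);
    p.add(as<std::string>(nm[i]), std::move(f));
  }
  return p;
}

static List params_to_list(const Params& p) {
  List out(p.names.size());
  CharacterVector nm(p.names.size());
  for (size_t i = 0; i < p.names.size(); ++i) {
    const fmat& f = p.vals[i];
    NumericMatrix m(f.n_rows, f.n_cols);
    for (size_t c = 0; c < f.n_cols; ++c)
      for (size_t r = 0; r < f.n_rows; ++r) m(r, c) = (double)f(r, c);
    nm[i] = p.names[i];
    out[i] = m;
  }
  out.names() = nm;
  return out;
}

static bool is_state(const std::string& n) {
  // BN running statistics are state, not trainable parameters
  return n.size() > 5 && (n.substr(n.size() - 5) == ".mean" || n.substr(n.size() - 4) == ".var");
}

// ---------------------------------------------------------------- im2col
static int out_len(int T, int k, int stride, int pad) {
  return (T + 2 * pad - k) / stride + 1;
}

static fmat im2col(const fmat& A, int C, int T, int B, int k, int stride, int pad, int& To) {
  To = out_len(T, k, stride, pad);
  fmat P(C * k, (size_t)To * B);
  const float* a = A.memptr();
  float* p = P.memptr();
  const size_t prow = (size_t)C * k;
  for (int b = 0; b < B; ++b) {
    const size_t a0 = (size_t)b * T, p0 = (size_t)b * To;
    for (int t = 0; t < To; ++t) {
      const int in0 = t * stride - pad;
      float* dst = p + (p0 + t) * prow;
      if (in0 >= 0 && in0 + k <= T) {
        std::memcpy(dst, a + (a0 + in0) * C, sizeof(float) * C * k);
      } else {
        for (int kk = 0; kk < k; ++kk) {
          const int ti = in0 + kk;
          if (ti < 0 || ti >= T) std::memset(dst + (size_t)kk * C, 0, sizeof(float) * C);
          else std::memcpy(dst + (size_t)kk * C, a + (a0 + ti) * C, sizeof(float) * C);
        }
      }
    }
  }
  return P;
}

static void col2im(const fmat& dP, fmat& dA, int C, int T, int B, int k, int stride, int pad, int To) {
  const float* p = dP.memptr();
  float* a = dA.memptr();
  const size_t prow = (size_t)C * k;
  const bool disjoint = stride >= k;  // patches never overlap: assign, no +=
  for (int b = 0; b < B; ++b) {
    const size_t a0 = (size_t)b * T, p0 = (size_t)b * To;
    for (int t = 0; t < To; ++t) {
      const int in0 = t * stride - pad;
      const float* src = p + (p0 + t) * prow;
      if (in0 >= 0 && in0 + k <= T) {
        float* dst = a + (a0 + in0) * C;
        const int nn = C * k;
        if (disjoint) {
          std::memcpy(dst, src, sizeof(float) * nn);
        } else {
          for (int q = 0; q < nn; ++q) dst[q] += src[q];
        }
      } else {
        for (int kk = 0; kk < k; ++kk) {
          const int ti = in0 + kk;
          if (ti < 0 || ti >= T) continue;
          float* dst = a + (a0 + ti) * C;
          const float* sp = src + (size_t)kk * C;
          for (int c = 0; c < C; ++c) dst[c] += sp[c];
        }
      }
    }
  }
}

// ---------------------------------------------------------------- batchnorm
struct BNCache {
  fvec invstd;
  fmat xhat;
};

// fused batch-norm forward (optionally with ReLU applied to the output);
// mean/variance use two robust centred passes, the third pass writes
// xhat and the affine output together
static fmat bn_train(const fmat& Y, const fmat& g, const fmat& b, fmat& rmean, fmat& rvar,
                     BNCache& cc, bool relu = false, float momentum = 0.1f) {
  const int C = Y.n_rows;
  const size_t N = Y.n_cols;
  const float eps = 1e-5f;
  const double dN = (double)N;
  const float* y = Y.memptr();
  // single pass with double accumulators (no cancellation at float scale)
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (size_t j = 0; j < N; ++j) {
    const float* col = y + (size_t)j * C;
    for (int c = 0; c < C; ++c) {
      const double v = col[c];
      s1[c] += v;
      s2[c] += v * v;
    }
  }
  fvec mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double m = s1[c] / dN;
    mean(c) = (float)m;
    var(c) = (float)std::max(s2[c] / dN - m * m, 0.0);
  }
  cc.invstd = 1.0f / arma::sqrt(var + eps);
  cc.xhat.set_size(C, N);
  fmat Z(C, N);
  float* xh = cc.xhat.memptr();
  float* z = Z.memptr();
  for (size_t j = 0; j < N; ++j) {
    const float* col = y + (size_t)j * C;
    float* xcol = xh + (size_t)j * C;
    float* zcol = z + (size_t)j * C;
    for (int c = 0; c < C; ++c) {
      const float x = (col[c] - mean(c)) * cc.invstd(c);
      xcol[c] = x;
      float v = x * g(c, 0) + b(c, 0);
      if (relu && v < 0) v = 0;
      zcol[c] = v;
    }
  }
  rmean.col(0) = (1 - momentum) * rmean.col(0) + momentum * mean;
  rvar.col(0) = (1 - momentum) * rvar.col(0) + momentum * var;
  return Z;
}

static fmat bn_eval(const fmat& Y, const fmat& g, const fmat& b, const fmat& rmean, const fmat& rvar) {
  const float eps = 1e-5f;
  const int C = Y.n_rows;
  const size_t N = Y.n_cols;
  fvec scale = g.col(0) / arma::sqrt(rvar.col(0) + eps);
  fvec shift = b.col(0) - rmean.col(0) % scale;
  fmat Z(C, N);
  const float* y = Y.memptr();
  float* z = Z.memptr();
  for (size_t j = 0; j < N; ++j) {
    const float* yc = y + j * C;
    float* zc = z + j * C;
    for (int c = 0; c < C; ++c) zc[c] = yc[c] * scale(c) + shift(c);
  }
  return Z;
}

static fmat bn_backward(const fmat& dZ, const fmat& g, const BNCache& cc, fmat& dg, fmat& db) {
  const int C = dZ.n_rows;
  const size_t N = dZ.n_cols;
  const float fN = (float)N;
  const float* dz = dZ.memptr();
  const float* xh = cc.xhat.memptr();
  fvec sdz(C, arma::fill::zeros), sdzx(C, arma::fill::zeros);
  for (size_t j = 0; j < N; ++j) {
    const float* zc = dz + (size_t)j * C;
    const float* xc = xh + (size_t)j * C;
    for (int c = 0; c < C; ++c) {
      sdz(c) += zc[c];
      sdzx(c) += zc[c] * xc[c];
    }
  }
  dg.col(0) += sdzx;
  db.col(0) += sdz;
  // dxhat = dZ * gamma; s1 = sum(dxhat), s2 = sum(dxhat * xhat)
  fvec gamma = g.col(0);
  fvec s1 = sdz % gamma, s2 = sdzx % gamma;
  fvec scale = cc.invstd / fN;
  fmat dY(C, N);
  float* dy = dY.memptr();
  for (size_t j = 0; j < N; ++j) {
    const float* zc = dz + (size_t)j * C;
    const float* xc = xh + (size_t)j * C;
    float* yc = dy + (size_t)j * C;
    for (int c = 0; c < C; ++c)
      yc[c] = (zc[c] * gamma(c) * fN - s1(c) - xc[c] * s2(c)) * scale(c);
  }
  return dY;
}

// ---------------------------------------------------------------- attention
struct AttCache {
  fmat F;           // pre-attention feature, C x (T*B)
  fmat a, mx;       // per-sample pooled descriptors, C x B
  arma::umat mx_t;  // time index of channel max, C x B
  fmat ha, hm;      // MLP hidden activations, Ch x B
  fmat mc;          // channel attention, C x B
  fmat mt;          // temporal attention, T x B
  arma::umat mt_c;  // channel index of temporal max, T x B
};

static fvec softmax_f(const fvec& u) {
  fvec e = arma::exp(u - u.max());
  return e / arma::accu(e);
}

// F -> F * Mc * Mt, caches for backward. Pooling (temporal avg/max for the
// channel path, channel max for the temporal path) is fused into a single
// pass over each sample's C x T slab.
static fmat attention_forward(const fmat& F, int C, int T, int B, fmat& W1, fmat& b1, fmat& W2,
                              fmat& b2, AttCache& cc) {
  cc.F = F;
  cc.a.set_size(C, B); cc.mx.set_size(C, B); cc.mx_t.set_size(C, B);
  cc.mc.set_size(C, B); cc.mt.set_size(T, B); cc.mt_c.set_size(T, B);
  const int Ch = W1.n_rows;
  cc.ha.set_size(Ch, B); cc.hm.set_size(Ch, B);
  fmat G(C, (size_t)T * B);
  fvec v(T), a(C), mx(C);
  for (int b = 0; b < B; ++b) {
    const float* fb = F.colptr((size_t)b * T);
    a.zeros();
    for (int c = 0; c < C; ++c) { mx(c) = fb[c]; cc.mx_t(c, b) = 0; }
    for (int t = 0; t < T; ++t) {
      const float* col = fb + (size_t)t * C;
      float cm = col[0];
      int ci = 0;
      for (int c = 0; c < C; ++c) {
        const float val = col[c];
        a(c) += val;
        if (val > mx(c)) { mx(c) = val; cc.mx_t(c, b) = t; }
        if (val > cm) { cm = val; ci = c; }
      }
      v(t) = cm;
      cc.mt_c(t, b) = ci;
    }
    a /= (float)T;
    fvec ha = arma::clamp(W1 * a + b1.col(0), 0.0f, arma::datum::inf);
    fvec hm = arma::clamp(W1 * mx + b1.col(0), 0.0f, arma::datum::inf);
    fvec u = W2 * ha + b2.col(0) + W2 * hm + b2.col(0);
    fvec mc = softmax_f(u);
    fvec mt = 1.0f + softmax_f(v);
    cc.a.col(b) = a; cc.mx.col(b) = mx; cc.ha.col(b) = ha; cc.hm.col(b) = hm;
    cc.mc.col(b) = mc; cc.mt.col(b) = mt;
    float* gb = G.colptr((size_t)b * T);
    for (int t = 0; t < T; ++t) {
      const float* fcol = fb + (size_t)t * C;
      float* gcol = gb + (size_t)t * C;
      const float mtt = mt(t);
      for (int c = 0; c < C; ++c) gcol[c] = fcol[c] * mc(c) * mtt;
    }
  }
  return G;
}

static fmat attention_backward(const fmat& dG, int C, int T, int B, fmat& W1, fmat& W2,
                               const AttCache& cc, fmat& dW1, fmat& db1, fmat& dW2, fmat& db2) {
  fmat dF(C, (size_t)T * B);
  fvec dmc(C), dmt(T);
  for (int b = 0; b < B; ++b) {
    const float* fb = cc.F.colptr((size_t)b * T);
    const float* dgb = dG.colptr((size_t)b * T);
    float* dfb = dF.colptr((size_t)b * T);
    const fvec mc = cc.mc.col(b), mt = cc.mt.col(b);
    dmc.zeros();
    // fused: direct path dF = dG*mc*mt, plus dmc/dmt accumulation
    for (int t = 0; t < T; ++t) {
      const float* fcol = fb + (size_t)t * C;
      const float* gcol = dgb + (size_t)t * C;
      float* dcol = dfb + (size_t)t * C;
      const float mtt = mt(t);
      float acc = 0;
      for (int c = 0; c < C; ++c) {
        const float g = gcol[c], f = fcol[c];
        dcol[c] = g * mc(c) * mtt;
        dmc(c) += g * f * mtt;
        acc += g * f * mc(c);
      }
      dmt(t) = acc;
    }
    // channel softmax backward
    fvec du = mc % (dmc - arma::dot(dmc, mc));
    // temporal softmax backward (softmax part is mt - 1)
    fvec s = mt - 1.0f;
    fvec dv = s % (dmt - arma::dot(dmt, s));
    for (int t = 0; t < T; ++t) dfb[(size_t)t * C + cc.mt_c(t, b)] += dv(t);
    // shared-MLP backward for the avg and max paths
    fvec ha = cc.ha.col(b), hm = cc.hm.col(b);
    dW2 += du * (ha + hm).t();
    db2.col(0) += 2.0f * du;
    fvec dha = (W2.t() * du) % arma::conv_to<fvec>::from(ha > 0);
    fvec dhm = (W2.t() * du) % arma::conv_to<fvec>::from(hm > 0);
    dW1 += dha * cc.a.col(b).t() + dhm * cc.mx.col(b).t();
    db1.col(0) += dha + dhm;
    fvec da = W1.t() * dha;
    da /= (float)T;
    fvec dmx = W1.t() * dhm;
    for (int t = 0; t < T; ++t) {
      float* dcol = dfb + (size_t)t * C;
      for (int c = 0; c < C; ++c) dcol[c] += da(c);
    }
    for (int c = 0; c < C; ++c) dfb[(size_t)cc.mx_t(c, b) * C + c] += dmx(c);
  }
  return dF;
}

// ---------------------------------------------------------------- blocks
struct BlockCache {
  fmat P1, P2, Xs, out;
  BNCache bn1, bn2, bnp;
  fmat R1mask;  // relu mask after bn1 (stored as the post-relu activation)
  AttCache att;
  int Tin, T1, T2, B;
};

static std::string bk(int i, const char* s) {
  return "b" + std::to_string(i + 1) + "." + s;
}

// forward one block; X is Cin x (Tin*B)
static fmat block_forward(Params& P, const Cfg& cfg, int i, const fmat& X, int Tin, int B,
                          bool train, BlockCache* cc, fmat* mc_out = nullptr, fmat* mt_out = nullptr) {
  const int Cin = (i == 0) ? cfg.Cin : cfg.ch[i - 1];
  const int Cout = cfg.ch[i];
  const int s1 = cfg.strides[i].first, s2 = cfg.strides[i].second;
  int T1, T2;
  fmat P1 = im2col(X, Cin, Tin, B, cfg.k, s1, cfg.pad, T1);
  fmat Y1 = P.get(bk(i, "conv1")) * P1;
  BNCache bc1, bc2, bcp;
  fmat R1 = train
                ? bn_train(Y1, P.get(bk(i, "bn1.gamma")), P.get(bk(i, "bn1.beta")),
                           P.get(bk(i, "bn1.mean")), P.get(bk(i, "bn1.var")), bc1, true)
                : arma::clamp(bn_eval(Y1, P.get(bk(i, "bn1.gamma")), P.get(bk(i, "bn1.beta")),
                                      P.get(bk(i, "bn1.mean")), P.get(bk(i, "bn1.var"))),
                              0.0f, arma::datum::inf);
  fmat P2 = im2col(R1, Cout, T1, B, cfg.k, s2, cfg.pad, T2);
  fmat Y2 = P.get(bk(i, "conv2")) * P2;
  fmat F = train
               ? bn_train(Y2, P.get(bk(i, "bn2.gamma")), P.get(bk(i, "bn2.beta")),
                          P.get(bk(i, "bn2.mean")), P.get(bk(i, "bn2.var")), bc2)
               : bn_eval(Y2, P.get(bk(i, "bn2.gamma")), P.get(bk(i, "bn2.beta")),
                         P.get(bk(i, "bn2.mean")), P.get(bk(i, "bn2.var")));
  AttCache ac;
  fmat G = attention_forward(F, Cout, T2, B, P.get(bk(i, "att.W1")), P.get(bk(i, "att.b1")),
                             P.get(bk(i, "att.W2")), P.get(bk(i, "att.b2")), ac);
  if (mc_out) *mc_out = ac.mc;
  if (mt_out) *mt_out = ac.mt;
  // 1x1 projection skip with stride s1*s2 (output length matches T2 exactly)
  const int ss = s1 * s2;
  fmat Xs(Cin, (size_t)T2 * B);
  {
    float* xs = Xs.memptr();
    const float* xp = X.memptr();
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < T2; ++t) {
        const int ti = std::min(t * ss, Tin - 1);
        std::memcpy(xs + ((size_t)b * T2 + t) * Cin, xp + ((size_t)b * Tin + ti) * Cin,
                    sizeof(float) * Cin);
      }
  }
  fmat Yp = P.get(bk(i, "proj")) * Xs;
  fmat S = train
               ? bn_train(Yp, P.get(bk(i, "bnp.gamma")), P.get(bk(i, "bnp.beta")),
                          P.get(bk(i, "bnp.mean")), P.get(bk(i, "bnp.var")), bcp)
               : bn_eval(Yp, P.get(bk(i, "bnp.gamma")), P.get(bk(i, "bnp.beta")),
                         P.get(bk(i, "bnp.mean")), P.get(bk(i, "bnp.var")));
  // out = relu(G + S), written in place over G
  {
    float* gp = G.memptr();
    const float* sp = S.memptr();
    const size_t nn = G.n_elem;
    for (size_t q = 0; q < nn; ++q) {
      const float v = gp[q] + sp[q];
      gp[q] = v > 0 ? v : 0;
    }
  }
  fmat out = std::move(G);
  if (cc) {
    cc->P1 = std::move(P1); cc->P2 = std::move(P2); cc->Xs = std::move(Xs);
    cc->bn1 = std::move(bc1); cc->bn2 = std::move(bc2); cc->bnp = std::move(bcp);
    cc->R1mask = std::move(R1); cc->att = std::move(ac);
    cc->out = out; cc->Tin = Tin; cc->T1 = T1; cc->T2 = T2; cc->B = B;
  }
  return out;
}

static fmat block_backward(Params& P, Params& G, const Cfg& cfg, int i, const fmat& dOut,
                           const BlockCache& cc, bool need_dx = true) {
  const int Cin = (i == 0) ? cfg.Cin : cfg.ch[i - 1];
  const int Cout = cfg.ch[i];
  const int s1 = cfg.strides[i].first, s2 = cfg.strides[i].second;
  const int B = cc.B;
  fmat dPre(dOut.n_rows, dOut.n_cols);
  {
    const float* d = dOut.memptr();
    const float* o = cc.out.memptr();
    float* p = dPre.memptr();
    const size_t nn = dPre.n_elem;
    for (size_t q = 0; q < nn; ++q) p[q] = o[q] > 0 ? d[q] : 0;
  }
  // skip path
  fmat dYp = bn_backward(dPre, P.get(bk(i, "bnp.gamma")), cc.bnp, G.get(bk(i, "bnp.gamma")),
                         G.get(bk(i, "bnp.beta")));
  G.get(bk(i, "proj")) += dYp * cc.Xs.t();
  fmat dXs = P.get(bk(i, "proj")).t() * dYp;
  // attention path
  fmat dF = attention_backward(dPre, Cout, cc.T2, B, P.get(bk(i, "att.W1")), P.get(bk(i, "att.W2")),
                               cc.att, G.get(bk(i, "att.W1")), G.get(bk(i, "att.b1")),
                               G.get(bk(i, "att.W2")), G.get(bk(i, "att.b2")));
  fmat dY2 = bn_backward(dF, P.get(bk(i, "bn2.gamma")), cc.bn2, G.get(bk(i, "bn2.gamma")),
                         G.get(bk(i, "bn2.beta")));
  G.get(bk(i, "conv2")) += dY2 * cc.P2.t();
  fmat dP2 = P.get(bk(i, "conv2")).t() * dY2;
  fmat dR1(Cout, (size_t)cc.T1 * B, arma::fill::zeros);
  col2im(dP2, dR1, Cout, cc.T1, B, cfg.k, s2, cfg.pad, cc.T2);
  {
    // ReLU mask applied in place (R1mask holds the post-ReLU activation)
    float* d = dR1.memptr();
    const float* r = cc.R1mask.memptr();
    const size_t nn = dR1.n_elem;
    for (size_t q = 0; q < nn; ++q)
      if (r[q] <= 0) d[q] = 0;
  }
  fmat dY1 = bn_backward(dR1, P.get(bk(i, "bn1.gamma")), cc.bn1, G.get(bk(i, "bn1.gamma")),
                         G.get(bk(i, "bn1.beta")));
  G.get(bk(i, "conv1")) += dY1 * cc.P1.t();
  if (!need_dx) return fmat();
  fmat dP1 = P.get(bk(i, "conv1")).t() * dY1;
  fmat dX(Cin, (size_t)cc.Tin * B, arma::fill::zeros);
  col2im(dP1, dX, Cin, cc.Tin, B, cfg.k, s1, cfg.pad, cc.T1);
  // add skip contribution
  const int ss = s1 * s2;
  {
    float* dx = dX.memptr();
    const float* ds = dXs.memptr();
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < cc.T2; ++t) {
        const int ti = std::min(t * ss, cc.Tin - 1);
        float* dst = dx + ((size_t)b * cc.Tin + ti) * Cin;
        const float* sp = ds + ((size_t)b * cc.T2 + t) * Cin;
        for (int c = 0; c < Cin; ++c) dst[c] += sp[c];
      }
  }
  return dX;
}

// ---------------------------------------------------------------- heads
struct MLPCache {
  std::vector<fmat> acts;  // input then post-relu hidden activations
};

static fmat mlp_forward(Params& P, const std::string& pre, int n_layers, const fmat& X,
                        MLPCache* cc) {
  fmat a = X;
  if (cc) cc->acts.push_back(a);
  for (int l = 0; l < n_layers; ++l) {
    std::string tag = pre + std::to_string(l + 1);
    fmat z = P.get(tag + ".W") * a;
    z.each_col() += P.get(tag + ".b").col(0);
    if (l < n_layers - 1) {
      a = arma::clamp(z, 0.0f, arma::datum::inf);
      if (cc) cc->acts.push_back(a);
    } else {
      a = z;
    }
  }
  return a;  // logits
}

// accumulates weight/bias gradients and returns the gradient w.r.t. input
static fmat mlp_backward(Params& P, Params& G, const std::string& pre, int n_layers,
                         const fmat& dlogits, const MLPCache& cc) {
  fmat d = dlogits;
  for (int l = n_layers - 1; l >= 0; --l) {
    std::string tag = pre + std::to_string(l + 1);
    G.get(tag + ".W") += d * cc.acts[l].t();
    G.get(tag + ".b").col(0) += arma::sum(d, 1);
    d = P.get(tag + ".W").t() * d;
    if (l > 0) d %= arma::conv_to<fmat>::from(cc.acts[l] > 0);
  }
  return d;
}

static fmat softmax_cols(const fmat& Z) {
  fmat E = Z;
  E.each_row() -= arma::max(Z, 0);
  E = arma::exp(E);
  arma::frowvec s = arma::sum(E, 0);
  E.each_row() /= s;
  return E;
}

// ---------------------------------------------------------------- dataset
struct DataStore {
  fmat X;  // 5 x (spe * n)
  std::vector<int> lab;   // 0..4, -1 unscored
  std::vector<int> rec;   // record index per epoch
  std::vector<int> rec_first, rec_last;  // by record index
  int spe = 0, n = 0, cap = 0;
};

static int clamp_neighbor(const DataStore& D, int g, int d) {
  int r = D.rec[g];
  int t = g + d;
  if (t < D.rec_first[r]) t = D.rec_first[r];
  if (t > D.rec_last[r]) t = D.rec_last[r];
  return t;
}

// [[Rcpp::export]]
SEXP cpp_store_new(int capacity, int spe) {
  DataStore* d = new DataStore();
  d->spe = spe;
  d->cap = capacity;
  d->X.set_size(5, (size_t)spe * capacity);
  XPtr<DataStore> p(d, true);
  return p;
}

// [[Rcpp::export]]
int cpp_store_add(SEXP xp, NumericVector arr, IntegerVector labels) {
  XPtr<DataStore> D(xp);
  IntegerVector dim = arr.attr("dim");
  if (dim.size() != 3 || dim[0] != 5 || dim[1] != D->spe) stop("bad epoch array shape");
  int m = dim[2];
  if (D->n + m > D->cap) stop("training store capacity exceeded");
  const double* src = REAL(arr);
  float* dst = D->X.memptr() + (size_t)5 * D->spe * D->n;
  const size_t nn = (size_t)5 * D->spe * m;
  for (size_t i = 0; i < nn; ++i) dst[i] = (float)src[i];
  int r = (int)D->rec_first.size();
  D->rec_first.push_back(D->n);
  D->rec_last.push_back(D->n + m - 1);
  for (int i = 0; i < m; ++i) {
    D->lab.push_back(labels[i]);
    D->rec.push_back(r);
  }
  D->n += m;
  return r;
}

// [[Rcpp::export]]
List cpp_store_info(SEXP xp) {
  XPtr<DataStore> D(xp);
  return List::create(_["n"] = D->n, _["spe"] = D->spe,
                      _["labels"] = IntegerVector(D->lab.begin(), D->lab.end()),
                      _["record"] = IntegerVector(D->rec.begin(), D->rec.end()));
}

// gather instances (epochs) into the activation layout 5 x (Tin*m)
static fmat gather(const DataStore& D, const std::vector<int>& idx) {
  fmat X(5, (size_t)D.spe * idx.size());
  const size_t slab = (size_t)5 * D.spe;
  float* dst = X.memptr();
  const float* src = D.X.memptr();
  for (size_t i = 0; i < idx.size(); ++i)
    std::memcpy(dst + i * slab, src + (size_t)idx[i] * slab, sizeof(float) * slab);
  return X;
}

// ---------------------------------------------------------------- full net
static fmat net_features(Params& P, const Cfg& cfg, const fmat& X0, int B, bool train,
                         std::vector<BlockCache>* caches, List* att_out = nullptr) {
  fmat A = X0;
  int T = cfg.Tin;
  List atts;
  for (int i = 0; i < cfg.nb(); ++i) {
    BlockCache* cc = caches ? &(*caches)[i] : nullptr;
    fmat mc, mt;
    A = block_forward(P, cfg, i, A, T, B, train, cc, att_out ? &mc : nullptr,
                      att_out ? &mt : nullptr);
    T = out_len(out_len(T, cfg.k, cfg.strides[i].first, cfg.pad), cfg.k, cfg.strides[i].second,
                cfg.pad);
    if (att_out) {
      NumericMatrix mcr(mc.n_rows, mc.n_cols), mtr(mt.n_rows, mt.n_cols);
      for (size_t c = 0; c < mc.n_cols; ++c) {
        for (size_t r = 0; r < mc.n_rows; ++r) mcr(r, c) = mc(r, c);
      }
      for (size_t c = 0; c < mt.n_cols; ++c) {
        for (size_t r = 0; r < mt.n_rows; ++r) mtr(r, c) = mt(r, c);
      }
      atts.push_back(List::create(_["channel"] = mcr, _["temporal"] = mtr));
    }
  }
  // global average pooling over time
  const int F = cfg.fdim();
  fmat feats(F, B);
  for (int b = 0; b < B; ++b)
    feats.col(b) = arma::mean(A.cols((size_t)b * T, (size_t)(b + 1) * T - 1), 1);
  if (att_out) *att_out = atts;
  if (caches) {
    // remember final temporal length for GAP backward
    (*caches).back().T2 = T;  // already equal; explicit
  }
  return feats;
}

static void gap_backward_into(fmat& dA, const fmat& dfeats, int T, int B) {
  for (int b = 0; b < B; ++b) {
    fvec g = dfeats.col(b) / (float)T;
    for (int t = 0; t < T; ++t) dA.col((size_t)b * T + t) = g;
  }
}

// make a zero-gradient Params mirroring trainables of P
static Params zero_grads(const Params& P) {
  Params G;
  for (size_t i = 0; i < P.names.size(); ++i)
    G.add(P.names[i], fmat(P.vals[i].n_rows, P.vals[i].n_cols, arma::fill::zeros));
  return G;
}

// one training batch: forward, losses, backward. Regime: 0 transitive,
// 1 none (SLB-only unweighted), 2 weighted (SLB-only). Returns losses.
struct StepOut {
  double L_ep, L_seq, L;
};

static StepOut batch_grads(Params& P, Params& G, const Cfg& cfg, const DataStore& D,
                           const std::vector<int>& centers, double alpha, const fvec& wts,
                           int regime) {
  const int B = (int)centers.size();
  const int W = cfg.win();
  const int nI = B * W;
  std::vector<int> inst(nI);
  for (int j = 0; j < B; ++j)
    for (int c = 0; c < W; ++c) inst[(size_t)j * W + c] = clamp_neighbor(D, centers[j], c - cfg.nctx);
  fmat X0 = gather(D, inst);
  std::vector<BlockCache> caches(cfg.nb());
  fmat feats = net_features(P, cfg, X0, nI, true, &caches);
  const int F = cfg.fdim();
  const int T3 = caches.back().T2;

  // ELB on center instances
  fmat fctr(F, B);
  for (int j = 0; j < B; ++j) fctr.col(j) = feats.col((size_t)j * W + cfg.nctx);
  MLPCache elb_cc;
  fmat elb_logits = mlp_forward(P, "elb.fc", (int)cfg.elb_hidden.size() + 1, fctr, &elb_cc);
  fmat p_ep = softmax_cols(elb_logits);
  // SLB on concatenated window features
  fmat fwin(F * W, B);
  for (int j = 0; j < B; ++j)
    for (int c = 0; c < W; ++c)
      fwin.submat((size_t)c * F, j, (size_t)(c + 1) * F - 1, j) = feats.col((size_t)j * W + c);
  MLPCache slb_cc;
  fmat slb_logits = mlp_forward(P, "slb.fc", (int)cfg.slb_hidden.size() + 1, fwin, &slb_cc);
  fmat p_seq = softmax_cols(slb_logits);

  // losses (double accumulation; probabilities clamped at 1e-12)
  double L_ep = 0, L_seq = 0, wsum = 0;
  for (int j = 0; j < B; ++j) {
    int y = D.lab[centers[j]];
    L_ep += -std::log(std::max((double)p_ep(y, j), 1e-12));
    double w = (double)wts(y);
    L_seq += w * -std::log(std::max((double)p_seq(y, j), 1e-12));
    wsum += w;
  }
  L_ep /= B;
  L_seq /= wsum;
  double L;
  if (regime == 0) L = alpha * L_ep + (1.0 - alpha) * L_seq;
  else L = L_seq;

  // backward
  fmat dfeats(F, nI, arma::fill::zeros);
  if (regime == 0) {
    // ELB: d(alpha * L_ep)/dlogits
    fmat dle = p_ep;
    for (int j = 0; j < B; ++j) {
      dle(D.lab[centers[j]], j) -= 1.0f;
      dle.col(j) *= (float)(alpha / B);
    }
    fmat dfc = mlp_backward(P, G, "elb.fc", (int)cfg.elb_hidden.size() + 1, dle, elb_cc);
    for (int j = 0; j < B; ++j) dfeats.col((size_t)j * W + cfg.nctx) += dfc.col(j);
  }
  {
    // SLB: d(coef * L_seq)/dlogits, coef = (1-alpha) in transitive else 1
    double coef = (regime == 0) ? (1.0 - alpha) : 1.0;
    fmat dls = p_seq;
    for (int j = 0; j < B; ++j) {
      int y = D.lab[centers[j]];
      dls(y, j) -= 1.0f;
      dls.col(j) *= (float)(coef * wts(y) / wsum);
    }
    fmat dwin = mlp_backward(P, G, "slb.fc", (int)cfg.slb_hidden.size() + 1, dls, slb_cc);
    if (regime != 0) {
      // no gradient gate: sequence loss reaches the CNN through all
      // window features
      for (int j = 0; j < B; ++j)
        for (int c = 0; c < W; ++c)
          dfeats.col((size_t)j * W + c) +=
              dwin.submat((size_t)c * F, j, (size_t)(c + 1) * F - 1, j);
    }
    // transitive: SLB input features are detached (gradient gate)
  }
  // through the CNN
  fmat dA(cfg.fdim(), (size_t)T3 * nI);
  gap_backward_into(dA, dfeats, T3, nI);
  for (int i = cfg.nb() - 1; i >= 0; --i)
    dA = block_backward(P, G, cfg, i, dA, caches[i], i > 0);
  return {L_ep, L_seq, L};
}

// ---------------------------------------------------------------- metrics
static void confusion_from(const std::vector<int>& yt, const std::vector<int>& yp,
                           arma::imat& cm) {
  cm.zeros(N_CLS, N_CLS);
  for (size_t i = 0; i < yt.size(); ++i) cm(yt[i], yp[i])++;
}

static double acc_of(const arma::imat& cm) {
  return (double)arma::trace(cm) / std::max((long long)arma::accu(cm), 1LL);
}

static double kappa_of(const arma::imat& cm) {
  double N = (double)arma::accu(cm);
  if (N <= 0) return 0;
  double po = (double)arma::trace(cm) / N, pe = 0;
  for (int c = 0; c < N_CLS; ++c)
    pe += (double)arma::accu(cm.row(c)) * (double)arma::accu(cm.col(c)) / (N * N);
  if (std::abs(1 - pe) < 1e-15) return po >= 1 ? 1.0 : 0.0;
  return (po - pe) / (1 - pe);
}

static double mf1_of(const arma::imat& cm) {
  double s = 0;
  int k = 0;
  for (int c = 0; c < N_CLS; ++c) {
    double row = (double)arma::accu(cm.row(c)), col = (double)arma::accu(cm.col(c));
    if (row == 0 && col == 0) continue;
    double tp = (double)cm(c, c);
    double prec = col > 0 ? tp / col : 0, rec = row > 0 ? tp / row : 0;
    double f1 = (prec + rec) > 0 ? 2 * prec * rec / (prec + rec) : 0;
    s += f1;
    k++;
  }
  return k > 0 ? s / k : 0;
}

// eval-mode branch probabilities for a set of epochs (whole records
// expected so context lookups resolve; missing neighbours fall back to
// the centre epoch)
static void eval_probs(Params& P, const Cfg& cfg, const DataStore& D, const std::vector<int>& idx,
                       fmat& p_ep, fmat& p_seq) {
  const int F = cfg.fdim(), Wn = cfg.win();
  const int m = (int)idx.size();
  fmat feats(F, m);
  const int chunk = 256;
  for (int at = 0; at < m; at += chunk) {
    int b = std::min(chunk, m - at);
    std::vector<int> sub(idx.begin() + at, idx.begin() + at + b);
    fmat X0 = gather(D, sub);
    feats.cols(at, at + b - 1) = net_features(P, cfg, X0, b, false, nullptr);
  }
  std::unordered_map<int, int> pos;
  for (int i = 0; i < m; ++i) pos[idx[i]] = i;
  p_ep = softmax_cols(mlp_forward(P, "elb.fc", (int)cfg.elb_hidden.size() + 1, feats, nullptr));
  fmat fwin(F * Wn, m);
  for (int i = 0; i < m; ++i)
    for (int c = 0; c < Wn; ++c) {
      int g = clamp_neighbor(D, idx[i], c - cfg.nctx);
      auto it = pos.find(g);
      int j = (it == pos.end()) ? i : it->second;
      fwin.submat((size_t)c * F, i, (size_t)(c + 1) * F - 1, i) = feats.col(j);
    }
  p_seq = softmax_cols(mlp_forward(P, "slb.fc", (int)cfg.slb_hidden.size() + 1, fwin, nullptr));
}

static int argmax_first(const fvec& p) {
  int best = 0;
  float bv = p(0);
  for (int c = 1; c < N_CLS; ++c)
    if (p(c) > bv) { bv = p(c); best = c; }
  return best;
}

// ---------------------------------------------------------------- adam
struct Adam {
  std::vector<fmat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Params& P) {
    for (auto& x : P.vals) {
      m.emplace_back(x.n_rows, x.n_cols, arma::fill::zeros);
      v.emplace_back(x.n_rows, x.n_cols, arma::fill::zeros);
    }
  }
  void step(Params& P, Params& G, double lr) {
    t++;
    double bc1 = 1 - std::pow(b1, (double)t), bc2 = 1 - std::pow(b2, (double)t);
    for (size_t i = 0; i < P.vals.size(); ++i) {
      if (is_state(P.names[i])) continue;
      m[i] = (float)b1 * m[i] + (float)(1 - b1) * G.vals[i];
      v[i] = (float)b2 * v[i] + (float)(1 - b2) * (G.vals[i] % G.vals[i]);
      fmat mhat = m[i] / (float)bc1, vhat = v[i] / (float)bc2;
      P.vals[i] -= (float)lr * mhat / (arma::sqrt(vhat) + (float)eps);
    }
  }
};

// ---------------------------------------------------------------- exports

// [[Rcpp::export]]
List cpp_forward(List params, List cfg_l, SEXP xp, IntegerVector idx, bool with_attention = false) {
  Params P = params_from_list(params);
  Cfg cfg = parse_cfg(cfg_l);
  XPtr<DataStore> D(xp);
  std::vector<int> v(idx.begin(), idx.end());
  fmat p_ep, p_seq;
  eval_probs(P, cfg, *D, v, p_ep, p_seq);
  NumericMatrix pe(N_CLS, p_ep.n_cols), ps(N_CLS, p_seq.n_cols);
  for (size_t c = 0; c < p_ep.n_cols; ++c)
    for (int r = 0; r < N_CLS; ++r) {
      pe(r, c) = p_ep(r, c);
      ps(r, c) = p_seq(r, c);
    }
  List out = List::create(_["p_ep"] = pe, _["p_seq"] = ps);
  if (with_attention) {
    // attention maps of the first requested epoch, per block
    std::vector<int> one(1, v[0]);
    fmat X0 = gather(*D, one);
    List atts;
    net_features(P, cfg, X0, 1, false, nullptr, &atts);
    out["attention"] = atts;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_features(List params, List cfg_l, NumericVector arr) {
  Params P = params_from_list(params);
  Cfg cfg = parse_cfg(cfg_l);
  IntegerVector dim = arr.attr("dim");
  int m = (dim.size() == 3) ? dim[2] : 1;
  if (dim[0] != cfg.Cin || dim[1] != cfg.Tin) stop("epoch tensor must be channels x samples");
  fmat X0(cfg.Cin, (size_t)cfg.Tin * m);
  const double* src = REAL(arr);
  float* dst = X0.memptr();
  for (size_t i = 0; i < (size_t)cfg.Cin * cfg.Tin * m; ++i) dst[i] = (float)src[i];
  fmat f = net_features(P, cfg, X0, m, false, nullptr);
  NumericMatrix out(f.n_rows, f.n_cols);
  for (size_t c = 0; c < f.n_cols; ++c)
    for (size_t r = 0; r < f.n_rows; ++r) out(r, c) = f(r, c);
  return out;
}

// [[Rcpp::export]]
List cpp_block_forward(List params, List cfg_l, int block, NumericMatrix x) {
  Params P = params_from_list(params);
  Cfg cfg = parse_cfg(cfg_l);
  fmat X(x.nrow(), x.ncol());
  for (int c = 0; c < x.ncol(); ++c)
    for (int r = 0; r < x.nrow(); ++r) X(r, c) = (float)x(r, c);
  fmat mc, mt;
  fmat out = block_forward(P, cfg, block - 1, X, x.ncol(), 1, false, nullptr, &mc, &mt);
  NumericMatrix o(out.n_rows, out.n_cols);
  for (size_t c = 0; c < out.n_cols; ++c)
    for (size_t r = 0; r < out.n_rows; ++r) o(r, c) = out(r, c);
  NumericVector mcv(mc.n_rows), mtv(mt.n_rows);
  for (size_t r = 0; r < mc.n_rows; ++r) mcv[r] = mc(r, 0);
  for (size_t r = 0; r < mt.n_rows; ++r) mtv[r] = mt(r, 0);
  return List::create(_["out"] = o, _["channel_attention"] = mcv, _["temporal_attention"] = mtv);
}

// [[Rcpp::export]]
List cpp_grads(List params, List cfg_l, SEXP xp, IntegerVector centers, double alpha,
               NumericVector weights, int regime) {
  Params P = params_from_list(params);
  Cfg cfg = parse_cfg(cfg_l);
  XPtr<DataStore> D(xp);
  Params G = zero_grads(P);
  fvec w(N_CLS);
  for (int c = 0; c < N_CLS; ++c) w(c) = (float)weights[c];
  std::vector<int> ctr(centers.begin(), centers.end());
  StepOut s = batch_grads(P, G, cfg, *D, ctr, alpha, w, regime);
  List gl = params_to_list(G);
  return List::create(_["grads"] = gl, _["L_ep"] = s.L_ep, _["L_seq"] = s.L_seq, _["L"] = s.L);
}

// [[Rcpp::export]]
List cpp_train(List params, List cfg_l, SEXP xp, IntegerVector train_idx, IntegerVector val_idx,
               List tcfg) {
  Params P = params_from_list(params);
  Cfg cfg = parse_cfg(cfg_l);
  XPtr<DataStore> D(xp);
  const int iters = as<int>(tcfg["iterations"]);
  const int batch = as<int>(tcfg["batch_size"]);
  double lr = as<double>(tcfg["lr"]);
  const double decay_frac = as<double>(tcfg["lr_decay_at_fraction"]);
  const double decay_fac = as<double>(tcfg["lr_decay_factor"]);
  const int epe = as<int>(tcfg["epochs_per_train_epoch"]);
  const int t_max = as<int>(tcfg["t_max"]);
  const int seed = as<int>(tcfg["seed"]);
  const int regime = as<int>(tcfg["regime"]);
  const double alpha_test = as<double>(tcfg["alpha_test"]);
  NumericVector wR = tcfg["class_weights"];
  fvec wts(N_CLS);
  for (int c = 0; c < N_CLS; ++c) wts(c) = (float)wR[c];

  std::vector<int> pool(train_idx.begin(), train_idx.end());
  std::vector<int> val(val_idx.begin(), val_idx.end());
  std::mt19937_64 rng(seed);
  auto reshuffle = [&](std::vector<int>& v) {
    for (size_t i = v.size() - 1; i > 0; --i) {
      std::uniform_int_distribution<size_t> d(0, i);
      std::swap(v[i], v[d(rng)]);
    }
  };
  reshuffle(pool);
  size_t pool_at = 0;

  Adam opt;
  opt.init(P);
  const int decay_it = (int)std::floor(decay_frac * iters);
  NumericMatrix hist(iters, 7);  // iter, epoch, alpha, L_ep, L_seq, L, lr
  std::vector<std::array<double, 5>> vlog;  // iter, epoch, acc, kappa, mf1
  double best_mf1 = -1;
  long best_iter = -1;
  Params best = P;

  auto validate = [&](int it, int T) {
    if (val.empty()) return;
    fmat p_ep, p_seq;
    eval_probs(P, cfg, *D, val, p_ep, p_seq);
    std::vector<int> yt, yp;
    for (size_t i = 0; i < val.size(); ++i) {
      int y = D->lab[val[i]];
      if (y < 0) continue;
      fvec p = (regime == 0)
                   ? fvec((float)alpha_test * p_ep.col(i) + (float)(1 - alpha_test) * p_seq.col(i))
                   : fvec(p_seq.col(i));
      yt.push_back(y);
      yp.push_back(argmax_first(p));
    }
    arma::imat cm;
    confusion_from(yt, yp, cm);
    double mf1 = mf1_of(cm);
    vlog.push_back({(double)it, (double)T, acc_of(cm), kappa_of(cm), mf1});
    if (mf1 >= best_mf1) {
      best_mf1 = mf1;
      best_iter = it;
      best = P;
    }
  };

  for (int it = 0; it < iters; ++it) {
    if (it == decay_it && it > 0) lr *= decay_fac;
    const int T = std::min(it / epe, t_max);
    const double alpha = 1.0 - std::pow((double)T / (double)t_max, 2.0);
    std::vector<int> centers(batch);
    for (int j = 0; j < batch; ++j) {
      if (pool_at >= pool.size()) {
        reshuffle(pool);
        pool_at = 0;
      }
      centers[j] = pool[pool_at++];
    }
    Params G = zero_grads(P);
    StepOut s = batch_grads(P, G, cfg, *D, centers, alpha, wts, regime);
    opt.step(P, G, lr);
    hist(it, 0) = it + 1;
    hist(it, 1) = T;
    hist(it, 2) = (regime == 0) ? alpha : 0.0;
    hist(it, 3) = s.L_ep;
    hist(it, 4) = s.L_seq;
    hist(it, 5) = s.L;
    hist(it, 6) = lr;
    if ((it + 1) % epe == 0 || it == iters - 1) validate(it + 1, T);
    if ((it & 63) == 0) Rcpp::checkUserInterrupt();
  }
  if (best_iter < 0) best = P;

  NumericMatrix vm(vlog.size(), 5);
  for (size_t i = 0; i < vlog.size(); ++i)
    for (int j = 0; j < 5; ++j) vm(i, j) = vlog[i][j];
  return List::create(_["params"] = params_to_list(P), _["best_params"] = params_to_list(best),
                      _["history"] = hist, _["val_log"] = vm, _["best_mf1"] = best_mf1,
                      _["best_iter"] = (double)best_iter);
}
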