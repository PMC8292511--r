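// Encoder-decoder Transformer for notation translation, with training
// (backpropagation + Adam, inverse-square-root warmup, label smoothing)
// and decoding (greedy step and beam search with incremental K/V caches).
//
// Everything is implemented here because no deep-learning runtime is
// available to R in this stack; single precision, single thread, own RNG
// so runs are bit-reproducible for a fixed seed.
//
// Token id convention (shared with the R side, 0-based):
//   0 = <pad>, 1 = <bos>, 2 = <eos>, 3 = <unk>, 4.. = vocabulary tokens.

#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>
#include <algorithm>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;

static const float LN_EPS = 1e-5f;
static const float NEG_INF = -1e9f;

// ---------------------------------------------------------------- RNG -----
struct Xoshiro {
  uint64_t s;
  explicit Xoshiro(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    // splitmix64
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  float normal() {
    double u1 = std::max(unif(), 1e-12), u2 = unif();
    return (float)(std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2));
  }
  int integer(int n) { return (int)(unif() * n) % n; }
};

// ------------------------------------------------------------- config -----
struct Cfg {
  int n_enc, n_dec, heads, d, ff, max_len, Vs, Vt;
  float dropout;
};

static Cfg cfg_from_list(const List& cl) {
  Cfg c;
  c.n_enc = as<int>(cl["n_encoder_layers"]);
  c.n_dec = as<int>(cl["n_decoder_layers"]);
  c.heads = as<int>(cl["n_heads"]);
  c.d = as<int>(cl["d_model"]);
  c.ff = as<int>(cl["d_ff"]);
  c.max_len = as<int>(cl["max_len"]);
  c.Vs = as<int>(cl["vocab_src"]);
  c.Vt = as<int>(cl["vocab_tgt"]);
  c.dropout = as<double>(cl["dropout"]);
  if (c.d % c.heads != 0) stop("d_model must be divisible by n_heads");
  return c;
}

// ------------------------------------------------------------- params -----
// parameter tensors are stored in one flat ordered map name -> fmat
typedef std::map<std::string, fmat> Params;

static std::vector<std::string> attn_names(const std::string& p) {
  const char* k[] = {"Wq", "Wk", "Wv", "Wo", "bq", "bk", "bv", "bo"};
  std::vector<std::string> v;
  for (int i = 0; i < 8; i++) v.push_back(p + k[i]);
  return v;
}

static std::vector<std::string> param_names(const Cfg& c) {
  std::vector<std::string> n = {"src_emb", "tgt_emb", "out_W", "out_b"};
  for (int l = 0; l < c.n_enc; l++) {
    std::string p = "enc" + std::to_string(l) + "_";
    for (auto& s : attn_names(p)) n.push_back(s);
    for (const char* s : {"ln1_g", "ln1_b", "W1", "b1", "W2", "b2", "ln2_g", "ln2_b"})
      n.push_back(p + s);
  }
  for (int l = 0; l < c.n_dec; l++) {
    std::string p = "dec" + std::to_string(l) + "_";
    for (auto& s : attn_names(p + "s")) n.push_back(s);
    n.push_back(p + "ln1_g"); n.push_back(p + "ln1_b");
    for (auto& s : attn_names(p + "c")) n.push_back(s);
    n.push_back(p + "ln2_g"); n.push_back(p + "ln2_b");
    for (const char* s : {"W1", "b1", "W2", "b2", "ln3_g", "ln3_b"})
      n.push_back(p + s);
  }
  return n;
}

static Params params_from_list(const List& pl, const Cfg& c) {
  Params P;
  std::vector<std::string> names = param_names(c);
  for (auto& nm : names) {
    if (!pl.containsElementNamed(nm.c_str())) stop("missing parameter: " + nm);
    NumericMatrix m = pl[nm];
    fmat f(m.nrow(), m.ncol());
    for (int j = 0; j < m.ncol(); j++)
      for (int i = 0; i < m.nrow(); i++) f(i, j) = (float)m(i, j);
    P[nm] = std::move(f);
  }
  return P;
}

static List params_to_list(const Params& P) {
  List out;
  CharacterVector nms;
  for (auto& kv : P) {
    NumericMatrix m(kv.second.n_rows, kv.second.n_cols);
    for (arma::uword j = 0; j < kv.second.n_cols; j++)
      for (arma::uword i = 0; i < kv.second.n_rows; i++) m(i, j) = kv.second(i, j);
    out.push_back(m);
    nms.push_back(kv.first);
  }
  out.attr("names") = nms;
  return out;
}

// ------------------------------------------------------- initialisation ---
static fmat init_mat(int r, int cc, float scale, Xoshiro& rng) {
  fmat m(r, cc);
  for (int j = 0; j < cc; j++)
    for (int i = 0; i < r; i++) m(i, j) = scale * rng.normal();
  return m;
}

// [[Rcpp::export(name = ".tf_init")]]
List tf_init(List config, int seed) {
  Cfg c = cfg_from_list(config);
  Xoshiro rng((uint64_t)seed * 2654435761ULL + 1ULL);
  Params P;
  float es = 1.0f / std::sqrt((float)c.d);
  P["src_emb"] = init_mat(c.Vs, c.d, es, rng);
  P["tgt_emb"] = init_mat(c.Vt, c.d, es, rng);
  P["out_W"] = init_mat(c.d, c.Vt, es, rng);
  P["out_b"] = fmat(1, c.Vt, arma::fill::zeros);
  auto add_attn = [&](const std::string& p) {
    float s = 1.0f / std::sqrt((float)c.d);
    for (auto& nm : {p + "Wq", p + "Wk", p + "Wv", p + "Wo"})
      P[nm] = init_mat(c.d, c.d, s, rng);
    for (auto& nm : {p + "bq", p + "bk", p + "bv", p + "bo"})
      P[nm] = fmat(1, c.d, arma::fill::zeros);
  };
  auto add_ln = [&](const std::string& nm) {
    P[nm + "_g"] = fmat(1, c.d, arma::fill::ones);
    P[nm + "_b"] = fmat(1, c.d, arma::fill::zeros);
  };
  auto add_ffn = [&](const std::string& p) {
    P[p + "W1"] = init_mat(c.d, c.ff, std::sqrt(2.0f / c.d), rng);
    P[p + "b1"] = fmat(1, c.ff, arma::fill::zeros);
    P[p + "W2"] = init_mat(c.ff, c.d, 1.0f / std::sqrt((float)c.ff), rng);
    P[p + "b2"] = fmat(1, c.d, arma::fill::zeros);
  };
  for (int l = 0; l < c.n_enc; l++) {
    std::string p = "enc" + std::to_string(l) + "_";
    add_attn(p); add_ln(p + "ln1"); add_ffn(p); add_ln(p + "ln2");
  }
  for (int l = 0; l < c.n_dec; l++) {
    std::string p = "dec" + std::to_string(l) + "_";
    add_attn(p + "s"); add_ln(p + "ln1");
    add_attn(p + "c"); add_ln(p + "ln2");
    add_ffn(p); add_ln(p + "ln3");
  }
  return params_to_list(P);
}

// -------------------------------------------------- positional encoding ---
static fmat pos_encoding(int L, int d) {
  fmat pe(L, d);
  for (int t = 0; t < L; t++) {
    for (int i = 0; i < d / 2; i++) {
      double ang = t / std::pow(10000.0, (2.0 * i) / d);
      pe(t, 2 * i) = (float)std::sin(ang);
      pe(t, 2 * i + 1) = (float)std::cos(ang);
    }
  }
  return pe;
}

// ------------------------------------------------------- forward pieces ---
struct LnCache { fmat x, xhat; fvec invstd; };

static fmat layernorm_fwd(const fmat& X, const fmat& g, const fmat& b, LnCache& cc) {
  fvec mu = arma::mean(X, 1);
  fmat xc = X.each_col() - mu;
  fvec var = arma::mean(arma::square(xc), 1);
  cc.invstd = 1.0f / arma::sqrt(var + LN_EPS);
  cc.x = X;
  cc.xhat = xc.each_col() % cc.invstd;
  fmat y = cc.xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static fmat layernorm_bwd(const fmat& dY, const fmat& g, const LnCache& cc,
                          fmat& dg, fmat& db) {
  int d = dY.n_cols;
  dg += arma::sum(dY % cc.xhat, 0);
  db += arma::sum(dY, 0);
  fmat dxhat = dY.each_row() % g;
  fvec t1 = arma::sum(dxhat, 1) / d;
  fvec t2 = arma::sum(dxhat % cc.xhat, 1) / d;
  fmat dx = dxhat;
  dx.each_col() -= t1;
  dx -= cc.xhat.each_col() % t2;
  dx.each_col() %= cc.invstd;
  return dx;
}

struct AttnCache {
  fmat Q, K, V, Ccat;         // (B*Lq x d), (B*Lk x d)
  std::vector<fmat> Pm;       // softmax per (example, head)
  fmat Xq, Xkv;               // inputs
};

// multi-head attention over a padded batch; rows of Xq grouped per example
static fmat mha_fwd(const Params& P, const std::string& p, const fmat& Xq,
                    const fmat& Xkv, int B, int Lq, int Lk,
                    const std::vector<int>& klen, bool causal, const Cfg& c,
                    AttnCache& cc) {
  int dh = c.d / c.heads;
  float scale = 1.0f / std::sqrt((float)dh);
  cc.Xq = Xq; cc.Xkv = Xkv;
  cc.Q = Xq * P.at(p + "Wq"); cc.Q.each_row() += P.at(p + "bq");
  cc.K = Xkv * P.at(p + "Wk"); cc.K.each_row() += P.at(p + "bk");
  cc.V = Xkv * P.at(p + "Wv"); cc.V.each_row() += P.at(p + "bv");
  cc.Ccat.set_size(B * Lq, c.d);
  cc.Pm.assign((size_t)B * c.heads, fmat());
  for (int b = 0; b < B; b++) {
    int q0 = b * Lq, k0 = b * Lk;
    for (int h = 0; h < c.heads; h++) {
      fmat Qh = cc.Q.submat(q0, h * dh, q0 + Lq - 1, (h + 1) * dh - 1);
      fmat Kh = cc.K.submat(k0, h * dh, k0 + Lk - 1, (h + 1) * dh - 1);
      fmat Vh = cc.V.submat(k0, h * dh, k0 + Lk - 1, (h + 1) * dh - 1);
      fmat S = Qh * Kh.t() * scale;
      for (int j = klen[b]; j < Lk; j++) S.col(j).fill(NEG_INF);
      if (causal)
        for (int i = 0; i < Lq; i++)
          for (int j = i + 1; j < Lk; j++) S(i, j) = NEG_INF;
      fvec mx = arma::max(S, 1);
      S.each_col() -= mx;
      fmat Pmat = arma::exp(S);
      fvec rs = arma::sum(Pmat, 1);
      Pmat.each_col() /= rs;
      cc.Pm[(size_t)b * c.heads + h] = Pmat;
      cc.Ccat.submat(q0, h * dh, q0 + Lq - 1, (h + 1) * dh - 1) = Pmat * Vh;
    }
  }
  fmat out = cc.Ccat * P.at(p + "Wo");
  out.each_row() += P.at(p + "bo");
  return out;
}

static void mha_bwd(const Params& P, const std::string& p, const fmat& dOut,
                    int B, int Lq, int Lk, const Cfg& c, const AttnCache& cc,
                    Params& G, fmat& dXq, fmat& dXkv) {
  int dh = c.d / c.heads;
  float scale = 1.0f / std::sqrt((float)dh);
  G[p + "Wo"] += cc.Ccat.t() * dOut;
  G[p + "bo"] += arma::sum(dOut, 0);
  fmat dC = dOut * P.at(p + "Wo").t();
  fmat dQ(arma::size(cc.Q), arma::fill::zeros);
  fmat dK(arma::size(cc.K), arma::fill::zeros);
  fmat dV(arma::size(cc.V), arma::fill::zeros);
  for (int b = 0; b < B; b++) {
    int q0 = b * Lq, k0 = b * Lk;
    for (int h = 0; h < c.heads; h++) {
      const fmat& Pmat = cc.Pm[(size_t)b * c.heads + h];
      fmat Qh = cc.Q.submat(q0, h * dh, q0 + Lq - 1, (h + 1) * dh - 1);
      fmat Kh = cc.K.submat(k0, h * dh, k0 + Lk - 1, (h + 1) * dh - 1);
      fmat Vh = cc.V.submat(k0, h * dh, k0 + Lk - 1, (h + 1) * dh - 1);
      fmat dCh = dC.submat(q0, h * dh, q0 + Lq - 1, (h + 1) * dh - 1);
      fmat dP = dCh * Vh.t();
      fmat dVh = Pmat.t() * dCh;
      fvec rs = arma::sum(dP % Pmat, 1);
      fmat dS = Pmat % (dP.each_col() - rs);
      dQ.submat(q0, h * dh, q0 + Lq - 1, (h + 1) * dh - 1) = dS * Kh * scale;
      dK.submat(k0, h * dh, k0 + Lk - 1, (h + 1) * dh - 1) = dS.t() * Qh * scale;
      dV.submat(k0, h * dh, k0 + Lk - 1, (h + 1) * dh - 1) = dVh;
    }
  }
  G[p + "Wq"] += cc.Xq.t() * dQ;  G[p + "bq"] += arma::sum(dQ, 0);
  G[p + "Wk"] += cc.Xkv.t() * dK; G[p + "bk"] += arma::sum(dK, 0);
  G[p + "Wv"] += cc.Xkv.t() * dV; G[p + "bv"] += arma::sum(dV, 0);
  dXq += dQ * P.at(p + "Wq").t();
  dXkv += dK * P.at(p + "Wk").t();
  dXkv += dV * P.at(p + "Wv").t();
}

struct FfnCache { fmat x, h; };

static fmat ffn_fwd(const Params& P, const std::string& p, const fmat& X,
                    FfnCache& cc) {
  cc.x = X;
  cc.h = X * P.at(p + "W1");
  cc.h.each_row() += P.at(p + "b1");
  cc.h.transform([](float v) { return v > 0 ? v : 0; });
  fmat y = cc.h * P.at(p + "W2");
  y.each_row() += P.at(p + "b2");
  return y;
}

static fmat ffn_bwd(const Params& P, const std::string& p, const fmat& dY,
                    const FfnCache& cc, Params& G) {
  G[p + "W2"] += cc.h.t() * dY;
  G[p + "b2"] += arma::sum(dY, 0);
  fmat dh = dY * P.at(p + "W2").t();
  dh %= arma::conv_to<fmat>::from(cc.h > 0);
  G[p + "W1"] += cc.x.t() * dh;
  G[p + "b1"] += arma::sum(dh, 0);
  return dh * P.at(p + "W1").t();
}

// dropout (inverted); mask cached for backward
static fmat dropout_fwd(const fmat& X, float rate, Xoshiro& rng, fmat& mask,
                        bool train) {
  if (!train || rate <= 0.0f) { mask.reset(); return X; }
  mask.set_size(arma::size(X));
  float keep = 1.0f - rate;
  for (arma::uword j = 0; j < X.n_cols; j++)
    for (arma::uword i = 0; i < X.n_rows; i++)
      mask(i, j) = rng.unif() < keep ? 1.0f / keep : 0.0f;
  return X % mask;
}
static fmat dropout_bwd(const fmat& dY, const fmat& mask) {
  if (mask.is_empty()) return dY;
  return dY % mask;
}

// ------------------------------------------------------- full forward -----
struct EncLayerCache { AttnCache att; LnCache ln1, ln2; FfnCache ffn; fmat dm1, dm2; };
struct DecLayerCache {
  AttnCache self_att, cross_att; LnCache ln1, ln2, ln3; FfnCache ffn;
  fmat dm1, dm2, dm3;
};
struct FwdCache {
  fmat Xsrc_emb, Xtgt_emb, dm_src, dm_tgt;
  std::vector<EncLayerCache> enc;
  std::vector<DecLayerCache> dec;
  fmat memory, dec_out;
  std::vector<int> src_ids, tgt_ids;
  int B, Ls, Lt;
  std::vector<int> slen, tlen;
};

static fmat embed(const fmat& emb, const std::vector<int>& ids, int B, int L,
                  int d) {
  fmat X(B * L, d, arma::fill::zeros);
  float sc = std::sqrt((float)d);
  static std::map<std::pair<int,int>, fmat> pe_cache;
  auto key = std::make_pair(L, d);
  if (!pe_cache.count(key)) pe_cache[key] = pos_encoding(L, d);
  const fmat& pe = pe_cache[key];
  for (int b = 0; b < B; b++)
    for (int t = 0; t < L; t++) {
      int id = ids[(size_t)b * L + t];
      if (id >= 0) X.row(b * L + t) = emb.row(id) * sc + pe.row(t);
    }
  return X;
}

// forward through encoder and decoder; returns logits over non-pad target
// rows (all rows kept, caller masks)
static fmat forward(const Params& P, const Cfg& c, FwdCache& F, bool train,
                    float drop, Xoshiro& rng) {
  fmat X = embed(P.at("src_emb"), F.src_ids, F.B, F.Ls, c.d);
  X = dropout_fwd(X, drop, rng, F.dm_src, train);
  F.enc.assign(c.n_enc, EncLayerCache());
  for (int l = 0; l < c.n_enc; l++) {
    std::string p = "enc" + std::to_string(l) + "_";
    EncLayerCache& L = F.enc[l];
    fmat A = mha_fwd(P, p, X, X, F.B, F.Ls, F.Ls, F.slen, false, c, L.att);
    A = dropout_fwd(A, drop, rng, L.dm1, train);
    X = layernorm_fwd(X + A, P.at(p + "ln1_g"), P.at(p + "ln1_b"), L.ln1);
    fmat Ff = ffn_fwd(P, p, X, L.ffn);
    Ff = dropout_fwd(Ff, drop, rng, L.dm2, train);
    X = layernorm_fwd(X + Ff, P.at(p + "ln2_g"), P.at(p + "ln2_b"), L.ln2);
  }
  F.memory = X;

  fmat Y = embed(P.at("tgt_emb"), F.tgt_ids, F.B, F.Lt, c.d);
  Y = dropout_fwd(Y, drop, rng, F.dm_tgt, train);
  F.dec.assign(c.n_dec, DecLayerCache());
  for (int l = 0; l < c.n_dec; l++) {
    std::string p = "dec" + std::to_string(l) + "_";
    DecLayerCache& L = F.dec[l];
    fmat A = mha_fwd(P, p + "s", Y, Y, F.B, F.Lt, F.Lt, F.tlen, true, c, L.self_att);
    A = dropout_fwd(A, drop, rng, L.dm1, train);
    Y = layernorm_fwd(Y + A, P.at(p + "ln1_g"), P.at(p + "ln1_b"), L.ln1);
    fmat Cc = mha_fwd(P, p + "c", Y, F.memory, F.B, F.Lt, F.Ls, F.slen, false,
                      c, L.cross_att);
    Cc = dropout_fwd(Cc, drop, rng, L.dm2, train);
    Y = layernorm_fwd(Y + Cc, P.at(p + "ln2_g"), P.at(p + "ln2_b"), L.ln2);
    fmat Ff = ffn_fwd(P, p, Y, L.ffn);
    Ff = dropout_fwd(Ff, drop, rng, L.dm3, train);
    Y = layernorm_fwd(Y + Ff, P.at(p + "ln3_g"), P.at(p + "ln3_b"), L.ln3);
  }
  F.dec_out = Y;
  fmat logits = Y * P.at("out_W");
  logits.each_row() += P.at("out_b");
  return logits;
}

// backward from dLogits; accumulates into G
static void backward(const Params& P, const Cfg& c, FwdCache& F,
                     const fmat& dLogits, Params& G) {
  G["out_W"] += F.dec_out.t() * dLogits;
  G["out_b"] += arma::sum(dLogits, 0);
  fmat dY = dLogits * P.at("out_W").t();
  fmat dMem(arma::size(F.memory), arma::fill::zeros);
  for (int l = c.n_dec - 1; l >= 0; l--) {
    std::string p = "dec" + std::to_string(l) + "_";
    DecLayerCache& L = F.dec[l];
    fmat dZ = layernorm_bwd(dY, P.at(p + "ln3_g"), L.ln3, G[p + "ln3_g"],
                            G[p + "ln3_b"]);
    fmat dFf = dropout_bwd(dZ, L.dm3);
    fmat dIn = ffn_bwd(P, p, dFf, L.ffn, G);
    dY = dZ + dIn;
    dZ = layernorm_bwd(dY, P.at(p + "ln2_g"), L.ln2, G[p + "ln2_g"],
                       G[p + "ln2_b"]);
    fmat dCc = dropout_bwd(dZ, L.dm2);
    fmat dQ(arma::size(dZ), arma::fill::zeros);
    mha_bwd(P, p + "c", dCc, F.B, F.Lt, F.Ls, c, L.cross_att, G, dQ, dMem);
    dY = dZ + dQ;
    dZ = layernorm_bwd(dY, P.at(p + "ln1_g"), L.ln1, G[p + "ln1_g"],
                       G[p + "ln1_b"]);
    fmat dA = dropout_bwd(dZ, L.dm1);
    fmat dSelf(arma::size(dZ), arma::fill::zeros);
    mha_bwd(P, p + "s", dA, F.B, F.Lt, F.Lt, c, L.self_att, G, dSelf, dSelf);
    dY = dZ + dSelf;
  }
  dY = dropout_bwd(dY, F.dm_tgt);
  float sc = std::sqrt((float)c.d);
  for (int b = 0; b < F.B; b++)
    for (int t = 0; t < F.Lt; t++) {
      int id = F.tgt_ids[(size_t)b * F.Lt + t];
      if (id >= 0) G["tgt_emb"].row(id) += dY.row(b * F.Lt + t) * sc;
    }
  fmat dX = dMem;
  for (int l = c.n_enc - 1; l >= 0; l--) {
    std::string p = "enc" + std::to_string(l) + "_";
    EncLayerCache& L = F.enc[l];
    fmat dZ = layernorm_bwd(dX, P.at(p + "ln2_g"), L.ln2, G[p + "ln2_g"],
                            G[p + "ln2_b"]);
    fmat dFf = dropout_bwd(dZ, L.dm2);
    fmat dIn = ffn_bwd(P, p, dFf, L.ffn, G);
    dX = dZ + dIn;
    dZ = layernorm_bwd(dX, P.at(p + "ln1_g"), L.ln1, G[p + "ln1_g"],
                       G[p + "ln1_b"]);
    fmat dA = dropout_bwd(dZ, L.dm1);
    fmat dSelf(arma::size(dZ), arma::fill::zeros);
    mha_bwd(P, p, dA, F.B, F.Ls, F.Ls, c, L.att, G, dSelf, dSelf);
    dX = dZ + dSelf;
  }
  dX = dropout_bwd(dX, F.dm_src);
  for (int b = 0; b < F.B; b++)
    for (int t = 0; t < F.Ls; t++) {
      int id = F.src_ids[(size_t)b * F.Ls + t];
      if (id >= 0) G["src_emb"].row(id) += dX.row(b * F.Ls + t) * sc;
    }
}

// label-smoothed cross entropy; fills dLogits; returns (loss, n_tokens)
static std::pair<double, int> ce_loss(const fmat& logits,
                                      const std::vector<int>& gold, int Vt,
                                      float smooth, fmat& dLogits) {
  int R = logits.n_rows;
  dLogits.zeros(R, Vt);
  double loss = 0.0;
  int ntok = 0;
  for (int i = 0; i < R; i++) if (gold[i] >= 0) ntok++;
  if (ntok == 0) return {0.0, 0};
  float unif = smooth / Vt;
  for (int i = 0; i < R; i++) {
    int y = gold[i];
    if (y < 0) continue;
    frowvec row = logits.row(i);
    float mx = row.max();
    frowvec ex = arma::exp(row - mx);
    float Z = arma::accu(ex);
    frowvec pr = ex / Z;
    // q = (1 - smooth) * onehot + smooth / V
    double li = 0.0;
    for (int v = 0; v < Vt; v++) {
      float q = unif + (v == y ? (1.0f - smooth) : 0.0f);
      float logp = (row(v) - mx) - std::log(Z);
      li -= q * logp;
      dLogits(i, v) = (pr(v) - q) / ntok;
    }
    loss += li;
  }
  return {loss / ntok, ntok};
}

// prepare a padded batch from ragged id vectors (already with specials)
static void make_batch(const std::vector<std::vector<int>>& src,
                       const std::vector<std::vector<int>>& tgt,
                       const std::vector<int>& idx, FwdCache& F,
                       std::vector<int>& gold) {
  int B = idx.size();
  int Ls = 1, Lt = 1;
  for (int b : idx) {
    Ls = std::max(Ls, (int)src[b].size());
    Lt = std::max(Lt, (int)tgt[b].size());  // tgt includes bos..eos
  }
  Lt -= 1;  // teacher forcing: input drops eos, gold drops bos
  F.B = B; F.Ls = Ls; F.Lt = Lt;
  F.src_ids.assign((size_t)B * Ls, -1);
  F.tgt_ids.assign((size_t)B * Lt, -1);
  F.slen.assign(B, 0); F.tlen.assign(B, 0);
  gold.assign((size_t)B * Lt, -1);
  for (int bi = 0; bi < B; bi++) {
    const std::vector<int>& s = src[idx[bi]];
    const std::vector<int>& t = tgt[idx[bi]];
    F.slen[bi] = s.size();
    F.tlen[bi] = t.size() - 1;
    for (size_t j = 0; j < s.size(); j++) F.src_ids[(size_t)bi * Ls + j] = s[j];
    for (size_t j = 0; j + 1 < t.size(); j++) {
      F.tgt_ids[(size_t)bi * Lt + j] = t[j];
      gold[(size_t)bi * Lt + j] = t[j + 1];
    }
  }
}

static std::vector<std::vector<int>> ragged_from_list(const List& l) {
  std::vector<std::vector<int>> out(l.size());
  for (int i = 0; i < l.size(); i++) {
    IntegerVector v = l[i];
    out[i] = std::vector<int>(v.begin(), v.end());
  }
  return out;
}

// ------------------------------------------------------------- training ---
// [[Rcpp::export(name = ".tf_train")]]
List tf_train(List params, List config, List src_list, List tgt_list,
              List tcfg) {
  Cfg c = cfg_from_list(config);
  Params P = params_from_list(params, c);
  std::vector<std::vector<int>> src = ragged_from_list(src_list);
  std::vector<std::vector<int>> tgt = ragged_from_list(tgt_list);

  int epochs = as<int>(tcfg["epochs"]);
  int batch = as<int>(tcfg["batch_size"]);
  double lr_mult = as<double>(tcfg["lr_mult"]);
  int warmup = as<int>(tcfg["warmup_steps"]);
  float smooth = (float)as<double>(tcfg["label_smoothing"]);
  int seed = as<int>(tcfg["seed"]);
  double clip = tcfg.containsElementNamed("clip_norm") ?
                as<double>(tcfg["clip_norm"]) : 1.0;
  int step0 = tcfg.containsElementNamed("step_offset") ?
              as<int>(tcfg["step_offset"]) : 0;

  // drop pairs exceeding max_len (counted, not fatal)
  std::vector<int> keep;
  int skipped = 0;
  for (size_t i = 0; i < src.size(); i++) {
    if ((int)src[i].size() <= c.max_len && (int)tgt[i].size() <= c.max_len + 1)
      keep.push_back(i);
    else skipped++;
  }
  if (keep.empty()) stop("training corpus is empty after length screening");

  Xoshiro rng((uint64_t)seed * 0x9E3779B9ULL + 17ULL);
  Params M, Vv;  // Adam moments
  for (auto& kv : P) {
    M[kv.first] = fmat(arma::size(kv.second), arma::fill::zeros);
    Vv[kv.first] = fmat(arma::size(kv.second), arma::fill::zeros);
  }
  std::vector<double> trace;
  int step = step0;
  float base = 1.0f / std::sqrt((float)c.d);
  for (int ep = 0; ep < epochs; ep++) {
    // shuffle, then sort within blocks of 10 batches by length so padded
    // batch shapes stay tight; finally shuffle the batch order
    for (size_t i = keep.size(); i > 1; i--)
      std::swap(keep[i - 1], keep[rng.integer(i)]);
    size_t block = (size_t)batch * 10;
    for (size_t ofs = 0; ofs < keep.size(); ofs += block) {
      size_t hi = std::min(ofs + block, keep.size());
      std::stable_sort(keep.begin() + ofs, keep.begin() + hi,
                       [&](int a, int b) {
                         return src[a].size() + tgt[a].size() <
                                src[b].size() + tgt[b].size();
                       });
    }
    std::vector<std::vector<int>> batches;
    for (size_t ofs = 0; ofs < keep.size(); ofs += batch)
      batches.emplace_back(keep.begin() + ofs,
                           keep.begin() + std::min(ofs + batch, keep.size()));
    for (size_t i = batches.size(); i > 1; i--)
      std::swap(batches[i - 1], batches[rng.integer(i)]);
    for (std::vector<int>& idx : batches) {
      FwdCache F;
      std::vector<int> gold;
      make_batch(src, tgt, idx, F, gold);
      fmat logits = forward(P, c, F, true, c.dropout, rng);
      fmat dLogits;
      auto lt = ce_loss(logits, gold, c.Vt, smooth, dLogits);
      Params G;
      for (auto& kv : P) G[kv.first] = fmat(arma::size(kv.second), arma::fill::zeros);
      backward(P, c, F, dLogits, G);
      if (clip > 0) {
        // global-norm gradient clipping guards against the loss spikes
        // post-layer-norm Transformers show on small batches
        double ss = 0;
        for (auto& kv : G) ss += arma::accu(arma::square(kv.second));
        double gn = std::sqrt(ss);
        if (gn > clip) {
          float sc2 = (float)(clip / gn);
          for (auto& kv : G) kv.second *= sc2;
        }
      }
      step++;
      float lr = lr_mult * base *
                 std::min(1.0f / std::sqrt((float)step),
                          step * std::pow((float)warmup, -1.5f));
      float b1 = 0.9f, b2 = 0.98f, eps = 1e-9f;
      float bc1 = 1.0f - std::pow(b1, (float)step);
      float bc2 = 1.0f - std::pow(b2, (float)step);
      for (auto& kv : P) {
        fmat& g = G[kv.first];
        fmat& m = M[kv.first];
        fmat& v = Vv[kv.first];
        m = b1 * m + (1.0f - b1) * g;
        v = b2 * v + (1.0f - b2) * (g % g);
        kv.second -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
      }
      trace.push_back(lt.first);
      if (!std::isfinite(lt.first)) stop("non-finite training loss at step %d", step);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = params_to_list(P),
                      _["loss_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["skipped"] = skipped,
                      _["steps"] = step);
}

// loss + gradients for one batch (finite-difference checks)
// [[Rcpp::export(name = ".tf_loss_grad")]]
List tf_loss_grad(List params, List config, List src_list, List tgt_list,
                  double smoothing, bool want_grads) {
  Cfg c = cfg_from_list(config);
  Params P = params_from_list(params, c);
  std::vector<std::vector<int>> src = ragged_from_list(src_list);
  std::vector<std::vector<int>> tgt = ragged_from_list(tgt_list);
  std::vector<int> idx(src.size());
  for (size_t i = 0; i < src.size(); i++) idx[i] = i;
  FwdCache F;
  std::vector<int> gold;
  make_batch(src, tgt, idx, F, gold);
  Xoshiro rng(1);
  fmat logits = forward(P, c, F, false, 0.0f, rng);
  fmat dLogits;
  auto lt = ce_loss(logits, gold, c.Vt, (float)smoothing, dLogits);
  List out = List::create(_["loss"] = lt.first, _["n_tokens"] = lt.second);
  if (want_grads) {
    Params G;
    for (auto& kv : P) G[kv.first] = fmat(arma::size(kv.second), arma::fill::zeros);
    backward(P, c, F, dLogits, G);
    out["grads"] = params_to_list(G);
  }
  return out;
}

// ---------------------------------------------------------- decoding ------
// next-token log-probabilities for one (src, prefix); full re-encode
// (reference path used by greedy decoding and toy-model enumeration)
// [[Rcpp::export(name = ".tf_logprobs")]]
NumericVector tf_logprobs(List params, List config, IntegerVector src_ids,
                          IntegerVector prefix_ids) {
  Cfg c = cfg_from_list(config);
  Params P = params_from_list(params, c);
  FwdCache F;
  F.B = 1;
  F.Ls = src_ids.size();
  F.Lt = prefix_ids.size();
  F.src_ids = std::vector<int>(src_ids.begin(), src_ids.end());
  F.tgt_ids = std::vector<int>(prefix_ids.begin(), prefix_ids.end());
  F.slen.assign(1, F.Ls);
  F.tlen.assign(1, F.Lt);
  Xoshiro rng(1);
  fmat logits = forward(P, c, F, false, 0.0f, rng);
  frowvec row = logits.row(F.Lt - 1);
  float mx = row.max();
  frowvec ex = arma::exp(row - mx);
  float Z = arma::accu(ex);
  NumericVector out(c.Vt);
  for (int v = 0; v < c.Vt; v++) out[v] = (row(v) - mx) - std::log(Z);
  return out;
}

// incremental decoder state for beam search
struct DecState {
  std::vector<fmat> K, V;   // per layer, growing (t x d)
};

struct BeamModel {
  const Params* P;
  Cfg c;
  fmat memory;              // (Ls x d)
  int Ls;
  std::vector<fmat> crossK, crossV;   // per layer (Ls x d)
  fmat pe;
};

static void run_encoder_single(const Params& P, const Cfg& c,
                               const std::vector<int>& sid, BeamModel& bm) {
  FwdCache F;
  F.B = 1; F.Ls = sid.size(); F.Lt = 1;
  F.src_ids = sid;
  F.tgt_ids.assign(1, 1);
  F.slen.assign(1, F.Ls);
  F.tlen.assign(1, 1);
  // encoder-only forward
  fmat X = embed(P.at("src_emb"), F.src_ids, 1, F.Ls, c.d);
  F.enc.assign(c.n_enc, EncLayerCache());
  for (int l = 0; l < c.n_enc; l++) {
    std::string p = "enc" + std::to_string(l) + "_";
    EncLayerCache& L = F.enc[l];
    fmat A = mha_fwd(P, p, X, X, 1, F.Ls, F.Ls, F.slen, false, c, L.att);
    X = layernorm_fwd(X + A, P.at(p + "ln1_g"), P.at(p + "ln1_b"), L.ln1);
    fmat Ff = ffn_fwd(P, p, X, L.ffn);
    X = layernorm_fwd(X + Ff, P.at(p + "ln2_g"), P.at(p + "ln2_b"), L.ln2);
  }
  bm.memory = X;
  bm.Ls = F.Ls;
  bm.crossK.resize(c.n_dec);
  bm.crossV.resize(c.n_dec);
  for (int l = 0; l < c.n_dec; l++) {
    std::string p = "dec" + std::to_string(l) + "_c";
    bm.crossK[l] = X * P.at(p + "Wk"); bm.crossK[l].each_row() += P.at(p + "bk");
    bm.crossV[l] = X * P.at(p + "Wv"); bm.crossV[l].each_row() += P.at(p + "bv");
  }
}

static fmat ln_row(const fmat& x, const fmat& g, const fmat& b) {
  float mu = arma::mean(arma::mean(x));
  fmat xc = x - mu;
  float var = arma::mean(arma::mean(xc % xc));
  fmat xhat = xc / std::sqrt(var + LN_EPS);
  fmat y = xhat % g + b;
  return y;
}

// one decoder step for one hypothesis; x is the embedding of token at
// position t; updates the K/V cache and returns log-probs
static frowvec dec_step(const BeamModel& bm, DecState& st, int token, int t) {
  const Params& P = *bm.P;
  const Cfg& c = bm.c;
  int dh = c.d / c.heads;
  float scale = 1.0f / std::sqrt((float)dh);
  fmat x = P.at("tgt_emb").row(token) * std::sqrt((float)c.d) + bm.pe.row(t);
  if ((int)st.K.size() != c.n_dec) {
    st.K.assign(c.n_dec, fmat());
    st.V.assign(c.n_dec, fmat());
  }
  for (int l = 0; l < c.n_dec; l++) {
    std::string p = "dec" + std::to_string(l) + "_";
    fmat q = x * P.at(p + "sWq"); q += P.at(p + "sbq");
    fmat k = x * P.at(p + "sWk"); k += P.at(p + "sbk");
    fmat v = x * P.at(p + "sWv"); v += P.at(p + "sbv");
    st.K[l] = arma::join_cols(st.K[l], k);
    st.V[l] = arma::join_cols(st.V[l], v);
    fmat ctx(1, c.d);
    for (int h = 0; h < c.heads; h++) {
      fmat qh = q.cols(h * dh, (h + 1) * dh - 1);
      fmat Kh = st.K[l].cols(h * dh, (h + 1) * dh - 1);
      fmat Vh = st.V[l].cols(h * dh, (h + 1) * dh - 1);
      fmat S = qh * Kh.t() * scale;
      float mx = S.max();
      fmat Pm = arma::exp(S - mx);
      Pm /= arma::accu(Pm);
      ctx.cols(h * dh, (h + 1) * dh - 1) = Pm * Vh;
    }
    fmat a = ctx * P.at(p + "sWo"); a += P.at(p + "sbo");
    x = ln_row(x + a, P.at(p + "ln1_g"), P.at(p + "ln1_b"));
    fmat qc = x * P.at(p + "cWq"); qc += P.at(p + "cbq");
    fmat ctx2(1, c.d);
    for (int h = 0; h < c.heads; h++) {
      fmat qh = qc.cols(h * dh, (h + 1) * dh - 1);
      fmat Kh = bm.crossK[l].cols(h * dh, (h + 1) * dh - 1);
      fmat Vh = bm.crossV[l].cols(h * dh, (h + 1) * dh - 1);
      fmat S = qh * Kh.t() * scale;
      float mx = S.max();
      fmat Pm = arma::exp(S - mx);
      Pm /= arma::accu(Pm);
      ctx2.cols(h * dh, (h + 1) * dh - 1) = Pm * Vh;
    }
    fmat a2 = ctx2 * P.at(p + "cWo"); a2 += P.at(p + "cbo");
    x = ln_row(x + a2, P.at(p + "ln2_g"), P.at(p + "ln2_b"));
    fmat h1 = x * P.at(p + "W1"); h1 += P.at(p + "b1");
    h1.transform([](float v2) { return v2 > 0 ? v2 : 0; });
    fmat f = h1 * P.at(p + "W2"); f += P.at(p + "b2");
    x = ln_row(x + f, P.at(p + "ln3_g"), P.at(p + "ln3_b"));
  }
  fmat logits = x * P.at("out_W");
  logits += P.at("out_b");
  frowvec row = logits.row(0);
  float mx = row.max();
  frowvec ex = arma::exp(row - mx);
  float Z = arma::accu(ex);
  return (row - mx) - std::log(Z);
}

struct Hyp {
  std::vector<int> ids;   // emitted tokens (no bos, may end with eos)
  double score;
  DecState st;
  bool done;
};

// beam search for a list of source sequences
// [[Rcpp::export(name = ".tf_beam")]]
List tf_beam(List params, List config, List src_list, int beam, int max_out) {
  Cfg c = cfg_from_list(config);
  Params P = params_from_list(params, c);
  std::vector<std::vector<int>> srcs = ragged_from_list(src_list);
  fmat pe = pos_encoding(c.max_len + 2, c.d);
  List results(srcs.size());
  for (size_t m = 0; m < srcs.size(); m++) {
    BeamModel bm;
    bm.P = &P; bm.c = c; bm.pe = pe;
    run_encoder_single(P, c, srcs[m], bm);
    std::vector<Hyp> alive(1);
    alive[0].score = 0.0; alive[0].done = false;
    std::vector<Hyp> done;
    auto hyp_order = [](const Hyp& x, const Hyp& y) { return x.score > y.score; };
    for (int t = 0; t < max_out; t++) {
      // expand every alive hypothesis
      struct Cand { int hyp, tok; double score; };
      std::vector<Cand> cands;
      std::vector<frowvec> lps(alive.size());
      for (size_t a = 0; a < alive.size(); a++) {
        int last = alive[a].ids.empty() ? 1 /*bos*/ : alive[a].ids.back();
        lps[a] = dec_step(bm, alive[a].st, last, t);
        for (int v = 0; v < c.Vt; v++) {
          if (v == 0 || v == 1) continue;  // never emit pad/bos
          cands.push_back({(int)a, v, alive[a].score + lps[a](v)});
        }
      }
      std::stable_sort(cands.begin(), cands.end(),
                       [](const Cand& x, const Cand& y) {
                         if (x.score != y.score) return x.score > y.score;
                         if (x.tok != y.tok) return x.tok < y.tok;
                         return x.hyp < y.hyp;
                       });
      // every end-token candidate finishes; the k best non-finishing
      // candidates stay alive (the live width never shrinks, so early
      // finishers cannot crowd out better deep sequences)
      std::vector<Hyp> next;
      for (auto& cd : cands) {
        bool fin = (cd.tok == 2);
        if (!fin && (int)next.size() >= beam) continue;
        Hyp h;
        h.ids = alive[cd.hyp].ids;
        h.ids.push_back(cd.tok);
        h.score = cd.score;
        h.done = fin;
        if (fin) {
          done.push_back(std::move(h));
        } else {
          h.st = alive[cd.hyp].st;
          next.push_back(std::move(h));
        }
      }
      std::stable_sort(done.begin(), done.end(), hyp_order);
      if ((int)done.size() > beam) done.resize(beam);
      alive = std::move(next);
      if (alive.empty()) break;
      // extensions only lower a score, so once the k-th finished
      // hypothesis beats the best alive one the search is complete
      if ((int)done.size() >= beam && done[beam - 1].score >= alive[0].score)
        break;
    }
    for (auto& h : alive) done.push_back(std::move(h));  // unfinished
    std::stable_sort(done.begin(), done.end(), hyp_order);
    if ((int)done.size() > beam) done.resize(beam);
    List cand_ids(done.size());
    NumericVector scores(done.size());
    LogicalVector finished(done.size());
    for (size_t i = 0; i < done.size(); i++) {
      cand_ids[i] = IntegerVector(done[i].ids.begin(), done[i].ids.end());
      scores[i] = done[i].score;
      finished[i] = done[i].done;
    }
    results[m] = List::create(_["ids"] = cand_ids, _["log_score"] = scores,
                              _["finished"] = finished);
  }
  return results;
}
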