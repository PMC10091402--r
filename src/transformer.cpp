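// Minimal encoder-decoder transformer for reaction-string translation.
//
// Pre-LayerNorm variant (stable under a constant learning rate), sinusoidal
// positional encodings, multi-head scaled dot-product attention, ReLU
// feed-forward blocks, Adam, gradient clipping, teacher-forced validation
// (token accuracy + perplexity) with patience-based early stopping, and
// beam-search n-best decoding.
//
// Sequences in a batch are packed row-wise into one activation matrix, so
// every projection and feed-forward op is a single large GEMM; only the
// attention score blocks are computed per sequence. Live beams are packed
// the same way during decoding.
//
// All randomness comes from a private mt19937 seeded from R, so training
// and inference are bit-reproducible for a fixed seed.

#include <RcppArmadillo.h>
#include <map>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Config {
  int n_layers, d_model, ff_dim, n_heads, vocab;
  int batch_tokens, beam_size, patience, validate_every, max_steps;
  int bos_id, eos_id, max_decode_len;
  double lr, grad_clip;
  bool freeze_src_emb;
  unsigned int seed;
};

static Config read_config(const Rcpp::List& cfg) {
  Config c;
  c.n_layers = cfg["n_layers"]; c.d_model = cfg["d_model"];
  c.ff_dim = cfg["ff_dim"]; c.n_heads = cfg["n_heads"];
  c.vocab = cfg["vocab"];
  c.batch_tokens = cfg["batch_tokens"]; c.beam_size = cfg["beam_size"];
  c.patience = cfg["patience"]; c.validate_every = cfg["validate_every"];
  c.max_steps = cfg["max_steps"];
  c.bos_id = Rcpp::as<int>(cfg["bos_id"]) - 1;  // R ids are 1-based
  c.eos_id = Rcpp::as<int>(cfg["eos_id"]) - 1;
  c.max_decode_len = cfg["max_decode_len"];
  c.lr = cfg["lr"]; c.grad_clip = cfg["grad_clip"];
  c.freeze_src_emb = cfg["freeze_src_emb"];
  c.seed = Rcpp::as<unsigned int>(cfg["seed"]);
  if (c.d_model % c.n_heads != 0) Rcpp::stop("d_model must be divisible by n_heads");
  return c;
}

struct ParamStore {
  std::vector<mat> v;
  std::vector<std::string> names;
  std::map<std::string, int> idx;

  void add(const std::string& n, int r, int cc) {
    idx[n] = (int)v.size();
    names.push_back(n);
    v.emplace_back(r, cc, fill::zeros);
  }
  mat& at(const std::string& n) { return v[idx.at(n)]; }
};

static void build_layout(ParamStore& p, const Config& c) {
  p.add("src_emb", c.vocab, c.d_model);
  p.add("tgt_emb", c.vocab, c.d_model);
  p.add("out_W", c.d_model, c.vocab);
  p.add("out_b", 1, c.vocab);
  auto attn = [&](const std::string& pre) {
    p.add(pre + ".Wq", c.d_model, c.d_model); p.add(pre + ".bq", 1, c.d_model);
    p.add(pre + ".Wk", c.d_model, c.d_model); p.add(pre + ".bk", 1, c.d_model);
    p.add(pre + ".Wv", c.d_model, c.d_model); p.add(pre + ".bv", 1, c.d_model);
    p.add(pre + ".Wo", c.d_model, c.d_model); p.add(pre + ".bo", 1, c.d_model);
  };
  auto ln = [&](const std::string& pre) {
    p.add(pre + ".g", 1, c.d_model); p.add(pre + ".b", 1, c.d_model);
  };
  auto ff = [&](const std::string& pre) {
    p.add(pre + ".W1", c.d_model, c.ff_dim); p.add(pre + ".b1", 1, c.ff_dim);
    p.add(pre + ".W2", c.ff_dim, c.d_model); p.add(pre + ".b2", 1, c.d_model);
  };
  for (int l = 0; l < c.n_layers; ++l) {
    std::string e = "enc" + std::to_string(l);
    ln(e + ".ln1"); attn(e + ".attn"); ln(e + ".ln2"); ff(e + ".ff");
  }
  for (int l = 0; l < c.n_layers; ++l) {
    std::string d = "dec" + std::to_string(l);
    ln(d + ".ln1"); attn(d + ".self");
    ln(d + ".ln2"); attn(d + ".cross");
    ln(d + ".ln3"); ff(d + ".ff");
  }
  ln("enc_ln"); ln("dec_ln");
}

static void init_params(ParamStore& p, const Config& c, std::mt19937& rng) {
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  for (size_t i = 0; i < p.v.size(); ++i) {
    const std::string& n = p.names[i];
    mat& m = p.v[i];
    if (n.size() > 2 && (n.substr(n.size() - 2) == ".g")) { m.ones(); continue; }
    bool bias = n.find(".b") != std::string::npos || n == "out_b";
    if (bias) { m.zeros(); continue; }
    double limit = std::sqrt(6.0 / (m.n_rows + m.n_cols));
    if (n == "src_emb" || n == "tgt_emb") limit = std::sqrt(3.0 / c.d_model);
    for (uword j = 0; j < m.n_elem; ++j) m(j) = limit * unif(rng);
  }
}

static Rcpp::List params_to_list(const ParamStore& p) {
  Rcpp::List out(p.v.size());
  Rcpp::CharacterVector nm(p.v.size());
  for (size_t i = 0; i < p.v.size(); ++i) {
    out[i] = Rcpp::wrap(p.v[i]);
    nm[i] = p.names[i];
  }
  out.attr("names") = nm;
  return out;
}

static void params_from_list(ParamStore& p, const Rcpp::List& lst) {
  Rcpp::CharacterVector nm = lst.attr("names");
  for (int i = 0; i < lst.size(); ++i) {
    std::string n = Rcpp::as<std::string>(nm[i]);
    mat m = Rcpp::as<mat>(lst[i]);
    mat& tgt = p.at(n);
    if (m.n_rows != tgt.n_rows || m.n_cols != tgt.n_cols)
      Rcpp::stop("parameter %s has wrong shape", n.c_str());
    tgt = m;
  }
}

// ---------- packing ---------------------------------------------------------

struct Pack {
  std::vector<std::vector<int>> seqs;
  std::vector<int> off;   // size n+1, row offsets into the packed matrix
  int total = 0;
  int n() const { return (int)seqs.size(); }
  void build() {
    off.assign(seqs.size() + 1, 0);
    for (size_t i = 0; i < seqs.size(); ++i) off[i + 1] = off[i] + (int)seqs[i].size();
    total = off.back();
  }
};

static const mat& positional(int T, int d) {
  static mat cache;
  if ((int)cache.n_rows < T || (int)cache.n_cols != d) {
    int rows = std::max(T, 256);
    cache.set_size(rows, d);
    for (int t = 0; t < rows; ++t)
      for (int i = 0; i < d; ++i) {
        double angle = t / std::pow(10000.0, (2.0 * (i / 2)) / d);
        cache(t, i) = (i % 2 == 0) ? std::sin(angle) : std::cos(angle);
      }
  }
  return cache;
}

static mat embed_pack(const mat& emb, const Pack& pk, int d) {
  mat X(pk.total, d);
  double s = std::sqrt((double)d);
  const mat& pos = positional(pk.total > 0 ? pk.total : 1, d);
  for (int i = 0; i < pk.n(); ++i) {
    const auto& seq = pk.seqs[i];
    for (size_t t = 0; t < seq.size(); ++t)
      X.row(pk.off[i] + t) = emb.row(seq[t]) * s + pos.row(t);
  }
  return X;
}

// ---------- building blocks -------------------------------------------------

struct LNCache { mat xhat; vec invstd; };

static mat ln_fwd(const mat& X, const mat& g, const mat& b, LNCache& c) {
  const double eps = 1e-5;
  vec mu = mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec var = mean(square(Xc), 1);
  c.invstd = 1.0 / sqrt(var + eps);
  c.xhat = Xc.each_col() % c.invstd;
  mat Y = c.xhat.each_row() % g;
  Y.each_row() += b;
  return Y;
}

static mat ln_bwd(const mat& dY, const mat& g, const LNCache& c,
                  mat& dg, mat& db) {
  dg += sum(dY % c.xhat, 0);
  db += sum(dY, 0);
  mat dxhat = dY.each_row() % g;
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % c.xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.invstd;
  return dX;
}

// Attention over packed activations. Query rows for sequence i live in
// [qoff[i], qoff[i+1]); key/value rows in [kbeg[i], kend[i]) of Xkv.
struct AttnCache {
  mat Q, K, V, ctx;
  std::vector<std::vector<mat>> A;   // [seq][head]
  const mat *Xq, *Xkv;
};

static mat attn_fwd(ParamStore& p, const std::string& pre, const Config& cf,
                    const mat& Xq, const mat& Xkv,
                    const std::vector<int>& qoff,
                    const std::vector<int>& kbeg, const std::vector<int>& kend,
                    bool causal, AttnCache& c) {
  int H = cf.n_heads, dh = cf.d_model / H;
  int n = (int)qoff.size() - 1;
  c.Xq = &Xq; c.Xkv = &Xkv;
  c.Q = Xq * p.at(pre + ".Wq"); c.Q.each_row() += p.at(pre + ".bq");
  c.K = Xkv * p.at(pre + ".Wk"); c.K.each_row() += p.at(pre + ".bk");
  c.V = Xkv * p.at(pre + ".Wv"); c.V.each_row() += p.at(pre + ".bv");
  c.ctx.set_size(Xq.n_rows, cf.d_model);
  c.A.assign(n, std::vector<mat>(H));
  double scale = 1.0 / std::sqrt((double)dh);
  for (int i = 0; i < n; ++i) {
    if (qoff[i + 1] == qoff[i]) continue;
    span qr(qoff[i], qoff[i + 1] - 1), kr(kbeg[i], kend[i] - 1);
    for (int h = 0; h < H; ++h) {
      span hc(h * dh, (h + 1) * dh - 1);
      mat S = c.Q(qr, hc) * c.K(kr, hc).t() * scale;
      if (causal)
        for (uword a = 0; a < S.n_rows; ++a)
          for (uword b = a + 1; b < S.n_cols; ++b) S(a, b) = -1e30;
      S.each_col() -= max(S, 1);
      mat E = exp(S);
      mat A = E.each_col() / sum(E, 1);
      c.A[i][h] = A;
      c.ctx(qr, hc) = A * c.V(kr, hc);
    }
  }
  mat out = c.ctx * p.at(pre + ".Wo");
  out.each_row() += p.at(pre + ".bo");
  return out;
}

// returns dXq; accumulates dXkv into dXkv_acc
static mat attn_bwd(ParamStore& p, ParamStore& g, const std::string& pre,
                    const Config& cf, const AttnCache& c, const mat& dOut,
                    const std::vector<int>& qoff,
                    const std::vector<int>& kbeg, const std::vector<int>& kend,
                    mat& dXkv_acc) {
  int H = cf.n_heads, dh = cf.d_model / H;
  int n = (int)qoff.size() - 1;
  double scale = 1.0 / std::sqrt((double)dh);
  g.at(pre + ".Wo") += c.ctx.t() * dOut;
  g.at(pre + ".bo") += sum(dOut, 0);
  mat dctx = dOut * p.at(pre + ".Wo").t();
  mat dQ(c.Q.n_rows, cf.d_model, fill::zeros);
  mat dK(c.K.n_rows, cf.d_model, fill::zeros);
  mat dV(c.V.n_rows, cf.d_model, fill::zeros);
  for (int i = 0; i < n; ++i) {
    if (qoff[i + 1] == qoff[i]) continue;
    span qr(qoff[i], qoff[i + 1] - 1), kr(kbeg[i], kend[i] - 1);
    for (int h = 0; h < H; ++h) {
      span hc(h * dh, (h + 1) * dh - 1);
      const mat& A = c.A[i][h];
      mat dctxh = dctx(qr, hc);
      mat dA = dctxh * c.V(kr, hc).t();
      dV(kr, hc) += A.t() * dctxh;
      vec rowdot = sum(dA % A, 1);
      mat dS = A % (dA.each_col() - rowdot);
      dQ(qr, hc) = dS * c.K(kr, hc) * scale;
      dK(kr, hc) += dS.t() * c.Q(qr, hc) * scale;
    }
  }
  g.at(pre + ".Wq") += c.Xq->t() * dQ;  g.at(pre + ".bq") += sum(dQ, 0);
  g.at(pre + ".Wk") += c.Xkv->t() * dK; g.at(pre + ".bk") += sum(dK, 0);
  g.at(pre + ".Wv") += c.Xkv->t() * dV; g.at(pre + ".bv") += sum(dV, 0);
  dXkv_acc += dK * p.at(pre + ".Wk").t() + dV * p.at(pre + ".Wv").t();
  return dQ * p.at(pre + ".Wq").t();
}

struct FFCache { mat H1; const mat* X; };

static mat ff_fwd(ParamStore& p, const std::string& pre, const mat& X, FFCache& c) {
  c.X = &X;
  c.H1 = X * p.at(pre + ".W1");
  c.H1.each_row() += p.at(pre + ".b1");
  c.H1.transform([](double x) { return x > 0 ? x : 0.0; });
  mat Y = c.H1 * p.at(pre + ".W2");
  Y.each_row() += p.at(pre + ".b2");
  return Y;
}

static mat ff_bwd(ParamStore& p, ParamStore& g, const std::string& pre,
                  const FFCache& c, const mat& dY) {
  g.at(pre + ".W2") += c.H1.t() * dY;
  g.at(pre + ".b2") += sum(dY, 0);
  mat dH1 = dY * p.at(pre + ".W2").t();
  dH1 %= conv_to<mat>::from(c.H1 > 0);
  g.at(pre + ".W1") += c.X->t() * dH1;
  g.at(pre + ".b1") += sum(dH1, 0);
  return dH1 * p.at(pre + ".W1").t();
}

// ---------- encoder / decoder over packs ------------------------------------

struct EncCache {
  std::vector<LNCache> ln1, ln2;
  std::vector<AttnCache> at;
  std::vector<FFCache> ff;
  std::vector<mat> ln1_out, ln2_out;
  LNCache lnf;
  mat M;
};

static void encode_pack(ParamStore& p, const Config& cf, const Pack& pk,
                        EncCache& ec) {
  mat X = embed_pack(p.at("src_emb"), pk, cf.d_model);
  int L = cf.n_layers;
  ec.ln1.resize(L); ec.ln2.resize(L); ec.at.resize(L); ec.ff.resize(L);
  ec.ln1_out.resize(L); ec.ln2_out.resize(L);
  std::vector<int> kb(pk.n()), ke(pk.n());
  for (int i = 0; i < pk.n(); ++i) { kb[i] = pk.off[i]; ke[i] = pk.off[i + 1]; }
  for (int l = 0; l < L; ++l) {
    std::string e = "enc" + std::to_string(l);
    ec.ln1_out[l] = ln_fwd(X, p.at(e + ".ln1.g"), p.at(e + ".ln1.b"), ec.ln1[l]);
    X += attn_fwd(p, e + ".attn", cf, ec.ln1_out[l], ec.ln1_out[l],
                  pk.off, kb, ke, false, ec.at[l]);
    ec.ln2_out[l] = ln_fwd(X, p.at(e + ".ln2.g"), p.at(e + ".ln2.b"), ec.ln2[l]);
    X += ff_fwd(p, e + ".ff", ec.ln2_out[l], ec.ff[l]);
  }
  ec.M = ln_fwd(X, p.at("enc_ln.g"), p.at("enc_ln.b"), ec.lnf);
}

struct DecCache {
  std::vector<LNCache> ln1, ln2, ln3;
  std::vector<AttnCache> self_at, cross_at;
  std::vector<FFCache> ff;
  std::vector<mat> ln1_out, ln2_out, ln3_out;
  LNCache lnf;
  mat H;
};

// mem_beg/mem_end give, per decoder sequence, its memory row range in M.
static void decode_pack(ParamStore& p, const Config& cf, const Pack& pk,
                        const mat& M, const std::vector<int>& mem_beg,
                        const std::vector<int>& mem_end, DecCache& dc) {
  mat Y = embed_pack(p.at("tgt_emb"), pk, cf.d_model);
  int L = cf.n_layers;
  dc.ln1.resize(L); dc.ln2.resize(L); dc.ln3.resize(L);
  dc.self_at.resize(L); dc.cross_at.resize(L); dc.ff.resize(L);
  dc.ln1_out.resize(L); dc.ln2_out.resize(L); dc.ln3_out.resize(L);
  std::vector<int> kb(pk.n()), ke(pk.n());
  for (int i = 0; i < pk.n(); ++i) { kb[i] = pk.off[i]; ke[i] = pk.off[i + 1]; }
  for (int l = 0; l < L; ++l) {
    std::string dd = "dec" + std::to_string(l);
    dc.ln1_out[l] = ln_fwd(Y, p.at(dd + ".ln1.g"), p.at(dd + ".ln1.b"), dc.ln1[l]);
    Y += attn_fwd(p, dd + ".self", cf, dc.ln1_out[l], dc.ln1_out[l],
                  pk.off, kb, ke, true, dc.self_at[l]);
    dc.ln2_out[l] = ln_fwd(Y, p.at(dd + ".ln2.g"), p.at(dd + ".ln2.b"), dc.ln2[l]);
    Y += attn_fwd(p, dd + ".cross", cf, dc.ln2_out[l], M,
                  pk.off, mem_beg, mem_end, false, dc.cross_at[l]);
    dc.ln3_out[l] = ln_fwd(Y, p.at(dd + ".ln3.g"), p.at(dd + ".ln3.b"), dc.ln3[l]);
    Y += ff_fwd(p, dd + ".ff", dc.ln3_out[l], dc.ff[l]);
  }
  dc.H = ln_fwd(Y, p.at("dec_ln.g"), p.at("dec_ln.b"), dc.lnf);
}

// Forward (+ optional backward) over a batch of (src, tgt) pairs.
// Returns summed token NLL; counts scored tokens and argmax-correct tokens.
static double batch_loss_grad(ParamStore& p, ParamStore* g, const Config& cf,
                              const std::vector<std::vector<int>>& src,
                              const std::vector<std::vector<int>>& tgt,
                              long* n_tokens, long* n_correct) {
  int n = (int)src.size();
  Pack ps; ps.seqs = src; ps.build();
  Pack pt; pt.seqs.resize(n);
  std::vector<std::vector<int>> lab(n);
  for (int i = 0; i < n; ++i) {
    pt.seqs[i].reserve(tgt[i].size() + 1);
    pt.seqs[i].push_back(cf.bos_id);
    pt.seqs[i].insert(pt.seqs[i].end(), tgt[i].begin(), tgt[i].end());
    lab[i] = tgt[i];
    lab[i].push_back(cf.eos_id);
  }
  pt.build();

  EncCache ec; encode_pack(p, cf, ps, ec);
  std::vector<int> mb(n), me(n);
  for (int i = 0; i < n; ++i) { mb[i] = ps.off[i]; me[i] = ps.off[i + 1]; }
  DecCache dc; decode_pack(p, cf, pt, ec.M, mb, me, dc);

  mat logits = dc.H * p.at("out_W");
  logits.each_row() += p.at("out_b");
  vec mx = max(logits, 1);
  mat sh = logits.each_col() - mx;
  vec lse = mx + log(sum(exp(sh), 1));
  double nll = 0;
  long correct = 0;
  for (int i = 0; i < n; ++i)
    for (size_t t = 0; t < lab[i].size(); ++t) {
      int r = pt.off[i] + (int)t;
      nll += lse(r) - logits(r, lab[i][t]);
      uword am; logits.row(r).max(am);
      if ((int)am == lab[i][t]) ++correct;
    }
  if (n_tokens) *n_tokens = pt.total;
  if (n_correct) *n_correct = correct;
  if (!g) return nll;

  mat dlogits = exp(logits.each_col() - lse);
  for (int i = 0; i < n; ++i)
    for (size_t t = 0; t < lab[i].size(); ++t)
      dlogits(pt.off[i] + t, lab[i][t]) -= 1.0;
  g->at("out_W") += dc.H.t() * dlogits;
  g->at("out_b") += sum(dlogits, 0);
  mat dH = dlogits * p.at("out_W").t();
  mat dY = ln_bwd(dH, p.at("dec_ln.g"), dc.lnf, g->at("dec_ln.g"), g->at("dec_ln.b"));
  mat dM(ec.M.n_rows, cf.d_model, fill::zeros);
  std::vector<int> kb(n), ke(n);
  for (int i = 0; i < n; ++i) { kb[i] = pt.off[i]; ke[i] = pt.off[i + 1]; }
  for (int l = cf.n_layers - 1; l >= 0; --l) {
    std::string dd = "dec" + std::to_string(l);
    mat dln3 = ff_bwd(p, *g, dd + ".ff", dc.ff[l], dY);
    dY += ln_bwd(dln3, p.at(dd + ".ln3.g"), dc.ln3[l], g->at(dd + ".ln3.g"), g->at(dd + ".ln3.b"));
    mat dln2 = attn_bwd(p, *g, dd + ".cross", cf, dc.cross_at[l], dY,
                        pt.off, mb, me, dM);
    dY += ln_bwd(dln2, p.at(dd + ".ln2.g"), dc.ln2[l], g->at(dd + ".ln2.g"), g->at(dd + ".ln2.b"));
    mat dself(pt.total, cf.d_model, fill::zeros);
    mat dln1 = attn_bwd(p, *g, dd + ".self", cf, dc.self_at[l], dY,
                        pt.off, kb, ke, dself);
    dln1 += dself;
    dY += ln_bwd(dln1, p.at(dd + ".ln1.g"), dc.ln1[l], g->at(dd + ".ln1.g"), g->at(dd + ".ln1.b"));
  }
  {
    mat& demb = g->at("tgt_emb");
    double s = std::sqrt((double)cf.d_model);
    for (int i = 0; i < n; ++i)
      for (size_t t = 0; t < pt.seqs[i].size(); ++t)
        demb.row(pt.seqs[i][t]) += dY.row(pt.off[i] + t) * s;
  }
  mat dX = ln_bwd(dM, p.at("enc_ln.g"), ec.lnf, g->at("enc_ln.g"), g->at("enc_ln.b"));
  std::vector<int> skb(n), ske(n);
  for (int i = 0; i < n; ++i) { skb[i] = ps.off[i]; ske[i] = ps.off[i + 1]; }
  for (int l = cf.n_layers - 1; l >= 0; --l) {
    std::string e = "enc" + std::to_string(l);
    mat dln2 = ff_bwd(p, *g, e + ".ff", ec.ff[l], dX);
    dX += ln_bwd(dln2, p.at(e + ".ln2.g"), ec.ln2[l], g->at(e + ".ln2.g"), g->at(e + ".ln2.b"));
    mat dself(ps.total, cf.d_model, fill::zeros);
    mat dln1 = attn_bwd(p, *g, e + ".attn", cf, ec.at[l], dX,
                        ps.off, skb, ske, dself);
    dln1 += dself;
    dX += ln_bwd(dln1, p.at(e + ".ln1.g"), ec.ln1[l], g->at(e + ".ln1.g"), g->at(e + ".ln1.b"));
  }
  if (!cf.freeze_src_emb) {
    mat& demb = g->at("src_emb");
    double s = std::sqrt((double)cf.d_model);
    for (int i = 0; i < n; ++i)
      for (size_t t = 0; t < ps.seqs[i].size(); ++t)
        demb.row(ps.seqs[i][t]) += dX.row(ps.off[i] + t) * s;
  }
  return nll;
}

// ---------- exports ---------------------------------------------------------

static std::vector<std::vector<int>> as_sequences(const Rcpp::List& lst) {
  std::vector<std::vector<int>> out(lst.size());
  for (int i = 0; i < lst.size(); ++i) {
    Rcpp::IntegerVector v = lst[i];
    out[i].resize(v.size());
    for (int j = 0; j < v.size(); ++j) out[i][j] = v[j] - 1;  // to 0-based
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List tf_init(Rcpp::List cfg) {
  Config c = read_config(cfg);
  ParamStore p; build_layout(p, c);
  std::mt19937 rng(c.seed);
  init_params(p, c, rng);
  return params_to_list(p);
}

// [[Rcpp::export]]
Rcpp::List tf_loss_grad(Rcpp::List params, Rcpp::List cfg,
                        Rcpp::IntegerVector src, Rcpp::IntegerVector tgt) {
  Config c = read_config(cfg);
  ParamStore p; build_layout(p, c); params_from_list(p, params);
  ParamStore g; build_layout(g, c);
  std::vector<std::vector<int>> s(1), t(1);
  s[0].resize(src.size()); t[0].resize(tgt.size());
  for (int i = 0; i < src.size(); ++i) s[0][i] = src[i] - 1;
  for (int i = 0; i < tgt.size(); ++i) t[0][i] = tgt[i] - 1;
  double loss = batch_loss_grad(p, &g, c, s, t, nullptr, nullptr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(g));
}

// [[Rcpp::export]]
Rcpp::List tf_train(Rcpp::List params, Rcpp::List cfg,
                    Rcpp::List train_src, Rcpp::List train_tgt,
                    Rcpp::List valid_src, Rcpp::List valid_tgt) {
  Config c = read_config(cfg);
  ParamStore p; build_layout(p, c); params_from_list(p, params);
  ParamStore g; build_layout(g, c);
  ParamStore m; build_layout(m, c);
  ParamStore v; build_layout(v, c);
  auto tr_s = as_sequences(train_src), tr_t = as_sequences(train_tgt);
  auto va_s = as_sequences(valid_src), va_t = as_sequences(valid_tgt);
  int n = tr_s.size();
  if (n == 0) Rcpp::stop("empty training set");
  std::mt19937 rng(c.seed + 1);

  auto validate = [&](double* acc, double* ppl) {
    double nll = 0; long tok = 0, ok = 0;
    size_t i = 0;
    while (i < va_s.size()) {
      std::vector<std::vector<int>> bs, bt;
      int toks = 0;
      while (i < va_s.size() && toks < 4096) {
        bs.push_back(va_s[i]); bt.push_back(va_t[i]);
        toks += (int)va_s[i].size() + (int)va_t[i].size() + 2;
        ++i;
      }
      long nt = 0, nc = 0;
      nll += batch_loss_grad(p, nullptr, c, bs, bt, &nt, &nc);
      tok += nt; ok += nc;
    }
    *acc = tok > 0 ? (double)ok / tok : 0.0;
    *ppl = tok > 0 ? std::exp(nll / tok) : 1e30;
  };

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  int pos = n;  // force reshuffle at start

  double best_acc = -1, best_ppl = datum::inf;
  int bad_validations = 0, step = 0, best_step = 0;
  std::string stop_reason = "max_steps";
  ParamStore best; build_layout(best, c); best.v = p.v;
  std::vector<int> log_step; std::vector<double> log_acc, log_ppl;

  const double b1 = 0.9, b2 = 0.98, eps = 1e-9;

  while (step < c.max_steps) {
    std::vector<std::vector<int>> bs, bt;
    int toks = 0;
    while (toks < c.batch_tokens) {
      if (pos >= n) { std::shuffle(order.begin(), order.end(), rng); pos = 0; }
      int i = order[pos++];
      bs.push_back(tr_s[i]); bt.push_back(tr_t[i]);
      toks += (int)tr_s[i].size() + (int)tr_t[i].size() + 2;
    }
    for (auto& gm : g.v) gm.zeros();
    long btok = 0;
    batch_loss_grad(p, &g, c, bs, bt, &btok, nullptr);
    double inv = 1.0 / std::max<long>(btok, 1);
    double sq = 0;
    for (auto& gm : g.v) { gm *= inv; sq += accu(square(gm)); }
    double nrm = std::sqrt(sq);
    if (nrm > c.grad_clip)
      for (auto& gm : g.v) gm *= c.grad_clip / nrm;
    ++step;
    double bc1 = 1.0 - std::pow(b1, step), bc2 = 1.0 - std::pow(b2, step);
    for (size_t k = 0; k < p.v.size(); ++k) {
      if (c.freeze_src_emb && p.names[k] == "src_emb") continue;
      m.v[k] = b1 * m.v[k] + (1 - b1) * g.v[k];
      v.v[k] = b2 * v.v[k] + (1 - b2) * square(g.v[k]);
      p.v[k] -= c.lr * (m.v[k] / bc1) / (sqrt(v.v[k] / bc2) + eps);
    }
    if (step % c.validate_every == 0) {
      double acc, ppl; validate(&acc, &ppl);
      log_step.push_back(step); log_acc.push_back(acc); log_ppl.push_back(ppl);
      bool improved = false;
      if (acc > best_acc + 1e-12) { best_acc = acc; improved = true; }
      if (ppl < best_ppl - 1e-12) { best_ppl = ppl; improved = true; }
      if (improved) {
        bad_validations = 0;
        best.v = p.v;
        best_step = step;
      } else if (++bad_validations >= c.patience) {
        stop_reason = "early_stopping";
        break;
      }
      Rcpp::checkUserInterrupt();
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = params_to_list(best),
    Rcpp::Named("log") = Rcpp::DataFrame::create(
      Rcpp::Named("step") = log_step,
      Rcpp::Named("token_accuracy") = log_acc,
      Rcpp::Named("perplexity") = log_ppl),
    Rcpp::Named("stopped_at") = step,
    Rcpp::Named("best_step") = best_step,
    Rcpp::Named("stop_reason") = stop_reason);
}

// ---------- beam search -----------------------------------------------------

struct Beam {
  std::vector<int> ids;
  double logp;
  bool done;
};

// [[Rcpp::export]]
Rcpp::List tf_predict(Rcpp::List params, Rcpp::List cfg, Rcpp::List src, int k) {
  Config c = read_config(cfg);
  if (k < 1 || k > c.beam_size) Rcpp::stop("k must be between 1 and beam_size");
  ParamStore p; build_layout(p, c); params_from_list(p, params);
  auto sources = as_sequences(src);
  Rcpp::List out(sources.size());

  for (size_t si = 0; si < sources.size(); ++si) {
    Pack ps; ps.seqs.push_back(sources[si]); ps.build();
    EncCache ec; encode_pack(p, c, ps, ec);
    int Tm = ec.M.n_rows;
    int max_len = std::min(c.max_decode_len, (int)(2 * sources[si].size() + 20));
    std::vector<Beam> beams{{std::vector<int>(), 0.0, false}};
    for (int stepi = 0; stepi < max_len; ++stepi) {
      std::vector<int> live;
      for (size_t b = 0; b < beams.size(); ++b) if (!beams[b].done) live.push_back(b);
      if (live.empty()) break;
      // pack all live beams into one decoder call
      Pack pt;
      for (int b : live) {
        std::vector<int> tin; tin.reserve(beams[b].ids.size() + 1);
        tin.push_back(c.bos_id);
        tin.insert(tin.end(), beams[b].ids.begin(), beams[b].ids.end());
        pt.seqs.push_back(tin);
      }
      pt.build();
      std::vector<int> mb(pt.n(), 0), me(pt.n(), Tm);
      DecCache dc; decode_pack(p, c, pt, ec.M, mb, me, dc);
      std::vector<Beam> pool;
      for (auto& b : beams) if (b.done) pool.push_back(b);
      for (int bi = 0; bi < (int)live.size(); ++bi) {
        const Beam& b = beams[live[bi]];
        rowvec logits = dc.H.row(pt.off[bi + 1] - 1) * p.at("out_W") + p.at("out_b");
        double mx = logits.max();
        rowvec lp = logits - (mx + std::log(accu(exp(logits - mx))));
        uvec ord = sort_index(lp, "descend");
        for (int j = 0; j < c.beam_size && j < (int)ord.n_elem; ++j) {
          Beam nb = b;
          int tok = ord(j);
          nb.logp += lp(tok);
          if (tok == c.eos_id) nb.done = true;
          else nb.ids.push_back(tok);
          pool.push_back(nb);
        }
      }
      std::stable_sort(pool.begin(), pool.end(),
                       [](const Beam& a, const Beam& b) { return a.logp > b.logp; });
      if ((int)pool.size() > c.beam_size) pool.resize(c.beam_size);
      beams = pool;
    }
    std::stable_sort(beams.begin(), beams.end(),
                     [](const Beam& a, const Beam& b) { return a.logp > b.logp; });
    int nk = std::min((int)beams.size(), k);
    Rcpp::List cand(nk);
    Rcpp::NumericVector scores(nk);
    for (int j = 0; j < nk; ++j) {
      Rcpp::IntegerVector ids(beams[j].ids.size());
      for (size_t t = 0; t < beams[j].ids.size(); ++t) ids[t] = beams[j].ids[t] + 1;
      cand[j] = ids;
      scores[j] = beams[j].logp;
    }
    out[si] = Rcpp::List::create(Rcpp::Named("ids") = cand,
                                 Rcpp::Named("scores") = scores);
  }
  return out;
}
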