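// Neural chain-CRF compute core.
//
// Layout conventions (column-major throughout):
//   - token embeddings X: d_e x N, one column per token
//   - BiLSTM hidden states H: d x N (forward states stacked over backward)
//   - unary scores: L x N; pairwise scores: cube L x L x (N-1), slice e
//     scoring (label at e, label at e+1) with the PREVIOUS label as row index
//   - label sequences y arrive 1-based from R and are used 0-based here
//
// The two binding layers use weight normalization (W row j = g_j * v_j/|v_j|),
// so their trainable parameters are direction matrices *_v and row gains *_g.
//
// The training path batches the LSTM recurrences across the minibatch:
// sentences are sorted by decreasing length so the set of sequences still
// active at step t is always a prefix, and each step runs one gemm over the
// active columns instead of per-sentence gemvs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Config {
  int L, d, c, m, H, d_e;
  bool share_bilstm, trainable_emb;
  double dropout_keep, ln_eps;
};

static Config read_config(const Rcpp::List& cfg) {
  Config c;
  c.L = Rcpp::as<int>(cfg["L"]);
  c.d = Rcpp::as<int>(cfg["d"]);
  c.c = Rcpp::as<int>(cfg["c"]);
  c.m = Rcpp::as<int>(cfg["m"]);
  c.d_e = Rcpp::as<int>(cfg["d_e"]);
  c.H = c.d / 2;
  c.share_bilstm = Rcpp::as<bool>(cfg["share_bilstm"]);
  c.trainable_emb = Rcpp::as<bool>(cfg["trainable_embeddings"]);
  c.dropout_keep = Rcpp::as<double>(cfg["dropout_keep"]);
  c.ln_eps = Rcpp::as<double>(cfg["ln_eps"]);
  return c;
}

// ---------------------------------------------------------------- numerics

static inline double lse(const vec& v) {
  double mx = v.max();
  return mx + std::log(accu(exp(v - mx)));
}

static inline mat elu(const mat& z) {
  mat out = z;
  for (uword i = 0; i < z.n_elem; ++i)
    if (z[i] <= 0.0) out[i] = std::expm1(z[i]);
  return out;
}
// derivative of ELU expressed through the pre-activation z
static inline mat elu_grad(const mat& z) {
  mat out(size(z), fill::ones);
  for (uword i = 0; i < z.n_elem; ++i)
    if (z[i] <= 0.0) out[i] = std::exp(z[i]);
  return out;
}

// ------------------------------------------------------------- weight norm

struct WnCache { mat What; mat Vhat; vec rn; };

static mat wn_forward(const mat& V, const vec& g, WnCache& cache) {
  cache.rn = sqrt(sum(square(V), 1));      // row norms
  cache.Vhat = V.each_col() / cache.rn;
  cache.What = cache.Vhat.each_col() % g;
  return cache.What;
}

static void wn_backward(const mat& dW, const vec& g, const WnCache& cache,
                        mat& dV, vec& dg) {
  vec dot_dw_vhat = sum(dW % cache.Vhat, 1);
  dg += dot_dw_vhat;
  mat rest = dW - (cache.Vhat.each_col() % dot_dw_vhat);
  dV += rest.each_col() % (g / cache.rn);
}

// ------------------------------------------------------------ batched LSTM
//
// Sentences are packed column-wise into one matrix; offs[s] is the first
// column of sentence s and lens[s] its length, with lens non-increasing.

static uword active_count(const uvec& lens, uword t) {
  uword k = 0;
  while (k < lens.n_elem && lens[k] > t) ++k;
  return k;
}

// reverse the columns of each sentence block (time reversal per sentence)
static mat flip_sentences(const mat& M, const uvec& lens, const uvec& offs) {
  mat out(size(M));
  for (uword s = 0; s < lens.n_elem; ++s)
    out.cols(offs[s], offs[s] + lens[s] - 1) =
      fliplr(M.cols(offs[s], offs[s] + lens[s] - 1));
  return out;
}

struct LstmCache { mat G; mat C; mat Hh; };  // gates (4H x T), cells, hiddens

static mat lstm_forward(const mat& Xcat, const uvec& lens, const uvec& offs,
                        const mat& W, const mat& U, const vec& b,
                        LstmCache& cache) {
  const uword H = U.n_cols, total = Xcat.n_cols, B = lens.n_elem;
  const uword maxN = lens[0];
  mat Zx = W * Xcat;
  Zx.each_col() += b;
  cache.G.set_size(4 * H, total);
  cache.C.set_size(H, total);
  cache.Hh.set_size(H, total);
  mat hprev(H, B, fill::zeros), cprev(H, B, fill::zeros);
  for (uword t = 0; t < maxN; ++t) {
    uword k = active_count(lens, t);
    mat Z(4 * H, k);
    for (uword s = 0; s < k; ++s) Z.col(s) = Zx.col(offs[s] + t);
    Z += U * hprev.cols(0, k - 1);
    mat ig = 1.0 / (1.0 + exp(-Z.rows(0, H - 1)));
    mat fg = 1.0 / (1.0 + exp(-Z.rows(H, 2 * H - 1)));
    mat og = 1.0 / (1.0 + exp(-Z.rows(2 * H, 3 * H - 1)));
    mat gg = tanh(Z.rows(3 * H, 4 * H - 1));
    mat cnew = fg % cprev.cols(0, k - 1) + ig % gg;
    mat hnew = og % tanh(cnew);
    for (uword s = 0; s < k; ++s) {
      uword col = offs[s] + t;
      cache.G.col(col).subvec(0, H - 1) = ig.col(s);
      cache.G.col(col).subvec(H, 2 * H - 1) = fg.col(s);
      cache.G.col(col).subvec(2 * H, 3 * H - 1) = og.col(s);
      cache.G.col(col).subvec(3 * H, 4 * H - 1) = gg.col(s);
      cache.C.col(col) = cnew.col(s);
      cache.Hh.col(col) = hnew.col(s);
    }
    hprev.cols(0, k - 1) = hnew;
    cprev.cols(0, k - 1) = cnew;
  }
  return cache.Hh;
}

// returns dX; accumulates dW, dU, db
static mat lstm_backward(const mat& Xcat, const uvec& lens, const uvec& offs,
                         const mat& W, const mat& U, const LstmCache& cache,
                         const mat& dH, mat& dW, mat& dU, vec& db) {
  const uword H = U.n_cols, total = Xcat.n_cols, B = lens.n_elem;
  const uword maxN = lens[0];
  mat dZ_all(4 * H, total, fill::zeros);
  mat dh_carry(H, B, fill::zeros), dc_carry(H, B, fill::zeros);
  for (uword step = 0; step < maxN; ++step) {
    uword t = maxN - 1 - step;
    uword k = active_count(lens, t);
    mat ig(H, k), fg(H, k), og(H, k), gg(H, k), cc(H, k), cprev(H, k),
        dh(H, k);
    for (uword s = 0; s < k; ++s) {
      uword col = offs[s] + t;
      ig.col(s) = cache.G.col(col).subvec(0, H - 1);
      fg.col(s) = cache.G.col(col).subvec(H, 2 * H - 1);
      og.col(s) = cache.G.col(col).subvec(2 * H, 3 * H - 1);
      gg.col(s) = cache.G.col(col).subvec(3 * H, 4 * H - 1);
      cc.col(s) = cache.C.col(col);
      if (t > 0) cprev.col(s) = cache.C.col(col - 1);
      else cprev.col(s).zeros();
      dh.col(s) = dH.col(col) + dh_carry.col(s);
    }
    mat tc = tanh(cc);
    mat dog = dh % tc;
    mat dc = dc_carry.cols(0, k - 1) + dh % og % (1.0 - square(tc));
    mat dig = dc % gg;
    mat dgg = dc % ig;
    mat dfg = dc % cprev;
    dc_carry.cols(0, k - 1) = dc % fg;
    mat dz(4 * H, k);
    dz.rows(0, H - 1) = dig % ig % (1.0 - ig);
    dz.rows(H, 2 * H - 1) = dfg % fg % (1.0 - fg);
    dz.rows(2 * H, 3 * H - 1) = dog % og % (1.0 - og);
    dz.rows(3 * H, 4 * H - 1) = dgg % (1.0 - square(gg));
    for (uword s = 0; s < k; ++s) dZ_all.col(offs[s] + t) = dz.col(s);
    dh_carry.cols(0, k - 1) = U.t() * dz;
  }
  dW += dZ_all * Xcat.t();
  db += sum(dZ_all, 1);
  mat Hshift(H, total, fill::zeros);          // hidden state one step back
  for (uword s = 0; s < B; ++s)
    if (lens[s] > 1)
      Hshift.cols(offs[s] + 1, offs[s] + lens[s] - 1) =
        cache.Hh.cols(offs[s], offs[s] + lens[s] - 2);
  dU += dZ_all * Hshift.t();
  return W.t() * dZ_all;
}

struct BiCache { LstmCache fw, bw; mat Xrev; };

static mat bilstm_forward(const mat& Xcat, const uvec& lens, const uvec& offs,
                          const mat& Wf, const mat& Uf, const vec& bf,
                          const mat& Wb, const mat& Ub, const vec& bb,
                          BiCache& cache) {
  mat Hf = lstm_forward(Xcat, lens, offs, Wf, Uf, bf, cache.fw);
  cache.Xrev = flip_sentences(Xcat, lens, offs);
  mat Hbrev = lstm_forward(cache.Xrev, lens, offs, Wb, Ub, bb, cache.bw);
  return join_cols(Hf, flip_sentences(Hbrev, lens, offs));
}

static mat bilstm_backward(const mat& Xcat, const uvec& lens, const uvec& offs,
                           const mat& Wf, const mat& Uf,
                           const mat& Wb, const mat& Ub, const BiCache& cache,
                           const mat& dH,
                           mat& dWf, mat& dUf, vec& dbf,
                           mat& dWb, mat& dUb, vec& dbb) {
  const uword H = Uf.n_cols;
  mat dX = lstm_backward(Xcat, lens, offs, Wf, Uf, cache.fw,
                         dH.rows(0, H - 1), dWf, dUf, dbf);
  mat dHb_rev = flip_sentences(dH.rows(H, 2 * H - 1), lens, offs);
  mat dXrev = lstm_backward(cache.Xrev, lens, offs, Wb, Ub, cache.bw,
                            dHb_rev, dWb, dUb, dbb);
  return dX + flip_sentences(dXrev, lens, offs);
}

// ---------------------------------------------------------------- chain CRF

// Negative log-likelihood and its gradient (marginals minus indicators).
// nodes: L x N; edges: cube L x L x (N-1); y 0-based.
static double crf_nll_grad(const mat& nodes, const cube& edges,
                           const ivec& y, mat& dnodes, cube& dedges,
                           bool want_grad) {
  const uword L = nodes.n_rows, N = nodes.n_cols;
  mat alpha(L, N);
  alpha.col(0) = nodes.col(0);
  for (uword i = 1; i < N; ++i) {
    mat tmp = edges.slice(i - 1);
    tmp.each_col() += alpha.col(i - 1);
    for (uword k = 0; k < L; ++k)
      alpha(k, i) = nodes(k, i) + lse(tmp.col(k));
  }
  double logZ = lse(alpha.col(N - 1));
  double score = 0.0;
  for (uword i = 0; i < N; ++i) score += nodes(y[i], i);
  for (uword i = 0; i + 1 < N; ++i) score += edges(y[i], y[i + 1], i);
  if (want_grad) {
    mat beta(L, N, fill::zeros);
    for (uword s = 1; s < N; ++s) {
      uword i = N - 1 - s;
      vec rhs = nodes.col(i + 1) + beta.col(i + 1);
      mat tmp = edges.slice(i);
      tmp.each_row() += rhs.t();
      for (uword j = 0; j < L; ++j)
        beta(j, i) = lse(tmp.row(j).t());
    }
    dnodes = exp(alpha + beta - logZ);
    for (uword i = 0; i < N; ++i) dnodes(y[i], i) -= 1.0;
    for (uword e = 0; e + 1 < N; ++e) {
      mat M = edges.slice(e);
      M.each_col() += alpha.col(e);
      M.each_row() += (nodes.col(e + 1) + beta.col(e + 1)).t();
      M = exp(M - logZ);
      M(y[e], y[e + 1]) -= 1.0;
      dedges.slice(e) = M;
    }
  }
  return logZ - score;
}

// ------------------------------------------------------------ param access

struct Params {
  mat E; vec ln_g, ln_b;
  mat u_fw_W, u_fw_U, u_bw_W, u_bw_U; vec u_fw_b, u_bw_b;
  mat p_fw_W, p_fw_U, p_bw_W, p_bw_U; vec p_fw_b, p_bw_b;
  mat u_W1_v, u_W2_v; vec u_W1_g, u_W2_g, u_b1, u_b2;
  mat A;
  mat Q1, Q2, Hm;
  mat p_W1_v, p_W2_v; vec p_W1_g, p_W2_g, p_b1, p_b2;
};

static Params read_params(const Rcpp::List& P, const Config& cfg) {
  Params p;
  p.E = Rcpp::as<mat>(P["E"]);
  p.ln_g = Rcpp::as<vec>(P["ln_g"]); p.ln_b = Rcpp::as<vec>(P["ln_b"]);
  p.u_fw_W = Rcpp::as<mat>(P["u_fw_W"]); p.u_fw_U = Rcpp::as<mat>(P["u_fw_U"]);
  p.u_fw_b = Rcpp::as<vec>(P["u_fw_b"]);
  p.u_bw_W = Rcpp::as<mat>(P["u_bw_W"]); p.u_bw_U = Rcpp::as<mat>(P["u_bw_U"]);
  p.u_bw_b = Rcpp::as<vec>(P["u_bw_b"]);
  if (!cfg.share_bilstm) {
    p.p_fw_W = Rcpp::as<mat>(P["p_fw_W"]); p.p_fw_U = Rcpp::as<mat>(P["p_fw_U"]);
    p.p_fw_b = Rcpp::as<vec>(P["p_fw_b"]);
    p.p_bw_W = Rcpp::as<mat>(P["p_bw_W"]); p.p_bw_U = Rcpp::as<mat>(P["p_bw_U"]);
    p.p_bw_b = Rcpp::as<vec>(P["p_bw_b"]);
  }
  p.u_W1_v = Rcpp::as<mat>(P["u_W1_v"]); p.u_W1_g = Rcpp::as<vec>(P["u_W1_g"]);
  p.u_b1 = Rcpp::as<vec>(P["u_b1"]);
  p.u_W2_v = Rcpp::as<mat>(P["u_W2_v"]); p.u_W2_g = Rcpp::as<vec>(P["u_W2_g"]);
  p.u_b2 = Rcpp::as<vec>(P["u_b2"]);
  p.A = Rcpp::as<mat>(P["A"]);
  p.Q1 = Rcpp::as<mat>(P["Q1"]); p.Q2 = Rcpp::as<mat>(P["Q2"]);
  p.Hm = Rcpp::as<mat>(P["Hm"]);
  p.p_W1_v = Rcpp::as<mat>(P["p_W1_v"]); p.p_W1_g = Rcpp::as<vec>(P["p_W1_g"]);
  p.p_b1 = Rcpp::as<vec>(P["p_b1"]);
  p.p_W2_v = Rcpp::as<mat>(P["p_W2_v"]); p.p_W2_g = Rcpp::as<vec>(P["p_W2_g"]);
  p.p_b2 = Rcpp::as<vec>(P["p_b2"]);
  return p;
}

struct Grads {
  mat E; vec ln_g, ln_b;
  mat u_fw_W, u_fw_U, u_bw_W, u_bw_U; vec u_fw_b, u_bw_b;
  mat p_fw_W, p_fw_U, p_bw_W, p_bw_U; vec p_fw_b, p_bw_b;
  mat u_W1_v, u_W2_v; vec u_W1_g, u_W2_g, u_b1, u_b2;
  mat A;
  mat Q1, Q2, Hm;
  mat p_W1_v, p_W2_v; vec p_W1_g, p_W2_g, p_b1, p_b2;

  Grads(const Params& p, const Config& cfg) {
    if (cfg.trainable_emb) E = zeros<mat>(size(p.E));
    ln_g = zeros<vec>(size(p.ln_g)); ln_b = zeros<vec>(size(p.ln_b));
    u_fw_W = zeros<mat>(size(p.u_fw_W)); u_fw_U = zeros<mat>(size(p.u_fw_U));
    u_fw_b = zeros<vec>(size(p.u_fw_b));
    u_bw_W = zeros<mat>(size(p.u_bw_W)); u_bw_U = zeros<mat>(size(p.u_bw_U));
    u_bw_b = zeros<vec>(size(p.u_bw_b));
    if (!cfg.share_bilstm) {
      p_fw_W = zeros<mat>(size(p.p_fw_W)); p_fw_U = zeros<mat>(size(p.p_fw_U));
      p_fw_b = zeros<vec>(size(p.p_fw_b));
      p_bw_W = zeros<mat>(size(p.p_bw_W)); p_bw_U = zeros<mat>(size(p.p_bw_U));
      p_bw_b = zeros<vec>(size(p.p_bw_b));
    }
    u_W1_v = zeros<mat>(size(p.u_W1_v)); u_W1_g = zeros<vec>(size(p.u_W1_g));
    u_b1 = zeros<vec>(size(p.u_b1));
    u_W2_v = zeros<mat>(size(p.u_W2_v)); u_W2_g = zeros<vec>(size(p.u_W2_g));
    u_b2 = zeros<vec>(size(p.u_b2));
    A = zeros<mat>(size(p.A));
    Q1 = zeros<mat>(size(p.Q1)); Q2 = zeros<mat>(size(p.Q2));
    Hm = zeros<mat>(size(p.Hm));
    p_W1_v = zeros<mat>(size(p.p_W1_v)); p_W1_g = zeros<vec>(size(p.p_W1_g));
    p_b1 = zeros<vec>(size(p.p_b1));
    p_W2_v = zeros<mat>(size(p.p_W2_v)); p_W2_g = zeros<vec>(size(p.p_W2_g));
    p_b2 = zeros<vec>(size(p.p_b2));
  }

  Rcpp::List as_list(const Config& cfg) const {
    Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("ln_g") = ln_g, Rcpp::Named("ln_b") = ln_b,
      Rcpp::Named("u_fw_W") = u_fw_W, Rcpp::Named("u_fw_U") = u_fw_U,
      Rcpp::Named("u_fw_b") = u_fw_b,
      Rcpp::Named("u_bw_W") = u_bw_W, Rcpp::Named("u_bw_U") = u_bw_U,
      Rcpp::Named("u_bw_b") = u_bw_b,
      Rcpp::Named("u_W1_v") = u_W1_v, Rcpp::Named("u_W1_g") = u_W1_g,
      Rcpp::Named("u_b1") = u_b1,
      Rcpp::Named("u_W2_v") = u_W2_v, Rcpp::Named("u_W2_g") = u_W2_g,
      Rcpp::Named("u_b2") = u_b2,
      Rcpp::Named("A") = A,
      Rcpp::Named("Q1") = Q1, Rcpp::Named("Q2") = Q2,
      Rcpp::Named("Hm") = Hm);
    out["p_W1_v"] = p_W1_v; out["p_W1_g"] = p_W1_g; out["p_b1"] = p_b1;
    out["p_W2_v"] = p_W2_v; out["p_W2_g"] = p_W2_g; out["p_b2"] = p_b2;
    if (!cfg.share_bilstm) {
      out["p_fw_W"] = p_fw_W; out["p_fw_U"] = p_fw_U; out["p_fw_b"] = p_fw_b;
      out["p_bw_W"] = p_bw_W; out["p_bw_U"] = p_bw_U; out["p_bw_b"] = p_bw_b;
    }
    if (cfg.trainable_emb) out["E"] = E;
    return out;
  }
};

// ----------------------------------------------------- embedding + layernorm

struct LnCache { mat Xhat; rowvec inv_std; };

// ids 0-based; ctx may be empty; returns d_e x N normalized embeddings
static mat embed_forward(const uvec& ids, const mat& ctx, const Params& p,
                         const Config& cfg, LnCache& ln) {
  const uword N = ids.n_elem;
  const uword d_w = p.E.n_cols;
  mat Xraw(cfg.d_e, N);
  for (uword t = 0; t < N; ++t) {
    Xraw.col(t).subvec(0, d_w - 1) = p.E.row(ids[t]).t();
    if (ctx.n_elem > 0)
      Xraw.col(t).subvec(d_w, cfg.d_e - 1) = ctx.row(t).t();
  }
  rowvec mu = mean(Xraw, 0);
  mat centered = Xraw.each_row() - mu;
  rowvec v = mean(square(centered), 0);
  ln.inv_std = 1.0 / sqrt(v + cfg.ln_eps);
  ln.Xhat = centered.each_row() % ln.inv_std;
  mat X = ln.Xhat.each_col() % p.ln_g;
  X.each_col() += p.ln_b;
  return X;
}

static void embed_backward(const mat& dX, const uvec& ids, const Params& p,
                           const Config& cfg, const LnCache& ln, Grads& g) {
  g.ln_g += sum(dX % ln.Xhat, 1);
  g.ln_b += sum(dX, 1);
  mat dXhat = dX.each_col() % p.ln_g;
  rowvec mean_dxh = mean(dXhat, 0);
  rowvec mean_dxh_xh = mean(dXhat % ln.Xhat, 0);
  mat dXraw = dXhat.each_row() - mean_dxh;
  dXraw -= ln.Xhat.each_row() % mean_dxh_xh;
  dXraw.each_row() %= ln.inv_std;
  if (cfg.trainable_emb) {
    const uword d_w = p.E.n_cols;
    for (uword t = 0; t < ids.n_elem; ++t)
      g.E.row(ids[t]) += dXraw.col(t).subvec(0, d_w - 1).t();
  }
}

// ----------------------------------------------- network heads (per sentence)

struct UnaryCache { mat Hd, Mask, A1; WnCache w1, w2; };

// Hu: d x N hidden states; returns U scores (L x N)
static mat unary_head_forward(const mat& Hu, const Params& p,
                              const Config& cfg, bool dropout,
                              UnaryCache& c) {
  c.Hd = Hu;
  if (dropout) {
    c.Mask.set_size(size(Hu));
    for (uword i = 0; i < c.Mask.n_elem; ++i)
      c.Mask[i] = (R::unif_rand() < cfg.dropout_keep) ? 1.0 / cfg.dropout_keep
                                                      : 0.0;
    c.Hd %= c.Mask;
  }
  mat W1 = wn_forward(p.u_W1_v, p.u_W1_g, c.w1);
  mat W2 = wn_forward(p.u_W2_v, p.u_W2_g, c.w2);
  c.A1 = W1 * c.Hd;
  c.A1.each_col() += p.u_b1;
  mat R = elu(c.A1) + c.Hd;
  mat U = W2 * R;
  U.each_col() += p.u_b2;
  return U;
}

// returns dHu (gradient at the BiLSTM output)
static mat unary_head_backward(const mat& dU, const Params& p,
                               bool dropout, const UnaryCache& c, Grads& g) {
  mat R = elu(c.A1) + c.Hd;
  mat dW2 = dU * R.t();
  g.u_b2 += sum(dU, 1);
  mat dR = c.w2.What.t() * dU;
  mat dA1 = dR % elu_grad(c.A1);
  mat dW1 = dA1 * c.Hd.t();
  g.u_b1 += sum(dA1, 1);
  mat dHd = dR + c.w1.What.t() * dA1;
  wn_backward(dW1, p.u_W1_g, c.w1, g.u_W1_v, g.u_W1_g);
  wn_backward(dW2, p.u_W2_g, c.w2, g.u_W2_v, g.u_W2_g);
  if (dropout) dHd %= c.Mask;
  return dHd;
}

struct PairCache { mat P, Q, Umat, Fd, Mask, A1; WnCache w1, w2; };

// Hp: d x N with N >= 2; returns V scores as cube L x L x (N-1)
static cube pairwise_head_forward(const mat& Hp, const Params& p,
                                  const Config& cfg, bool dropout,
                                  PairCache& c) {
  const uword N = Hp.n_cols, L = cfg.L;
  c.P = p.Q1 * Hp;
  c.Q = p.Q2 * Hp;
  c.Umat = c.P.cols(0, N - 2) % c.Q.cols(1, N - 1);
  c.Fd = p.Hm * c.Umat;
  if (dropout) {
    c.Mask.set_size(size(c.Fd));
    for (uword i = 0; i < c.Mask.n_elem; ++i)
      c.Mask[i] = (R::unif_rand() < cfg.dropout_keep) ? 1.0 / cfg.dropout_keep
                                                      : 0.0;
    c.Fd %= c.Mask;
  }
  mat W1 = wn_forward(p.p_W1_v, p.p_W1_g, c.w1);
  mat W2 = wn_forward(p.p_W2_v, p.p_W2_g, c.w2);
  c.A1 = W1 * c.Fd;
  c.A1.each_col() += p.p_b1;
  mat R = elu(c.A1) + c.Fd;
  mat Vflat = W2 * R;                       // L^2 x (N-1)
  Vflat.each_col() += p.p_b2;
  cube V(L, L, N - 1);
  for (uword e = 0; e + 1 < N; ++e)
    V.slice(e) = reshape(mat(Vflat.col(e)), L, L).t();  // index j*L+k, j = prev
  return V;
}

// dV cube -> returns dHp
static mat pairwise_head_backward(const cube& dV, const mat& Hp,
                                  const Params& p, const Config& cfg,
                                  bool dropout, const PairCache& c, Grads& g) {
  const uword L = cfg.L, E = dV.n_slices, N = E + 1;
  mat dVflat(L * L, E);
  for (uword e = 0; e < E; ++e)
    dVflat.col(e) = vectorise(dV.slice(e).t());
  mat R = elu(c.A1) + c.Fd;
  mat dW2 = dVflat * R.t();
  g.p_b2 += sum(dVflat, 1);
  mat dR = c.w2.What.t() * dVflat;
  mat dA1 = dR % elu_grad(c.A1);
  mat dW1 = dA1 * c.Fd.t();
  g.p_b1 += sum(dA1, 1);
  mat dFd = dR + c.w1.What.t() * dA1;
  wn_backward(dW1, p.p_W1_g, c.w1, g.p_W1_v, g.p_W1_g);
  wn_backward(dW2, p.p_W2_g, c.w2, g.p_W2_v, g.p_W2_g);
  if (dropout) dFd %= c.Mask;
  g.Hm += dFd * c.Umat.t();
  mat dU = p.Hm.t() * dFd;                  // c x (N-1)
  mat dP(size(c.P), fill::zeros), dQ(size(c.Q), fill::zeros);
  dP.cols(0, N - 2) = dU % c.Q.cols(1, N - 1);
  dQ.cols(1, N - 1) = dU % c.P.cols(0, N - 2);
  g.Q1 += dP * Hp.t();
  g.Q2 += dQ * Hp.t();
  return p.Q1.t() * dP + p.Q2.t() * dQ;
}

static cube broadcast_edges(const mat& A, uword n_edges) {
  cube E(A.n_rows, A.n_cols, n_edges);
  for (uword e = 0; e < n_edges; ++e) E.slice(e) = A;
  return E;
}

// --------------------------------------------------------------- exports

// Joint negative log-likelihoods and parameter gradients for a minibatch.
// Returns per-sentence NLL vectors and gradient SUMS over the batch
// (no L2 term; the caller owns regularization and batch averaging).
// [[Rcpp::export]]
Rcpp::List cpp_batch_loss_grad(Rcpp::List ids_list, Rcpp::List ctx_list,
                               Rcpp::List y_list, Rcpp::List params,
                               Rcpp::List config, bool dropout,
                               bool want_grad) {
  Config cfg = read_config(config);
  Params p = read_params(params, cfg);
  Grads g(p, cfg);
  const uword B = ids_list.size();
  const uword L = cfg.L;
  vec nll_u(B), nll_p(B);

  std::vector<uvec> ids(B);
  std::vector<mat> ctx(B);
  std::vector<ivec> ys(B);
  uvec lens_raw(B);
  for (uword s = 0; s < B; ++s) {
    ids[s] = Rcpp::as<uvec>(ids_list[s]) - 1;
    if (ctx_list.size() > 0) {
      SEXP cs = ctx_list[s];
      if (!Rf_isNull(cs)) ctx[s] = Rcpp::as<mat>(cs);
    }
    ys[s] = Rcpp::as<ivec>(y_list[s]) - 1;
    lens_raw[s] = ids[s].n_elem;
  }
  // order sentences by non-increasing length so active sets are prefixes
  uvec order = stable_sort_index(lens_raw, "descend");
  uvec lens(B), offs(B);
  uword total = 0;
  for (uword r = 0; r < B; ++r) {
    lens[r] = lens_raw[order[r]];
    offs[r] = total;
    total += lens[r];
  }

  mat Xcat(cfg.d_e, total);
  std::vector<LnCache> ln(B);
  for (uword r = 0; r < B; ++r) {
    uword s = order[r];
    Xcat.cols(offs[r], offs[r] + lens[r] - 1) =
      embed_forward(ids[s], ctx[s], p, cfg, ln[r]);
  }

  BiCache ub;
  mat Hu_all = bilstm_forward(Xcat, lens, offs,
                              p.u_fw_W, p.u_fw_U, p.u_fw_b,
                              p.u_bw_W, p.u_bw_U, p.u_bw_b, ub);
  mat Hp_all;
  BiCache pb;
  if (!cfg.share_bilstm)
    Hp_all = bilstm_forward(Xcat, lens, offs,
                            p.p_fw_W, p.p_fw_U, p.p_fw_b,
                            p.p_bw_W, p.p_bw_U, p.p_bw_b, pb);
  const mat& Hpair_all = cfg.share_bilstm ? Hu_all : Hp_all;

  mat dHu_all(size(Hu_all), fill::zeros);
  mat dHp_all;
  if (!cfg.share_bilstm) dHp_all.zeros(size(Hp_all));

  for (uword r = 0; r < B; ++r) {
    uword s = order[r];
    const uword N = lens[r];
    mat Hu = Hu_all.cols(offs[r], offs[r] + N - 1);
    UnaryCache uc;
    mat U = unary_head_forward(Hu, p, cfg, dropout, uc);
    cube Aedges = broadcast_edges(p.A, N > 1 ? N - 1 : 0);
    mat dU(L, N); cube dAedges(L, L, N > 1 ? N - 1 : 0);
    nll_u[s] = crf_nll_grad(U, Aedges, ys[s], dU, dAedges, want_grad);

    bool has_pair = N >= 2;
    PairCache pc;
    mat Hp;
    cube dV;
    if (has_pair) {
      Hp = Hpair_all.cols(offs[r], offs[r] + N - 1);
      cube V = pairwise_head_forward(Hp, p, cfg, dropout, pc);
      mat zero_nodes(L, N, fill::zeros);
      mat dzn(L, N); dV.set_size(L, L, N - 1);
      nll_p[s] = crf_nll_grad(zero_nodes, V, ys[s], dzn, dV, want_grad);
    } else {
      nll_p[s] = std::log((double)L);       // edges-only chain, N = 1: uniform
    }

    if (!want_grad) continue;
    for (uword e = 0; e + 1 < N; ++e) g.A += dAedges.slice(e);
    dHu_all.cols(offs[r], offs[r] + N - 1) +=
      unary_head_backward(dU, p, dropout, uc, g);
    if (has_pair) {
      mat dHp = pairwise_head_backward(dV, Hp, p, cfg, dropout, pc, g);
      if (cfg.share_bilstm)
        dHu_all.cols(offs[r], offs[r] + N - 1) += dHp;
      else
        dHp_all.cols(offs[r], offs[r] + N - 1) += dHp;
    }
  }

  if (want_grad) {
    mat dX = bilstm_backward(Xcat, lens, offs, p.u_fw_W, p.u_fw_U,
                             p.u_bw_W, p.u_bw_U, ub, dHu_all,
                             g.u_fw_W, g.u_fw_U, g.u_fw_b,
                             g.u_bw_W, g.u_bw_U, g.u_bw_b);
    if (!cfg.share_bilstm)
      dX += bilstm_backward(Xcat, lens, offs, p.p_fw_W, p.p_fw_U,
                            p.p_bw_W, p.p_bw_U, pb, dHp_all,
                            g.p_fw_W, g.p_fw_U, g.p_fw_b,
                            g.p_bw_W, g.p_bw_U, g.p_bw_b);
    for (uword r = 0; r < B; ++r)
      embed_backward(dX.cols(offs[r], offs[r] + lens[r] - 1),
                     ids[order[r]], p, cfg, ln[r], g);
  }

  return Rcpp::List::create(
    Rcpp::Named("nll_u") = nll_u,
    Rcpp::Named("nll_p") = nll_p,
    Rcpp::Named("grads") = want_grad ? g.as_list(cfg) : Rcpp::List());
}

// Node and edge potentials of one sentence (no dropout).
// Returns U as N x L and V as an L x L x (N-1) cube (previous label = row).
// [[Rcpp::export]]
Rcpp::List cpp_potentials(Rcpp::IntegerVector ids_r, Rcpp::RObject ctx_r,
                          Rcpp::List params, Rcpp::List config) {
  Config cfg = read_config(config);
  Params p = read_params(params, cfg);
  uvec ids = Rcpp::as<uvec>(ids_r) - 1;
  mat ctx;
  if (!ctx_r.isNULL()) ctx = Rcpp::as<mat>(ctx_r);
  const uword N = ids.n_elem, L = cfg.L;
  LnCache ln;
  mat X = embed_forward(ids, ctx, p, cfg, ln);
  uvec lens(1); lens[0] = N;
  uvec offs(1); offs[0] = 0;
  BiCache ub;
  mat Hu = bilstm_forward(X, lens, offs, p.u_fw_W, p.u_fw_U, p.u_fw_b,
                          p.u_bw_W, p.u_bw_U, p.u_bw_b, ub);
  UnaryCache uc;
  mat U = unary_head_forward(Hu, p, cfg, false, uc);
  cube V(L, L, 0);
  if (N >= 2) {
    mat Hp;
    if (cfg.share_bilstm) {
      Hp = Hu;
    } else {
      BiCache pb;
      Hp = bilstm_forward(X, lens, offs, p.p_fw_W, p.p_fw_U, p.p_fw_b,
                          p.p_bw_W, p.p_bw_U, p.p_bw_b, pb);
    }
    PairCache pc;
    V = pairwise_head_forward(Hp, p, cfg, false, pc);
  }
  return Rcpp::List::create(Rcpp::Named("U") = U.t(),
                            Rcpp::Named("V") = V);
}

// Viterbi over nodes (L x N) + edges (L x L x (N-1)); lowest-index tie-break.
// [[Rcpp::export]]
Rcpp::List cpp_viterbi(const arma::mat& nodes, const arma::cube& edges) {
  const uword L = nodes.n_rows, N = nodes.n_cols;
  mat delta(L, N);
  umat back(L, N, fill::zeros);
  delta.col(0) = nodes.col(0);
  for (uword i = 1; i < N; ++i) {
    for (uword k = 0; k < L; ++k) {
      double best = -datum::inf; uword bj = 0;
      for (uword j = 0; j < L; ++j) {
        double v = delta(j, i - 1) + edges(j, k, i - 1);
        if (v > best) { best = v; bj = j; }   // strict > keeps the lowest j
      }
      delta(k, i) = nodes(k, i) + best;
      back(k, i) = bj;
    }
  }
  uword yN = delta.col(N - 1).index_max();    // first (lowest) maximum
  ivec y(N);
  y[N - 1] = yN;
  for (uword s = 1; s < N; ++s) {
    uword i = N - 1 - s;
    y[i] = back(y[i + 1], i + 1);
  }
  Rcpp::IntegerVector labels(N);
  for (uword i = 0; i < N; ++i) labels[i] = y[i] + 1;
  return Rcpp::List::create(Rcpp::Named("labels") = labels,
                            Rcpp::Named("score") = delta(yN, N - 1));
}

// Forward-algorithm log-partition over generic potentials.
// [[Rcpp::export]]
double cpp_log_partition(const arma::mat& nodes, const arma::cube& edges) {
  const uword L = nodes.n_rows, N = nodes.n_cols;
  vec alpha = nodes.col(0);
  for (uword i = 1; i < N; ++i) {
    mat tmp = edges.slice(i - 1);
    tmp.each_col() += alpha;
    vec nxt(L);
    for (uword k = 0; k < L; ++k) nxt[k] = lse(tmp.col(k));
    alpha = nodes.col(i) + nxt;
  }
  return lse(alpha);
}

// Fused gradient clipping + Adam update.  Updates (copies of) params, m, v
// for every array named in grads and returns them with the post-clip norm.
// [[Rcpp::export]]
Rcpp::List cpp_adam_step(Rcpp::List params, Rcpp::List grads,
                         Rcpp::List m, Rcpp::List v, int t, double lr,
                         double clip_norm, double beta1, double beta2,
                         double eps) {
  Rcpp::CharacterVector names = grads.names();
  const int K = names.size();
  double sq = 0.0;
  for (int i = 0; i < K; ++i) {
    Rcpp::NumericVector g(grads[i]);
    for (double x : g) {
      if (!std::isfinite(x))
        Rcpp::stop("non-finite gradient in parameter %s",
                   std::string(names[i]).c_str());
      sq += x * x;
    }
  }
  double norm = std::sqrt(sq);
  double scale = (norm > clip_norm) ? clip_norm / norm : 1.0;
  double c1 = 1.0 - std::pow(beta1, t), c2 = 1.0 - std::pow(beta2, t);
  Rcpp::List pout = Rcpp::clone(params), mout = Rcpp::clone(m),
             vout = Rcpp::clone(v);
  for (int i = 0; i < K; ++i) {
    std::string nm = Rcpp::as<std::string>(names[i]);
    Rcpp::NumericVector g(grads[i]);
    Rcpp::NumericVector pv(pout[nm]), mv(mout[nm]), vv(vout[nm]);
    const int n = g.size();
    for (int j = 0; j < n; ++j) {
      double gj = g[j] * scale;
      mv[j] = beta1 * mv[j] + (1.0 - beta1) * gj;
      vv[j] = beta2 * vv[j] + (1.0 - beta2) * gj * gj;
      pv[j] -= lr * (mv[j] / c1) / (std::sqrt(vv[j] / c2) + eps);
    }
  }
  return Rcpp::List::create(Rcpp::Named("params") = pout,
                            Rcpp::Named("m") = mout,
                            Rcpp::Named("v") = vout,
                            Rcpp::Named("grad_norm") = norm);
}
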