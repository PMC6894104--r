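// BiLSTM-CRF forward/backward core and in-place SGD epoch driver.
//
// Layout conventions:
//  - parameter list `params` holds matrices named as in R/model.R
//  - LSTM gate blocks are stacked [input; forget; cell; output] along rows
//  - CRF transition matrix is (K+2)x(K+2); row = from, col = to;
//    index K (0-based) is the start state, K+1 the stop state
//  - all token / tag / vocabulary indices arriving from R are 1-based
//  - cpp_train_epoch mutates the parameter and velocity matrices in place;
//    the R caller owns (and has duplicated) them

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline vec sigm(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

static inline double logsumexp_vec(const vec& x) {
  double m = x.max();
  return m + std::log(accu(exp(x - m)));
}

struct LSTMCache { mat I, F, G, O, C, H; };

// One directional pass. `rev` processes t = T-1 .. 0. The input projection
// W*X is computed as a single product; only the recurrence runs per step.
static void lstm_fwd(const mat& W, const mat& U, const vec& b,
                     const mat& X, bool rev, LSTMCache& cc) {
  const uword T = X.n_cols, H = U.n_cols;
  cc.I.set_size(H, T); cc.F.set_size(H, T); cc.G.set_size(H, T);
  cc.O.set_size(H, T); cc.C.set_size(H, T); cc.H.set_size(H, T);
  mat ZW = W * X;
  ZW.each_col() += b;
  vec h(H, fill::zeros), c(H, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    uword t = rev ? (T - 1 - s) : s;
    vec z = ZW.col(t) + U * h;
    vec i = sigm(z.subvec(0, H - 1));
    vec f = sigm(z.subvec(H, 2 * H - 1));
    vec g = tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = sigm(z.subvec(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    cc.I.col(t) = i; cc.F.col(t) = f; cc.G.col(t) = g;
    cc.O.col(t) = o; cc.C.col(t) = c; cc.H.col(t) = h;
  }
}

// BPTT for one direction; returns dX and accumulates dW/dU/db. The
// per-step work is only the recurrent part; weight gradients and dX come
// from single products over the accumulated gate deltas.
static mat lstm_bwd(const mat& W, const mat& U, const mat& X, bool rev,
                    const LSTMCache& cc, const mat& dH_in,
                    mat& dW, mat& dU, vec& db) {
  const uword T = X.n_cols, H = U.n_cols;
  mat dZ(4 * H, T);
  vec dh_carry(H, fill::zeros), dc(H, fill::zeros);
  for (uword s = T; s-- > 0;) {
    uword t = rev ? (T - 1 - s) : s;
    bool has_prev = (s > 0);
    uword tp = rev ? (t + 1) : (t - 1);
    vec dh = dH_in.col(t) + dh_carry;
    vec tc = tanh(cc.C.col(t));
    dc += dh % cc.O.col(t) % (1.0 - tc % tc);
    dZ.col(t).subvec(0, H - 1) =
        (dc % cc.G.col(t)) % cc.I.col(t) % (1.0 - cc.I.col(t));
    dZ.col(t).subvec(H, 2 * H - 1) = has_prev
        ? vec((dc % cc.C.col(tp)) % cc.F.col(t) % (1.0 - cc.F.col(t)))
        : vec(H, fill::zeros);
    dZ.col(t).subvec(2 * H, 3 * H - 1) =
        (dc % cc.I.col(t)) % (1.0 - cc.G.col(t) % cc.G.col(t));
    dZ.col(t).subvec(3 * H, 4 * H - 1) =
        (dh % tc) % cc.O.col(t) % (1.0 - cc.O.col(t));
    if (has_prev) dU += dZ.col(t) * cc.H.col(tp).t();
    dh_carry = U.t() * dZ.col(t);
    dc = dc % cc.F.col(t);
  }
  dW += dZ * X.t();
  db += sum(dZ, 1);
  return W.t() * dZ;
}

// Linear-chain CRF negative log-likelihood and, optionally, gradients
// w.r.t. emissions and transitions (forward-backward marginals).
static double crf_core(const mat& em, const mat& trans, const ivec& tags,
                       bool want_grad, mat& dem, mat& dtr) {
  const int T = em.n_rows, K = em.n_cols, S = K, E = K + 1;
  const mat core = trans.submat(0, 0, K - 1, K - 1);
  mat alpha(T, K);
  alpha.row(0) = trans.row(S).subvec(0, K - 1) + em.row(0);
  for (int t = 1; t < T; ++t) {
    mat Z = core;
    Z.each_col() += alpha.row(t - 1).t();
    rowvec m = max(Z, 0);
    alpha.row(t) = m + log(sum(exp(Z.each_row() - m), 0)) + em.row(t);
  }
  vec last = alpha.row(T - 1).t() + trans.col(E).subvec(0, K - 1);
  double logZ = logsumexp_vec(last);
  double gold = trans(S, tags(0) - 1);
  for (int t = 0; t < T; ++t) {
    gold += em(t, tags(t) - 1);
    if (t > 0) gold += trans(tags(t - 1) - 1, tags(t) - 1);
  }
  gold += trans(tags(T - 1) - 1, E);
  double nll = logZ - gold;
  if (!want_grad) return nll;

  mat beta(T, K);
  beta.row(T - 1) = trans.col(E).subvec(0, K - 1).t();
  for (int t = T - 2; t >= 0; --t) {
    mat Z = core;
    Z.each_row() += em.row(t + 1) + beta.row(t + 1);
    vec m = max(Z, 1);
    beta.row(t) = (m + log(sum(exp(Z.each_col() - m), 1))).t();
  }
  dem = exp(alpha + beta - logZ);
  for (int t = 0; t < T; ++t) dem(t, tags(t) - 1) -= 1.0;
  dtr.zeros(K + 2, K + 2);
  dtr.row(S).subvec(0, K - 1) = exp(alpha.row(0) + beta.row(0) - logZ);
  dtr.col(E).subvec(0, K - 1) =
      exp(alpha.row(T - 1).t() + trans.col(E).subvec(0, K - 1) - logZ);
  dtr(S, tags(0) - 1) -= 1.0;
  dtr(tags(T - 1) - 1, E) -= 1.0;
  for (int t = 0; t < T - 1; ++t) {
    mat P = core;
    P.each_col() += alpha.row(t).t();
    P.each_row() += em.row(t + 1) + beta.row(t + 1);
    dtr.submat(0, 0, K - 1, K - 1) += exp(P - logZ);
  }
  for (int t = 1; t < T; ++t) dtr(tags(t - 1) - 1, tags(t) - 1) -= 1.0;
  return nll;
}

// [[Rcpp::export]]
List cpp_crf_nll(const arma::mat& emissions, const arma::mat& trans,
                 const arma::ivec& tags, bool want_grad) {
  if ((int)trans.n_rows != (int)emissions.n_cols + 2 ||
      trans.n_rows != trans.n_cols)
    stop("transition matrix must be (K+2) x (K+2)");
  if ((int)tags.n_elem != (int)emissions.n_rows)
    stop("tags length must equal number of emission rows");
  for (uword t = 0; t < tags.n_elem; ++t)
    if (tags(t) < 1 || tags(t) > (sword)emissions.n_cols)
      stop("tag index out of range at position %d", (int)t + 1);
  mat dem, dtr;
  double nll = crf_core(emissions, trans, tags, want_grad, dem, dtr);
  if (!want_grad) return List::create(_["nll"] = nll);
  return List::create(_["nll"] = nll, _["d_emissions"] = dem,
                      _["d_trans"] = dtr);
}

// Max-score decoding with suffix scores, emitting the lexicographically
// smallest tag-index path among the ties.
// [[Rcpp::export]]
List cpp_viterbi(const arma::mat& emissions, const arma::mat& trans) {
  const int T = emissions.n_rows, K = emissions.n_cols, S = K, E = K + 1;
  if ((int)trans.n_rows != K + 2 || trans.n_rows != trans.n_cols)
    stop("transition matrix must be (K+2) x (K+2)");
  if (T == 0)
    return List::create(_["path"] = IntegerVector(0), _["score"] = 0.0);
  mat omega(T, K);  // best score of any completion starting at (t, k)
  for (int k = 0; k < K; ++k)
    omega(T - 1, k) = emissions(T - 1, k) + trans(k, E);
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double best = -datum::inf;
      for (int j = 0; j < K; ++j) {
        double v = trans(k, j) + omega(t + 1, j);
        if (v > best) best = v;
      }
      omega(t, k) = emissions(t, k) + best;
    }
  }
  IntegerVector path(T);
  double best = -datum::inf;
  int arg = 0;
  for (int k = 0; k < K; ++k) {
    double v = trans(S, k) + omega(0, k);
    if (v > best) { best = v; arg = k; }
  }
  path[0] = arg + 1;
  double score = best;
  for (int t = 1; t < T; ++t) {
    int p = path[t - 1] - 1;
    double bb = -datum::inf;
    int a = 0;
    for (int k = 0; k < K; ++k) {
      double v = trans(p, k) + omega(t, k);
      if (v > bb) { bb = v; a = k; }
    }
    path[t] = a + 1;
  }
  return List::create(_["path"] = path, _["score"] = score);
}

// --- parameter views -------------------------------------------------------

// Non-copying armadillo views onto the R matrices of the parameter list.
struct PView {
  mat Eword, Echar;
  std::vector<mat> Efeat;
  mat cfW, cfU, cbW, cbU, wfW, wfU, wbW, wbU, outW, trans;
  vec cfb, cbb, wfb, wbb, outb;
};

static mat view_mat(SEXP x) {
  NumericMatrix m(x);
  return mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
static vec view_vec(SEXP x) {
  NumericVector v(x);
  return vec(v.begin(), v.size(), false, true);
}

static PView make_view(List params) {
  PView p;
  p.Eword = view_mat(params["Eword"]);
  p.Echar = view_mat(params["Echar"]);
  List ef = params["Efeat"];
  for (int k = 0; k < ef.size(); ++k) p.Efeat.push_back(view_mat(ef[k]));
  p.cfW = view_mat(params["cfW"]); p.cfU = view_mat(params["cfU"]);
  p.cbW = view_mat(params["cbW"]); p.cbU = view_mat(params["cbU"]);
  p.wfW = view_mat(params["wfW"]); p.wfU = view_mat(params["wfU"]);
  p.wbW = view_mat(params["wbW"]); p.wbU = view_mat(params["wbU"]);
  p.outW = view_mat(params["outW"]); p.trans = view_mat(params["trans"]);
  p.cfb = view_vec(params["cfb"]); p.cbb = view_vec(params["cbb"]);
  p.wfb = view_vec(params["wfb"]); p.wbb = view_vec(params["wbb"]);
  p.outb = view_vec(params["outb"]);
  return p;
}

// Dense gradients of one sentence plus sparse embedding-row gradients.
struct SparseGrad {
  std::unordered_map<int, int> slot;  // 1-based row id -> local column
  mat G;                              // dim x n_used
  int used = 0;
  void init(int dim, int cap) { G.zeros(dim, cap); used = 0; slot.clear(); }
  void add(int id, const vec& g) {
    auto it = slot.find(id);
    int c;
    if (it == slot.end()) { c = used++; slot[id] = c; } else c = it->second;
    G.col(c) += g;
  }
};

struct Grads {
  SparseGrad Eword, Echar;
  std::vector<SparseGrad> Efeat;
  mat cfW, cfU, cbW, cbU, wfW, wfU, wbW, wbU, outW, trans;
  vec cfb, cbb, wfb, wbb, outb;
};

struct Sent {
  ivec word_ids;                 // 1-based
  std::vector<ivec> char_ids;    // per token, 1-based
  imat feat_ids;                 // T x n_streams, 1-based
  ivec tag_ids;                  // 1-based, may be empty
};

static Sent unpack_sent(const IntegerVector& word_ids, List char_ids,
                        const IntegerMatrix& feat_ids,
                        const IntegerVector& tag_ids) {
  Sent s;
  const int T = word_ids.size();
  s.word_ids.set_size(T);
  for (int t = 0; t < T; ++t) s.word_ids(t) = word_ids[t];
  s.char_ids.resize(T);
  for (int t = 0; t < T; ++t) {
    IntegerVector cid = char_ids[t];
    ivec cc(cid.size());
    for (int c = 0; c < cid.size(); ++c) cc(c) = cid[c];
    s.char_ids[t] = cc;
  }
  s.feat_ids.set_size(feat_ids.nrow(), feat_ids.ncol());
  for (int i = 0; i < feat_ids.nrow(); ++i)
    for (int j = 0; j < feat_ids.ncol(); ++j)
      s.feat_ids(i, j) = feat_ids(i, j);
  s.tag_ids.set_size(tag_ids.size());
  for (int t = 0; t < tag_ids.size(); ++t) s.tag_ids(t) = tag_ids[t];
  return s;
}

// Full forward (and optionally backward) pass over one sentence.
// Returns the CRF negative log-likelihood (0 when tags are absent);
// emissions are written to `emissions_out`.
static double sentence_pass(const PView& p, const Sent& s, const mat& mask,
                            bool have_mask, bool want_grad, Grads* gr,
                            mat& emissions_out) {
  const int T = s.word_ids.n_elem;
  if (T == 0) stop("empty sentence");
  const int dw = p.Eword.n_cols, Hc = p.cfU.n_cols;
  const int nf = p.Efeat.size();
  if ((int)s.feat_ids.n_cols != nf) stop("feature stream count mismatch");
  int dfsum = 0;
  for (int k = 0; k < nf; ++k) dfsum += p.Efeat[k].n_cols;
  const int D = dw + 2 * Hc + dfsum;

  std::vector<mat> Xc(T);
  std::vector<LSTMCache> ccf(T), ccb(T);
  mat X0(D, T);
  for (int t = 0; t < T; ++t) {
    int wid = s.word_ids(t);
    if (wid < 1 || wid > (int)p.Eword.n_rows) stop("word id out of range");
    const ivec& cid = s.char_ids[t];
    int Tc = cid.n_elem;
    if (Tc == 0) stop("token with no characters");
    mat Xci(p.Echar.n_cols, Tc);
    for (int c = 0; c < Tc; ++c) {
      int id = cid(c);
      if (id < 1 || id > (int)p.Echar.n_rows) stop("char id out of range");
      Xci.col(c) = p.Echar.row(id - 1).t();
    }
    Xc[t] = Xci;
    lstm_fwd(p.cfW, p.cfU, p.cfb, Xci, false, ccf[t]);
    lstm_fwd(p.cbW, p.cbU, p.cbb, Xci, true, ccb[t]);
    vec x(D);
    x.subvec(0, dw - 1) = p.Eword.row(wid - 1).t();
    x.subvec(dw, dw + Hc - 1) = ccf[t].H.col(Tc - 1);
    x.subvec(dw + Hc, dw + 2 * Hc - 1) = ccb[t].H.col(0);
    int off = dw + 2 * Hc;
    for (int k = 0; k < nf; ++k) {
      int fid = s.feat_ids(t, k);
      if (fid < 1 || fid > (int)p.Efeat[k].n_rows)
        stop("feature id out of range");
      int dk = p.Efeat[k].n_cols;
      x.subvec(off, off + dk - 1) = p.Efeat[k].row(fid - 1).t();
      off += dk;
    }
    X0.col(t) = x;
  }
  if (have_mask && ((int)mask.n_rows != D || (int)mask.n_cols != T))
    stop("dropout mask must be input_width x T");
  mat X = have_mask ? mat(X0 % mask) : X0;

  LSTMCache wf, wb;
  lstm_fwd(p.wfW, p.wfU, p.wfb, X, false, wf);
  lstm_fwd(p.wbW, p.wbU, p.wbb, X, true, wb);
  mat Hw = join_cols(wf.H, wb.H);  // 2Hw x T
  mat emT = p.outW * Hw;           // K x T
  emT.each_col() += p.outb;
  emissions_out = emT.t();         // T x K

  if (s.tag_ids.n_elem == 0) return 0.0;
  if ((int)s.tag_ids.n_elem != T) stop("tag length mismatch");
  mat dem, dtr;
  double nll = crf_core(emissions_out, p.trans, s.tag_ids, want_grad, dem,
                        dtr);
  if (!want_grad) return nll;

  Grads& g = *gr;
  g.trans = dtr;
  mat demT = dem.t();  // K x T
  g.outW = demT * Hw.t();
  g.outb = sum(demT, 1);
  mat dHw = p.outW.t() * demT;
  const int Hwn = p.wfU.n_cols;
  mat dHf = dHw.rows(0, Hwn - 1), dHb = dHw.rows(Hwn, 2 * Hwn - 1);

  g.wfW.zeros(size(p.wfW)); g.wfU.zeros(size(p.wfU));
  g.wfb.zeros(p.wfb.n_elem);
  g.wbW.zeros(size(p.wbW)); g.wbU.zeros(size(p.wbU));
  g.wbb.zeros(p.wbb.n_elem);
  mat dX = lstm_bwd(p.wfW, p.wfU, X, false, wf, dHf, g.wfW, g.wfU, g.wfb) +
           lstm_bwd(p.wbW, p.wbU, X, true, wb, dHb, g.wbW, g.wbU, g.wbb);
  if (have_mask) dX = dX % mask;

  g.Eword.init(dw, T);
  int ncharTotal = 0;
  for (int t = 0; t < T; ++t) ncharTotal += Xc[t].n_cols;
  g.Echar.init(p.Echar.n_cols, ncharTotal);
  g.Efeat.resize(nf);
  for (int k = 0; k < nf; ++k) g.Efeat[k].init(p.Efeat[k].n_cols, T);

  g.cfW.zeros(size(p.cfW)); g.cfU.zeros(size(p.cfU));
  g.cfb.zeros(p.cfb.n_elem);
  g.cbW.zeros(size(p.cbW)); g.cbU.zeros(size(p.cbU));
  g.cbb.zeros(p.cbb.n_elem);

  for (int t = 0; t < T; ++t) {
    g.Eword.add(s.word_ids(t), dX.col(t).subvec(0, dw - 1));
    int Tc = Xc[t].n_cols;
    mat dHfc(Hc, Tc, fill::zeros), dHbc(Hc, Tc, fill::zeros);
    dHfc.col(Tc - 1) = dX.col(t).subvec(dw, dw + Hc - 1);
    dHbc.col(0) = dX.col(t).subvec(dw + Hc, dw + 2 * Hc - 1);
    mat dXc = lstm_bwd(p.cfW, p.cfU, Xc[t], false, ccf[t], dHfc, g.cfW,
                       g.cfU, g.cfb) +
              lstm_bwd(p.cbW, p.cbU, Xc[t], true, ccb[t], dHbc, g.cbW,
                       g.cbU, g.cbb);
    const ivec& cid = s.char_ids[t];
    for (int c = 0; c < Tc; ++c) g.Echar.add(cid(c), dXc.col(c));
    int off = dw + 2 * Hc;
    for (int k = 0; k < nf; ++k) {
      int dk = p.Efeat[k].n_cols;
      g.Efeat[k].add(s.feat_ids(t, k), dX.col(t).subvec(off, off + dk - 1));
      off += dk;
    }
  }
  return nll;
}

static List pack_sparse(const SparseGrad& sg) {
  IntegerVector rows(sg.used);
  mat out(sg.G.n_rows, sg.used);
  for (auto& kv : sg.slot) {
    rows[kv.second] = kv.first;
    out.col(kv.second) = sg.G.col(kv.second);
  }
  return List::create(_["rows"] = rows, _["grad"] = out.t());
}

// Single-sentence entry point (prediction, tests, gradient checks).
// [[Rcpp::export]]
List cpp_sentence(List params, const IntegerVector& word_ids, List char_ids,
                  const IntegerMatrix& feat_ids, const IntegerVector& tag_ids,
                  const NumericMatrix& drop_mask, bool want_grad) {
  PView p = make_view(params);
  Sent s = unpack_sent(word_ids, char_ids, feat_ids, tag_ids);
  bool have_mask = drop_mask.nrow() > 0;
  mat mask;
  if (have_mask)
    mask = mat(const_cast<double*>(drop_mask.begin()), drop_mask.nrow(),
               drop_mask.ncol(), false, true);
  mat emissions;
  if (s.tag_ids.n_elem == 0) {
    sentence_pass(p, s, mask, have_mask, false, nullptr, emissions);
    return List::create(_["emissions"] = emissions);
  }
  if (!want_grad) {
    double nll = sentence_pass(p, s, mask, have_mask, false, nullptr,
                               emissions);
    return List::create(_["loss"] = nll, _["emissions"] = emissions);
  }
  Grads g;
  double nll = sentence_pass(p, s, mask, have_mask, true, &g, emissions);
  List gfeat(g.Efeat.size());
  for (size_t k = 0; k < g.Efeat.size(); ++k) gfeat[k] = pack_sparse(g.Efeat[k]);
  List grads = List::create(
      _["Eword"] = pack_sparse(g.Eword), _["Echar"] = pack_sparse(g.Echar),
      _["Efeat"] = gfeat,
      _["cfW"] = g.cfW, _["cfU"] = g.cfU, _["cfb"] = g.cfb,
      _["cbW"] = g.cbW, _["cbU"] = g.cbU, _["cbb"] = g.cbb,
      _["wfW"] = g.wfW, _["wfU"] = g.wfU, _["wfb"] = g.wfb,
      _["wbW"] = g.wbW, _["wbU"] = g.wbU, _["wbb"] = g.wbb,
      _["outW"] = g.outW, _["outb"] = g.outb, _["trans"] = g.trans);
  return List::create(_["loss"] = nll, _["emissions"] = emissions,
                      _["grads"] = grads);
}

static inline void clip_inplace(mat& g, double lo, double hi) {
  g.clamp(lo, hi);
}
static inline void clip_inplace(vec& g, double lo, double hi) {
  g.clamp(lo, hi);
}

static void sgd_dense(mat& P, mat& V, mat& G, double lr, double mom,
                      double lo, double hi) {
  clip_inplace(G, lo, hi);
  V = mom * V + G;
  P -= lr * V;
}
static void sgd_dense(vec& P, vec& V, vec& G, double lr, double mom,
                      double lo, double hi) {
  clip_inplace(G, lo, hi);
  V = mom * V + G;
  P -= lr * V;
}
// Lazy momentum on embedding rows: velocity advances only when touched.
static void sgd_sparse(mat& P, mat& V, const SparseGrad& sg, double lr,
                       double mom, double lo, double hi) {
  for (auto& kv : sg.slot) {
    int r = kv.first - 1;
    vec g = sg.G.col(kv.second);
    g.clamp(lo, hi);
    V.row(r) = mom * V.row(r) + g.t();
    P.row(r) -= lr * V.row(r);
  }
}

// One SGD epoch with per-sentence updates, performed in place on the
// parameter and velocity matrices. `order` is the (seeded, R-side) visit
// order; `masks` holds one inverted-dropout mask per sentence (or empty
// matrices when dropout is off). Returns the summed sentence NLL.
// [[Rcpp::export]]
double cpp_train_epoch(List params, List vel, List sentences,
                       const IntegerVector& order, List masks, double lr,
                       double mom, double clip_lo, double clip_hi) {
  PView p = make_view(params);
  PView v = make_view(vel);
  double total = 0.0;
  Grads g;
  mat emissions;
  for (int oi = 0; oi < order.size(); ++oi) {
    int si = order[oi] - 1;
    List sl = sentences[si];
    Sent s = unpack_sent(sl["word_ids"], sl["char_ids"], sl["feat_ids"],
                         sl["tag_ids"]);
    NumericMatrix mk = masks[si];
    bool have_mask = mk.nrow() > 0;
    mat mask;
    if (have_mask)
      mask = mat(mk.begin(), mk.nrow(), mk.ncol(), false, true);
    double nll = sentence_pass(p, s, mask, have_mask, true, &g, emissions);
    if (!std::isfinite(nll))
      stop("non-finite sentence loss during training");
    total += nll;
    sgd_dense(p.cfW, v.cfW, g.cfW, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.cfU, v.cfU, g.cfU, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.cfb, v.cfb, g.cfb, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.cbW, v.cbW, g.cbW, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.cbU, v.cbU, g.cbU, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.cbb, v.cbb, g.cbb, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.wfW, v.wfW, g.wfW, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.wfU, v.wfU, g.wfU, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.wfb, v.wfb, g.wfb, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.wbW, v.wbW, g.wbW, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.wbU, v.wbU, g.wbU, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.wbb, v.wbb, g.wbb, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.outW, v.outW, g.outW, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.outb, v.outb, g.outb, lr, mom, clip_lo, clip_hi);
    sgd_dense(p.trans, v.trans, g.trans, lr, mom, clip_lo, clip_hi);
    sgd_sparse(p.Eword, v.Eword, g.Eword, lr, mom, clip_lo, clip_hi);
    sgd_sparse(p.Echar, v.Echar, g.Echar, lr, mom, clip_lo, clip_hi);
    for (size_t k = 0; k < g.Efeat.size(); ++k)
      sgd_sparse(p.Efeat[k], v.Efeat[k], g.Efeat[k], lr, mom, clip_lo,
                 clip_hi);
  }
  return total;
}

// Batch decoding: emissions + Viterbi for a list of sentences, returning
// the 1-based tag path per sentence.
// [[Rcpp::export]]
List cpp_predict_batch(List params, List sentences) {
  PView p = make_view(params);
  List out(sentences.size());
  mat emissions;
  mat nomask;
  for (int i = 0; i < sentences.size(); ++i) {
    List sl = sentences[i];
    Sent s = unpack_sent(sl["word_ids"], sl["char_ids"], sl["feat_ids"],
                         IntegerVector(0));
    sentence_pass(p, s, nomask, false, false, nullptr, emissions);
    out[i] = cpp_viterbi(emissions, p.trans)["path"];
  }
  return out;
}
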