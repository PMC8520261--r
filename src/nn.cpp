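// Deep multi-head attention network for piRNA target identification.
//
// Dense compute core: forward pass, analytic backward pass and Adam training
// loop for the three sub-networks (conv + squeeze-excitation motif
// extraction, site-by-site multi-head attention with a residual feed-forward
// block, fully connected classifier). Parameters travel as a named R list of
// matrices/vectors; sequences arrive 0-based integer encoded (A=0, U=1,
// G=2, C=3), one row per example.
//
// Layers are templated on the element type: the training loop and batched
// forward run in single precision (the throughput-critical path), while the
// exported component-level operations run in double precision so they can be
// compared against reference implementations at tight tolerances.
//
// Conventions: matrices are (positions x channels) for sequence features and
// (out x in) for fully connected weights, applied as X * W^T + b.
// Batch feature tensors are stacked row blocks: example b occupies rows
// [b*L, (b+1)*L) of a (B*L x F) matrix.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double BN_EPS = 1e-5;
static const double LN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

struct Cfg {
  int Lp, Lm, F, ks, red, heads, hd, ffh, fc1, fc2;
  double d_scale;        // softmax scale divisor sqrt(d), d = piRNA length
  double p_se, p_attn, p_cls;
  bool pure_cnn;
  // the pure-CNN ablation rejoins the pooled piRNA features at the second
  // fully connected layer, keeping the ablation a two-input classifier while
  // staying strictly smaller than the attention model
  int fc2_in() const { return fc1 + (pure_cnn ? F : 0); }
};

static Cfg cfg_from_list(const Rcpp::List& cl) {
  Cfg c;
  c.Lp = Rcpp::as<int>(cl["pirna_len"]);
  c.Lm = Rcpp::as<int>(cl["mrna_len"]);
  c.F = Rcpp::as<int>(cl["n_filters"]);
  c.ks = Rcpp::as<int>(cl["kernel_size"]);
  c.red = Rcpp::as<int>(cl["se_reduction"]);
  c.heads = Rcpp::as<int>(cl["n_heads"]);
  c.hd = c.F / c.heads;
  c.ffh = Rcpp::as<int>(cl["ff_hidden"]);
  c.fc1 = Rcpp::as<int>(cl["fc1_width"]);
  c.fc2 = Rcpp::as<int>(cl["fc2_width"]);
  c.d_scale = std::sqrt(Rcpp::as<double>(cl["attn_scale_d"]));
  c.p_se = Rcpp::as<double>(cl["dropout_se"]);
  c.p_attn = Rcpp::as<double>(cl["dropout_attn"]);
  c.p_cls = Rcpp::as<double>(cl["dropout_cls"]);
  c.pure_cnn = Rcpp::as<bool>(cl["pure_cnn"]);
  if (c.F % c.heads != 0) Rcpp::stop("n_filters must be divisible by n_heads");
  return c;
}

// fast RNG for dropout masks (xorshift64*; quality is ample for masking)
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed * 2685821657736338717ULL + 1442695040888963407ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  double u() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// ---------------------------------------------------------------------------
// parameter bundle

template <typename eT>
struct ParamsT {
  Mat<eT> convW[2]; Col<eT> convB[2];
  Col<eT> bnG[2], bnB[2], bnM[2], bnV[2];
  Col<eT> prelu[2];
  Mat<eT> seW1[2]; Col<eT> seB1[2]; Mat<eT> seW2[2]; Col<eT> seB2[2];
  Mat<eT> Wq, Wk, Wv, Wh; Col<eT> bh;
  Col<eT> ln1G, ln1B;
  Mat<eT> ffW1; Col<eT> ffB1, ffPr1; Mat<eT> ffW2; Col<eT> ffB2, ffPr2;
  Col<eT> ln2G, ln2B;
  Mat<eT> cW1; Col<eT> cB1, cbn1G, cbn1B, cbn1M, cbn1V, cPr1;
  Mat<eT> cW2; Col<eT> cB2, cbn2G, cbn2B, cbn2M, cbn2V, cPr2;
  Mat<eT> cW3; Col<eT> cB3;
};

template <typename eT>
static Mat<eT> getm(const Rcpp::List& l, const std::string& nm) {
  if (!l.containsElementNamed(nm.c_str()))
    Rcpp::stop("missing parameter: " + nm);
  return conv_to<Mat<eT>>::from(Rcpp::as<mat>(l[nm]));
}
template <typename eT>
static Col<eT> getv(const Rcpp::List& l, const std::string& nm) {
  if (!l.containsElementNamed(nm.c_str()))
    Rcpp::stop("missing parameter: " + nm);
  return conv_to<Col<eT>>::from(Rcpp::as<vec>(l[nm]));
}

template <typename eT>
static ParamsT<eT> params_from_list(const Rcpp::List& l, const Cfg& c) {
  ParamsT<eT> p;
  const char* br[2] = {"pi", "mr"};
  for (int i = 0; i < 2; ++i) {
    std::string b(br[i]);
    p.convW[i] = getm<eT>(l, b + "_conv_W");
    p.convB[i] = getv<eT>(l, b + "_conv_b");
    p.bnG[i] = getv<eT>(l, b + "_bn_gamma");
    p.bnB[i] = getv<eT>(l, b + "_bn_beta");
    p.bnM[i] = getv<eT>(l, b + "_bn_rmean");
    p.bnV[i] = getv<eT>(l, b + "_bn_rvar");
    p.prelu[i] = getv<eT>(l, b + "_prelu");
    p.seW1[i] = getm<eT>(l, b + "_se_W1");
    p.seB1[i] = getv<eT>(l, b + "_se_b1");
    p.seW2[i] = getm<eT>(l, b + "_se_W2");
    p.seB2[i] = getv<eT>(l, b + "_se_b2");
  }
  if (!c.pure_cnn) {
    p.Wq = getm<eT>(l, "att_Wq"); p.Wk = getm<eT>(l, "att_Wk");
    p.Wv = getm<eT>(l, "att_Wv"); p.Wh = getm<eT>(l, "att_Wh");
    p.bh = getv<eT>(l, "att_bh");
  }
  p.ln1G = getv<eT>(l, "ln1_gamma"); p.ln1B = getv<eT>(l, "ln1_beta");
  p.ffW1 = getm<eT>(l, "ff_W1"); p.ffB1 = getv<eT>(l, "ff_b1");
  p.ffPr1 = getv<eT>(l, "ff_prelu1");
  p.ffW2 = getm<eT>(l, "ff_W2"); p.ffB2 = getv<eT>(l, "ff_b2");
  p.ffPr2 = getv<eT>(l, "ff_prelu2");
  p.ln2G = getv<eT>(l, "ln2_gamma"); p.ln2B = getv<eT>(l, "ln2_beta");
  p.cW1 = getm<eT>(l, "cls_W1"); p.cB1 = getv<eT>(l, "cls_b1");
  p.cbn1G = getv<eT>(l, "cls_bn1_gamma"); p.cbn1B = getv<eT>(l, "cls_bn1_beta");
  p.cbn1M = getv<eT>(l, "cls_bn1_rmean"); p.cbn1V = getv<eT>(l, "cls_bn1_rvar");
  p.cPr1 = getv<eT>(l, "cls_prelu1");
  p.cW2 = getm<eT>(l, "cls_W2"); p.cB2 = getv<eT>(l, "cls_b2");
  p.cbn2G = getv<eT>(l, "cls_bn2_gamma"); p.cbn2B = getv<eT>(l, "cls_bn2_beta");
  p.cbn2M = getv<eT>(l, "cls_bn2_rmean"); p.cbn2V = getv<eT>(l, "cls_bn2_rvar");
  p.cPr2 = getv<eT>(l, "cls_prelu2");
  p.cW3 = getm<eT>(l, "cls_W3"); p.cB3 = getv<eT>(l, "cls_b3");
  return p;
}

template <typename eT>
static Rcpp::List params_to_list(const ParamsT<eT>& p, const Cfg& c) {
  Rcpp::List l;
  auto wm = [](const Mat<eT>& m) { return Rcpp::wrap(conv_to<mat>::from(m)); };
  auto wv = [](const Col<eT>& v) { return Rcpp::wrap(conv_to<vec>::from(v)); };
  const char* br[2] = {"pi", "mr"};
  for (int i = 0; i < 2; ++i) {
    std::string b(br[i]);
    l[b + "_conv_W"] = wm(p.convW[i]); l[b + "_conv_b"] = wv(p.convB[i]);
    l[b + "_bn_gamma"] = wv(p.bnG[i]); l[b + "_bn_beta"] = wv(p.bnB[i]);
    l[b + "_bn_rmean"] = wv(p.bnM[i]); l[b + "_bn_rvar"] = wv(p.bnV[i]);
    l[b + "_prelu"] = wv(p.prelu[i]);
    l[b + "_se_W1"] = wm(p.seW1[i]); l[b + "_se_b1"] = wv(p.seB1[i]);
    l[b + "_se_W2"] = wm(p.seW2[i]); l[b + "_se_b2"] = wv(p.seB2[i]);
  }
  if (!c.pure_cnn) {
    l["att_Wq"] = wm(p.Wq); l["att_Wk"] = wm(p.Wk); l["att_Wv"] = wm(p.Wv);
    l["att_Wh"] = wm(p.Wh); l["att_bh"] = wv(p.bh);
  }
  l["ln1_gamma"] = wv(p.ln1G); l["ln1_beta"] = wv(p.ln1B);
  l["ff_W1"] = wm(p.ffW1); l["ff_b1"] = wv(p.ffB1); l["ff_prelu1"] = wv(p.ffPr1);
  l["ff_W2"] = wm(p.ffW2); l["ff_b2"] = wv(p.ffB2); l["ff_prelu2"] = wv(p.ffPr2);
  l["ln2_gamma"] = wv(p.ln2G); l["ln2_beta"] = wv(p.ln2B);
  l["cls_W1"] = wm(p.cW1); l["cls_b1"] = wv(p.cB1);
  l["cls_bn1_gamma"] = wv(p.cbn1G); l["cls_bn1_beta"] = wv(p.cbn1B);
  l["cls_bn1_rmean"] = wv(p.cbn1M); l["cls_bn1_rvar"] = wv(p.cbn1V);
  l["cls_prelu1"] = wv(p.cPr1);
  l["cls_W2"] = wm(p.cW2); l["cls_b2"] = wv(p.cB2);
  l["cls_bn2_gamma"] = wv(p.cbn2G); l["cls_bn2_beta"] = wv(p.cbn2B);
  l["cls_bn2_rmean"] = wv(p.cbn2M); l["cls_bn2_rvar"] = wv(p.cbn2V);
  l["cls_prelu2"] = wv(p.cPr2);
  l["cls_W3"] = wm(p.cW3); l["cls_b3"] = wv(p.cB3);
  return l;
}

// ---------------------------------------------------------------------------
// primitive layers (templated on element type)

// zero-padded im2col of a one-hot batch: output (B*L x ks*4), column w*4+r
template <typename eT>
static Mat<eT> onehot_im2col(const imat& S, int ks) {
  const int B = S.n_rows, L = S.n_cols, m = (ks - 1) / 2;
  Mat<eT> X(B * L, ks * 4, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < L; ++j)
      for (int w = 0; w < ks; ++w) {
        int q = j + w - m;
        if (q >= 0 && q < L) X(b * L + j, w * 4 + S(b, q)) = eT(1);
      }
  return X;
}

// generic zero-padded im2col of a real L x 4 encoding (component interface)
template <typename eT>
static Mat<eT> real_im2col(const Mat<eT>& E, int ks) {
  const int L = E.n_rows, m = (ks - 1) / 2;
  Mat<eT> X(L, ks * 4, fill::zeros);
  for (int j = 0; j < L; ++j)
    for (int w = 0; w < ks; ++w) {
      int q = j + w - m;
      if (q >= 0 && q < L)
        for (int r = 0; r < 4; ++r) X(j, w * 4 + r) = E(q, r);
    }
  return X;
}

template <typename eT>
struct BNCache { Mat<eT> xhat; Row<eT> invstd; };

template <typename eT>
static Mat<eT> bn_forward(const Mat<eT>& X, Col<eT>& gamma, Col<eT>& beta,
                          Col<eT>& rmean, Col<eT>& rvar, bool training,
                          BNCache<eT>* cache) {
  const eT N = (eT)X.n_rows;
  Row<eT> mu, var;
  if (training) {
    mu = mean(X, 0);
    Mat<eT> cen = X;
    cen.each_row() -= mu;
    var = mean(square(cen), 0);                     // biased, for normalization
    eT corr = N > 1 ? N / (N - 1) : eT(1);          // unbiased for running stats
    rmean = (eT)(1.0 - BN_MOMENTUM) * rmean + (eT)BN_MOMENTUM * mu.t();
    rvar = (eT)(1.0 - BN_MOMENTUM) * rvar + (eT)BN_MOMENTUM * corr * var.t();
  } else {
    mu = rmean.t(); var = rvar.t();
  }
  Row<eT> invstd = eT(1) / sqrt(var + (eT)BN_EPS);
  Mat<eT> xhat = X;
  xhat.each_row() -= mu;
  xhat.each_row() %= invstd;
  Mat<eT> Y = xhat;
  Y.each_row() %= gamma.t();
  Y.each_row() += beta.t();
  if (cache) { cache->xhat = std::move(xhat); cache->invstd = invstd; }
  return Y;
}

template <typename eT>
static Mat<eT> bn_backward(const Mat<eT>& dY, const BNCache<eT>& c,
                           const Col<eT>& gamma, Col<eT>& dgamma, Col<eT>& dbeta) {
  const eT N = (eT)dY.n_rows;
  dgamma = sum(dY % c.xhat, 0).t();
  dbeta = sum(dY, 0).t();
  Row<eT> sdy = dbeta.t(), sdyx = dgamma.t();
  Mat<eT> dX = dY * N;
  dX.each_row() -= sdy;
  dX -= c.xhat.each_row() % sdyx;
  dX.each_row() %= (gamma.t() % c.invstd) / N;
  return dX;
}

// PReLU with one learnable slope per channel (column)
template <typename eT>
static Mat<eT> prelu_forward(const Mat<eT>& X, const Col<eT>& slope) {
  Mat<eT> Y(size(X));
  for (uword j = 0; j < X.n_cols; ++j) {
    const eT a = slope[j];
    const eT* xi = X.colptr(j); eT* yi = Y.colptr(j);
    for (uword i = 0; i < X.n_rows; ++i)
      yi[i] = xi[i] > 0 ? xi[i] : a * xi[i];
  }
  return Y;
}

template <typename eT>
static Mat<eT> prelu_backward(const Mat<eT>& dY, const Mat<eT>& Xpre,
                              const Col<eT>& slope, Col<eT>& dslope) {
  Mat<eT> dX(size(dY));
  dslope.zeros(slope.n_elem);
  for (uword j = 0; j < dY.n_cols; ++j) {
    const eT a = slope[j];
    eT ds = 0;
    const eT* xi = Xpre.colptr(j); const eT* gi = dY.colptr(j);
    eT* di = dX.colptr(j);
    for (uword i = 0; i < dY.n_rows; ++i) {
      if (xi[i] > 0) di[i] = gi[i];
      else { di[i] = a * gi[i]; ds += gi[i] * xi[i]; }
    }
    dslope[j] = ds;
  }
  return dX;
}

template <typename eT>
struct LNCache { Mat<eT> xhat; Col<eT> invstd; };

// layer normalization across the channel axis, one (mu, sd) per row
template <typename eT>
static Mat<eT> ln_forward(const Mat<eT>& X, const Col<eT>& gamma,
                          const Col<eT>& beta, LNCache<eT>* cache) {
  Col<eT> mu = mean(X, 1);
  Mat<eT> xhat = X;
  xhat.each_col() -= mu;
  Col<eT> invstd = eT(1) / sqrt(mean(square(xhat), 1) + (eT)LN_EPS);
  xhat.each_col() %= invstd;
  Mat<eT> Y = xhat;
  Y.each_row() %= gamma.t();
  Y.each_row() += beta.t();
  if (cache) { cache->xhat = std::move(xhat); cache->invstd = std::move(invstd); }
  return Y;
}

template <typename eT>
static Mat<eT> ln_backward(const Mat<eT>& dY, const LNCache<eT>& c,
                           const Col<eT>& gamma, Col<eT>& dgamma, Col<eT>& dbeta) {
  dgamma = sum(dY % c.xhat, 0).t();
  dbeta = sum(dY, 0).t();
  Mat<eT> g = dY;
  g.each_row() %= gamma.t();
  Col<eT> mg = mean(g, 1), mgx = mean(g % c.xhat, 1);
  Mat<eT> dX = g;
  dX.each_col() -= mg;
  dX -= c.xhat.each_col() % mgx;
  dX.each_col() %= c.invstd;
  return dX;
}

template <typename eT>
static Mat<eT> softmax_rows(const Mat<eT>& S) {
  Mat<eT> A = S;
  A.each_col() -= max(S, 1);
  A = exp(A);
  A.each_col() /= sum(A, 1);
  return A;
}

// inverted dropout mask (0 or 1/(1-p))
template <typename eT>
static Mat<eT> dropout_mask(int nr, int nc, double p, Rng& rng) {
  Mat<eT> M(nr, nc);
  const eT scale = (eT)(1.0 / (1.0 - p));
  const uint64_t thr = (uint64_t)(p * 18446744073709551615.0);
  eT* ptr = M.memptr();
  const uword n = M.n_elem;
  for (uword i = 0; i < n; ++i) ptr[i] = rng.next() < thr ? eT(0) : scale;
  return M;
}

// ---------------------------------------------------------------------------
// branch forward/backward (conv -> BN -> PReLU -> SE -> dropout)

template <typename eT>
struct BranchCache {
  Mat<eT> X2col, bnOut;
  BNCache<eT> bn;
  Mat<eT> act;              // post-PReLU (= SE input)
  Mat<eT> S, Z1, E;         // SE squeeze means, hidden (post-ReLU), excitation
  Mat<eT> drop;             // dropout mask ((B*L) x F), empty in eval
  int B, L;
};

template <typename eT>
static Mat<eT> branch_forward(const imat& seqs, const ParamsT<eT>& p, int br,
                              const Cfg& c, bool training, Rng* rng,
                              BranchCache<eT>* cc) {
  const int B = seqs.n_rows, L = seqs.n_cols, F = c.F;
  Mat<eT> X2col = onehot_im2col<eT>(seqs, c.ks);
  Mat<eT> convPre = X2col * p.convW[br].t();
  convPre.each_row() += p.convB[br].t();
  BNCache<eT> bnc;
  // const_cast: the running-stats update only happens in training mode, and
  // training always owns a mutable parameter copy
  Mat<eT> bnOut = bn_forward<eT>(convPre, const_cast<Col<eT>&>(p.bnG[br]),
                                 const_cast<Col<eT>&>(p.bnB[br]),
                                 const_cast<Col<eT>&>(p.bnM[br]),
                                 const_cast<Col<eT>&>(p.bnV[br]), training, &bnc);
  Mat<eT> act = prelu_forward<eT>(bnOut, p.prelu[br]);
  // squeeze: per-example channel means (row blocks are contiguous per column)
  Mat<eT> S(B, F);
  for (int f = 0; f < F; ++f) {
    const eT* col = act.colptr(f);
    for (int b = 0; b < B; ++b) {
      eT s = 0;
      for (int i = 0; i < L; ++i) s += col[b * L + i];
      S(b, f) = s / (eT)L;
    }
  }
  Mat<eT> Z1 = S * p.seW1[br].t();
  Z1.each_row() += p.seB1[br].t();
  Z1 = clamp(Z1, eT(0), std::numeric_limits<eT>::max());
  Mat<eT> E = Z1 * p.seW2[br].t();
  E.each_row() += p.seB2[br].t();
  E = eT(1) / (eT(1) + exp(-E));
  Mat<eT> out(B * L, F);
  for (int f = 0; f < F; ++f) {
    const eT* a = act.colptr(f); eT* o = out.colptr(f);
    for (int b = 0; b < B; ++b) {
      const eT e = E(b, f);
      for (int i = 0; i < L; ++i) o[b * L + i] = a[b * L + i] * e;
    }
  }
  Mat<eT> drop;
  if (training && c.p_se > 0) {
    drop = dropout_mask<eT>(B * L, F, c.p_se, *rng);
    out %= drop;
  }
  if (cc) {
    cc->X2col = std::move(X2col);
    cc->bn = std::move(bnc); cc->bnOut = std::move(bnOut); cc->act = std::move(act);
    cc->S = std::move(S); cc->Z1 = std::move(Z1); cc->E = std::move(E);
    cc->drop = std::move(drop); cc->B = B; cc->L = L;
  }
  return out;
}

template <typename eT>
struct BranchGrads {
  Mat<eT> convW; Col<eT> convB, bnG, bnB, prelu;
  Mat<eT> seW1; Col<eT> seB1; Mat<eT> seW2; Col<eT> seB2;
};

template <typename eT>
static void branch_backward(const Mat<eT>& dOut_in, const BranchCache<eT>& cc,
                            const ParamsT<eT>& p, int br, BranchGrads<eT>& g) {
  const int B = cc.B, L = cc.L, F = cc.act.n_cols;
  Mat<eT> dOut = dOut_in;
  if (!cc.drop.is_empty()) dOut %= cc.drop;
  // SE backward
  Mat<eT> dact(size(cc.act));
  Mat<eT> dE(B, F);
  for (int f = 0; f < F; ++f) {
    const eT* a = cc.act.colptr(f); const eT* do_ = dOut.colptr(f);
    eT* da = dact.colptr(f);
    for (int b = 0; b < B; ++b) {
      const eT e = cc.E(b, f);
      eT s = 0;
      for (int i = 0; i < L; ++i) {
        da[b * L + i] = do_[b * L + i] * e;
        s += do_[b * L + i] * a[b * L + i];
      }
      dE(b, f) = s;
    }
  }
  Mat<eT> dEpre = dE % cc.E % (eT(1) - cc.E);
  g.seW2 = dEpre.t() * cc.Z1;
  g.seB2 = sum(dEpre, 0).t();
  Mat<eT> dZ1 = dEpre * p.seW2[br];
  dZ1.elem(find(cc.Z1 == 0)).zeros();    // ReLU gate
  g.seW1 = dZ1.t() * cc.S;
  g.seB1 = sum(dZ1, 0).t();
  Mat<eT> dS = dZ1 * p.seW1[br];
  for (int f = 0; f < F; ++f) {
    eT* da = dact.colptr(f);
    for (int b = 0; b < B; ++b) {
      const eT add = dS(b, f) / (eT)L;
      for (int i = 0; i < L; ++i) da[b * L + i] += add;
    }
  }
  // PReLU, BN, conv
  Mat<eT> dBnOut = prelu_backward<eT>(dact, cc.bnOut, p.prelu[br], g.prelu);
  Mat<eT> dConvPre = bn_backward<eT>(dBnOut, cc.bn, p.bnG[br], g.bnG, g.bnB);
  g.convW = dConvPre.t() * cc.X2col;
  g.convB = sum(dConvPre, 0).t();
}

// ---------------------------------------------------------------------------
// full forward with cache

template <typename eT>
struct FwdCache {
  BranchCache<eT> pi, mr;
  Mat<eT> Pbig, Mbig;                // branch outputs (B*Lp x F), (B*Lm x F)
  Mat<eT> Qbig, Kbig, Vbig, Hcat;    // attention intermediates
  Cube<eT> attn;                     // (Lm x Lp x B*heads) softmax matrices
  Mat<eT> Hdrop;                     // dropout mask on H
  Mat<eT> Kin;                       // K = H + M (pre-LN)
  LNCache<eT> ln1; Mat<eT> Kn;       // post-LN1
  Mat<eT> ffA1pre, ffA1, ffDrop, ffA2pre;
  LNCache<eT> ln2; Mat<eT> Rout;
  Mat<eT> pool;                      // pure-CNN pooled piRNA features (B x F)
  Mat<eT> Xcls;                      // classifier input (B x D)
  Mat<eT> f1pre; BNCache<eT> cbn1; Mat<eT> f1bn, f1act; Mat<eT> cdrop1;
  Mat<eT> f2pre; BNCache<eT> cbn2; Mat<eT> f2bn, f2act; Mat<eT> cdrop2;
  Mat<eT> probs;
  int B;
};

template <typename eT>
static void attention_forward(const Mat<eT>& Mbig, const Mat<eT>& Pbig,
                              const ParamsT<eT>& p, const Cfg& c, int B,
                              FwdCache<eT>& f, Mat<eT>& Hout, bool keep_weights) {
  const int Lm = c.Lm, Lp = c.Lp, hd = c.hd;
  Mat<eT> Qbig = Mbig * p.Wq, Kbig = Pbig * p.Wk, Vbig = Pbig * p.Wv;
  Mat<eT> Hcat(B * Lm, c.F);
  if (keep_weights) f.attn.set_size(Lm, Lp, (size_t)B * c.heads);
  const eT inv_scale = eT(1.0 / c.d_scale);
  Mat<eT> Qb(Lm, hd), Kb(Lp, hd), Vb(Lp, hd), A(Lm, Lp), Ht(Lm, hd);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < c.heads; ++h) {
      Qb = Qbig.submat(b * Lm, h * hd, (b + 1) * Lm - 1, (h + 1) * hd - 1);
      Kb = Kbig.submat(b * Lp, h * hd, (b + 1) * Lp - 1, (h + 1) * hd - 1);
      Vb = Vbig.submat(b * Lp, h * hd, (b + 1) * Lp - 1, (h + 1) * hd - 1);
      A = softmax_rows<eT>(Qb * Kb.t() * inv_scale);
      Ht = A * Vb;
      Hcat.submat(b * Lm, h * hd, (b + 1) * Lm - 1, (h + 1) * hd - 1) = Ht;
      if (keep_weights) f.attn.slice((size_t)b * c.heads + h) = A;
    }
  }
  Hout = Hcat * p.Wh.t();
  Hout.each_row() += p.bh.t();
  f.Qbig = std::move(Qbig); f.Kbig = std::move(Kbig); f.Vbig = std::move(Vbig);
  f.Hcat = std::move(Hcat);
}

// flatten position-major: example row = (pos1 channels..., pos2 channels...)
template <typename eT>
static Mat<eT> flatten_rows(const Mat<eT>& big, int B, int L, int F) {
  Mat<eT> X(B, L * F);
  for (int f = 0; f < F; ++f) {
    const eT* col = big.colptr(f);
    for (int b = 0; b < B; ++b)
      for (int i = 0; i < L; ++i)
        X(b, (uword)i * F + f) = col[b * L + i];
  }
  return X;
}

template <typename eT>
static Mat<eT> unflatten_rows(const Mat<eT>& X, int B, int L, int F) {
  Mat<eT> big(B * L, F);
  for (int f = 0; f < F; ++f) {
    eT* col = big.colptr(f);
    for (int b = 0; b < B; ++b)
      for (int i = 0; i < L; ++i)
        col[b * L + i] = X(b, (uword)i * F + f);
  }
  return big;
}

template <typename eT>
static Mat<eT> forward_full(const imat& pi, const imat& mr, const ParamsT<eT>& p,
                            const Cfg& c, bool training, Rng* rng,
                            FwdCache<eT>& f, bool keep_attention) {
  const int B = pi.n_rows;
  f.B = B;
  f.Pbig = branch_forward<eT>(pi, p, 0, c, training, rng, &f.pi);
  f.Mbig = branch_forward<eT>(mr, p, 1, c, training, rng, &f.mr);

  if (!c.pure_cnn) {
    Mat<eT> H;
    attention_forward<eT>(f.Mbig, f.Pbig, p, c, B, f, H, keep_attention);
    if (training && c.p_attn > 0) {
      f.Hdrop = dropout_mask<eT>(H.n_rows, H.n_cols, c.p_attn, *rng);
      H %= f.Hdrop;
    }
    f.Kin = H + f.Mbig;
  } else {
    f.Kin = f.Mbig;
    // pooled piRNA features rejoin at the classifier
    f.pool.set_size(B, c.F);
    for (int ff = 0; ff < c.F; ++ff) {
      const eT* col = f.Pbig.colptr(ff);
      for (int b = 0; b < B; ++b) {
        eT s = 0;
        for (int i = 0; i < c.Lp; ++i) s += col[b * c.Lp + i];
        f.pool(b, ff) = s / (eT)c.Lp;
      }
    }
  }
  f.Kn = ln_forward<eT>(f.Kin, p.ln1G, p.ln1B, &f.ln1);
  // residual feed-forward: R = LN(K' + PReLU(PReLU(K' W1^T) W2^T))
  f.ffA1pre = f.Kn * p.ffW1.t();
  f.ffA1pre.each_row() += p.ffB1.t();
  f.ffA1 = prelu_forward<eT>(f.ffA1pre, p.ffPr1);
  Mat<eT> ffz;
  if (training && c.p_attn > 0) {
    f.ffDrop = dropout_mask<eT>(f.ffA1.n_rows, f.ffA1.n_cols, c.p_attn, *rng);
    ffz = f.ffA1 % f.ffDrop;
  } else ffz = f.ffA1;
  f.ffA2pre = ffz * p.ffW2.t();
  f.ffA2pre.each_row() += p.ffB2.t();
  Mat<eT> ffA2 = prelu_forward<eT>(f.ffA2pre, p.ffPr2);
  f.Rout = ln_forward<eT>(f.Kn + ffA2, p.ln2G, p.ln2B, &f.ln2);

  // classifier
  f.Xcls = flatten_rows<eT>(f.Rout, B, c.Lm, c.F);
  f.f1pre = f.Xcls * p.cW1.t();
  f.f1pre.each_row() += p.cB1.t();
  f.f1bn = bn_forward<eT>(f.f1pre, const_cast<Col<eT>&>(p.cbn1G),
                          const_cast<Col<eT>&>(p.cbn1B),
                          const_cast<Col<eT>&>(p.cbn1M),
                          const_cast<Col<eT>&>(p.cbn1V), training, &f.cbn1);
  Mat<eT> x1 = prelu_forward<eT>(f.f1bn, p.cPr1);
  if (training && c.p_cls > 0) {
    f.cdrop1 = dropout_mask<eT>(x1.n_rows, x1.n_cols, c.p_cls, *rng);
    x1 %= f.cdrop1;
  }
  if (c.pure_cnn) x1 = join_rows(x1, f.pool);
  f.f2pre = x1 * p.cW2.t();
  f.f2pre.each_row() += p.cB2.t();
  f.f2bn = bn_forward<eT>(f.f2pre, const_cast<Col<eT>&>(p.cbn2G),
                          const_cast<Col<eT>&>(p.cbn2B),
                          const_cast<Col<eT>&>(p.cbn2M),
                          const_cast<Col<eT>&>(p.cbn2V), training, &f.cbn2);
  Mat<eT> x2 = prelu_forward<eT>(f.f2bn, p.cPr2);
  if (training && c.p_cls > 0) {
    f.cdrop2 = dropout_mask<eT>(x2.n_rows, x2.n_cols, c.p_cls, *rng);
    x2 %= f.cdrop2;
  }
  Mat<eT> logits = x2 * p.cW3.t();
  logits.each_row() += p.cB3.t();
  f.probs = softmax_rows<eT>(logits);
  // post-dropout activations are the inputs of the next linear map, which is
  // what the weight gradients need
  f.f1act = std::move(x1); f.f2act = std::move(x2);
  return f.probs;
}

// ---------------------------------------------------------------------------
// backward

template <typename eT>
struct Grads {
  BranchGrads<eT> pi, mr;
  Mat<eT> Wq, Wk, Wv, Wh; Col<eT> bh;
  Col<eT> ln1G, ln1B;
  Mat<eT> ffW1; Col<eT> ffB1, ffPr1; Mat<eT> ffW2; Col<eT> ffB2, ffPr2;
  Col<eT> ln2G, ln2B;
  Mat<eT> cW1; Col<eT> cB1, cbn1G, cbn1B, cPr1;
  Mat<eT> cW2; Col<eT> cB2, cbn2G, cbn2B, cPr2;
  Mat<eT> cW3; Col<eT> cB3;
};

template <typename eT>
static void backward_full(const FwdCache<eT>& f, const ParamsT<eT>& p,
                          const Cfg& c, const ivec& y, Grads<eT>& g) {
  const int B = f.B;
  // cross-entropy + softmax
  Mat<eT> dLogits = f.probs;
  for (int b = 0; b < B; ++b) dLogits(b, y[b]) -= eT(1);
  dLogits /= (eT)B;
  // classifier
  g.cW3 = dLogits.t() * f.f2act;
  g.cB3 = sum(dLogits, 0).t();
  Mat<eT> dx2 = dLogits * p.cW3;
  if (!f.cdrop2.is_empty()) dx2 %= f.cdrop2;
  Mat<eT> df2bn = prelu_backward<eT>(dx2, f.f2bn, p.cPr2, g.cPr2);
  Mat<eT> df2pre = bn_backward<eT>(df2bn, f.cbn2, p.cbn2G, g.cbn2G, g.cbn2B);
  g.cW2 = df2pre.t() * f.f1act;
  g.cB2 = sum(df2pre, 0).t();
  Mat<eT> dx1cat = df2pre * p.cW2;
  Mat<eT> dPool;
  Mat<eT> dx1;
  if (c.pure_cnn) {
    dPool = dx1cat.cols(c.fc1, c.fc1 + c.F - 1);
    dx1 = dx1cat.cols(0, c.fc1 - 1);
  } else dx1 = std::move(dx1cat);
  if (!f.cdrop1.is_empty()) dx1 %= f.cdrop1;
  Mat<eT> df1bn = prelu_backward<eT>(dx1, f.f1bn, p.cPr1, g.cPr1);
  Mat<eT> df1pre = bn_backward<eT>(df1bn, f.cbn1, p.cbn1G, g.cbn1G, g.cbn1B);
  g.cW1 = df1pre.t() * f.Xcls;
  g.cB1 = sum(df1pre, 0).t();
  Mat<eT> dRout = unflatten_rows<eT>(df1pre * p.cW1, B, c.Lm, c.F);
  // LN2 / residual FF
  Mat<eT> dRsum = ln_backward<eT>(dRout, f.ln2, p.ln2G, g.ln2G, g.ln2B);
  Mat<eT> dffA2pre = prelu_backward<eT>(dRsum, f.ffA2pre, p.ffPr2, g.ffPr2);
  Mat<eT> ffz;
  if (!f.ffDrop.is_empty()) ffz = f.ffA1 % f.ffDrop; else ffz = f.ffA1;
  g.ffW2 = dffA2pre.t() * ffz;
  g.ffB2 = sum(dffA2pre, 0).t();
  Mat<eT> dffz = dffA2pre * p.ffW2;
  if (!f.ffDrop.is_empty()) dffz %= f.ffDrop;
  Mat<eT> dffA1pre = prelu_backward<eT>(dffz, f.ffA1pre, p.ffPr1, g.ffPr1);
  g.ffW1 = dffA1pre.t() * f.Kn;
  g.ffB1 = sum(dffA1pre, 0).t();
  Mat<eT> dKn = dRsum + dffA1pre * p.ffW1;   // residual + feed-forward paths
  Mat<eT> dKin = ln_backward<eT>(dKn, f.ln1, p.ln1G, g.ln1G, g.ln1B);

  Mat<eT> dMbig, dPbig;
  if (!c.pure_cnn) {
    Mat<eT> dH = dKin;                       // K = H + M
    dMbig = dKin;
    if (!f.Hdrop.is_empty()) dH %= f.Hdrop;
    g.Wh = dH.t() * f.Hcat;
    g.bh = sum(dH, 0).t();
    Mat<eT> dHcat = dH * p.Wh;
    Mat<eT> dQbig(size(f.Qbig), fill::zeros), dKbig(size(f.Kbig), fill::zeros),
            dVbig(size(f.Vbig), fill::zeros);
    const int Lm = c.Lm, Lp = c.Lp, hd = c.hd;
    const eT inv_scale = eT(1.0 / c.d_scale);
    Mat<eT> Qb(Lm, hd), Kb(Lp, hd), Vb(Lp, hd), dHt(Lm, hd), dA(Lm, Lp),
            dS(Lm, Lp);
    for (int b = 0; b < B; ++b) {
      for (int h = 0; h < c.heads; ++h) {
        Qb = f.Qbig.submat(b * Lm, h * hd, (b + 1) * Lm - 1, (h + 1) * hd - 1);
        Kb = f.Kbig.submat(b * Lp, h * hd, (b + 1) * Lp - 1, (h + 1) * hd - 1);
        Vb = f.Vbig.submat(b * Lp, h * hd, (b + 1) * Lp - 1, (h + 1) * hd - 1);
        const Mat<eT>& A = f.attn.slice((size_t)b * c.heads + h);
        dHt = dHcat.submat(b * Lm, h * hd, (b + 1) * Lm - 1, (h + 1) * hd - 1);
        dA = dHt * Vb.t();
        dVbig.submat(b * Lp, h * hd, (b + 1) * Lp - 1, (h + 1) * hd - 1) =
          A.t() * dHt;
        // softmax backward, rowwise: dS = A o (dA - rowsum(dA o A))
        dS = dA;
        dS.each_col() -= sum(dA % A, 1);
        dS %= A;
        dQbig.submat(b * Lm, h * hd, (b + 1) * Lm - 1, (h + 1) * hd - 1) =
          dS * Kb * inv_scale;
        dKbig.submat(b * Lp, h * hd, (b + 1) * Lp - 1, (h + 1) * hd - 1) =
          dS.t() * Qb * inv_scale;
      }
    }
    g.Wq = f.Mbig.t() * dQbig;
    g.Wk = f.Pbig.t() * dKbig;
    g.Wv = f.Pbig.t() * dVbig;
    dMbig += dQbig * p.Wq.t();
    dPbig = dKbig * p.Wk.t() + dVbig * p.Wv.t();
  } else {
    dMbig = std::move(dKin);
    dPbig.zeros(size(f.Pbig));
    for (int ff = 0; ff < c.F; ++ff) {
      eT* col = dPbig.colptr(ff);
      for (int b = 0; b < B; ++b) {
        const eT add = dPool(b, ff) / (eT)c.Lp;
        for (int i = 0; i < c.Lp; ++i) col[b * c.Lp + i] += add;
      }
    }
  }
  branch_backward<eT>(dPbig, f.pi, p, 0, g.pi);
  branch_backward<eT>(dMbig, f.mr, p, 1, g.mr);
}

// ---------------------------------------------------------------------------
// Adam

template <typename eT>
struct Adam {
  std::vector<Mat<eT>> m, v;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const std::vector<Mat<eT>*>& ps, double lr0) {
    lr = lr0;
    m.clear(); v.clear();
    for (auto* p : ps) {
      m.push_back(zeros<Mat<eT>>(size(*p)));
      v.push_back(zeros<Mat<eT>>(size(*p)));
    }
  }
  void step(const std::vector<Mat<eT>*>& ps, const std::vector<const Mat<eT>*>& gs) {
    ++t;
    const eT bc1 = (eT)(1.0 - std::pow(b1, (double)t));
    const eT bc2 = (eT)(1.0 - std::pow(b2, (double)t));
    const eT a1 = (eT)b1, a2 = (eT)b2, e = (eT)eps, l = (eT)lr;
    for (size_t i = 0; i < ps.size(); ++i) {
      Mat<eT>& mi = m[i]; Mat<eT>& vi = v[i];
      Mat<eT>& pi = *ps[i]; const Mat<eT>& gi = *gs[i];
      eT* mp = mi.memptr(); eT* vp = vi.memptr(); eT* pp = pi.memptr();
      const eT* gp = gi.memptr();
      const uword n = pi.n_elem;
      for (uword k = 0; k < n; ++k) {
        mp[k] = a1 * mp[k] + (eT(1) - a1) * gp[k];
        vp[k] = a2 * vp[k] + (eT(1) - a2) * gp[k] * gp[k];
        pp[k] -= l * (mp[k] / bc1) / (std::sqrt(vp[k] / bc2) + e);
      }
    }
  }
};

// Collect pointers to trainable tensors in a fixed order. arma::Col derives
// publicly from arma::Mat (a one-column matrix), so Col pointers upcast.
template <typename eT>
static void collect_trainables(ParamsT<eT>& p, const Cfg& c,
                               std::vector<Mat<eT>*>& out) {
  auto add = [&out](Mat<eT>& m) { out.push_back(&m); };
  auto addv = [&out](Col<eT>& v) { out.push_back(static_cast<Mat<eT>*>(&v)); };
  for (int i = 0; i < 2; ++i) {
    add(p.convW[i]); addv(p.convB[i]);
    addv(p.bnG[i]); addv(p.bnB[i]);
    addv(p.prelu[i]);
    add(p.seW1[i]); addv(p.seB1[i]); add(p.seW2[i]); addv(p.seB2[i]);
  }
  if (!c.pure_cnn) { add(p.Wq); add(p.Wk); add(p.Wv); add(p.Wh); addv(p.bh); }
  addv(p.ln1G); addv(p.ln1B);
  add(p.ffW1); addv(p.ffB1); addv(p.ffPr1);
  add(p.ffW2); addv(p.ffB2); addv(p.ffPr2);
  addv(p.ln2G); addv(p.ln2B);
  add(p.cW1); addv(p.cB1); addv(p.cbn1G); addv(p.cbn1B); addv(p.cPr1);
  add(p.cW2); addv(p.cB2); addv(p.cbn2G); addv(p.cbn2B); addv(p.cPr2);
  add(p.cW3); addv(p.cB3);
}

template <typename eT>
static void collect_grads(Grads<eT>& g, const Cfg& c,
                          std::vector<const Mat<eT>*>& out) {
  auto add = [&out](const Mat<eT>& m) { out.push_back(&m); };
  auto addv = [&out](const Col<eT>& v) {
    out.push_back(static_cast<const Mat<eT>*>(&v));
  };
  BranchGrads<eT>* brs[2] = {&g.pi, &g.mr};
  for (int i = 0; i < 2; ++i) {
    BranchGrads<eT>& b = *brs[i];
    add(b.convW); addv(b.convB); addv(b.bnG); addv(b.bnB); addv(b.prelu);
    add(b.seW1); addv(b.seB1); add(b.seW2); addv(b.seB2);
  }
  if (!c.pure_cnn) { add(g.Wq); add(g.Wk); add(g.Wv); add(g.Wh); addv(g.bh); }
  addv(g.ln1G); addv(g.ln1B);
  add(g.ffW1); addv(g.ffB1); addv(g.ffPr1);
  add(g.ffW2); addv(g.ffB2); addv(g.ffPr2);
  addv(g.ln2G); addv(g.ln2B);
  add(g.cW1); addv(g.cB1); addv(g.cbn1G); addv(g.cbn1B); addv(g.cPr1);
  add(g.cW2); addv(g.cB2); addv(g.cbn2G); addv(g.cbn2B); addv(g.cPr2);
  add(g.cW3); addv(g.cB3);
}

template <typename eT>
static Rcpp::List grads_to_list(const Grads<eT>& g, const Cfg& c) {
  Rcpp::List l;
  auto wm = [](const Mat<eT>& m) { return Rcpp::wrap(conv_to<mat>::from(m)); };
  auto wv = [](const Col<eT>& v) { return Rcpp::wrap(conv_to<vec>::from(v)); };
  const char* br[2] = {"pi", "mr"};
  const BranchGrads<eT>* brs[2] = {&g.pi, &g.mr};
  for (int i = 0; i < 2; ++i) {
    std::string b(br[i]);
    const BranchGrads<eT>& bg = *brs[i];
    l[b + "_conv_W"] = wm(bg.convW); l[b + "_conv_b"] = wv(bg.convB);
    l[b + "_bn_gamma"] = wv(bg.bnG); l[b + "_bn_beta"] = wv(bg.bnB);
    l[b + "_prelu"] = wv(bg.prelu);
    l[b + "_se_W1"] = wm(bg.seW1); l[b + "_se_b1"] = wv(bg.seB1);
    l[b + "_se_W2"] = wm(bg.seW2); l[b + "_se_b2"] = wv(bg.seB2);
  }
  if (!c.pure_cnn) {
    l["att_Wq"] = wm(g.Wq); l["att_Wk"] = wm(g.Wk); l["att_Wv"] = wm(g.Wv);
    l["att_Wh"] = wm(g.Wh); l["att_bh"] = wv(g.bh);
  }
  l["ln1_gamma"] = wv(g.ln1G); l["ln1_beta"] = wv(g.ln1B);
  l["ff_W1"] = wm(g.ffW1); l["ff_b1"] = wv(g.ffB1); l["ff_prelu1"] = wv(g.ffPr1);
  l["ff_W2"] = wm(g.ffW2); l["ff_b2"] = wv(g.ffB2); l["ff_prelu2"] = wv(g.ffPr2);
  l["ln2_gamma"] = wv(g.ln2G); l["ln2_beta"] = wv(g.ln2B);
  l["cls_W1"] = wm(g.cW1); l["cls_b1"] = wv(g.cB1);
  l["cls_bn1_gamma"] = wv(g.cbn1G); l["cls_bn1_beta"] = wv(g.cbn1B);
  l["cls_prelu1"] = wv(g.cPr1);
  l["cls_W2"] = wm(g.cW2); l["cls_b2"] = wv(g.cB2);
  l["cls_bn2_gamma"] = wv(g.cbn2G); l["cls_bn2_beta"] = wv(g.cbn2B);
  l["cls_prelu2"] = wv(g.cPr2);
  l["cls_W3"] = wm(g.cW3); l["cls_b3"] = wv(g.cB3);
  return l;
}

// ---------------------------------------------------------------------------
// exported: loss + gradients (double precision; used by the
// finite-difference verification of the backward pass)

// [[Rcpp::export]]
Rcpp::List nn_loss_grads_cpp(Rcpp::List params, Rcpp::List cfg,
                             Rcpp::IntegerMatrix pi_seqs, Rcpp::IntegerMatrix mr_seqs,
                             Rcpp::IntegerVector y, bool with_grads = true, int seed = 1) {
  Cfg c = cfg_from_list(cfg);
  ParamsT<double> p = params_from_list<double>(params, c);
  imat pi = Rcpp::as<imat>(pi_seqs), mr = Rcpp::as<imat>(mr_seqs);
  ivec yy = Rcpp::as<ivec>(y);
  Rng rng((uint64_t)seed);
  FwdCache<double> f;
  mat probs = forward_full<double>(pi, mr, p, c, true, &rng, f, !c.pure_cnn);
  double loss = 0;
  for (uword i = 0; i < probs.n_rows; ++i)
    loss += -std::log(std::max(probs(i, yy[i]), 1e-12));
  loss /= probs.n_rows;
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loss") = loss);
  if (with_grads) {
    Grads<double> g;
    backward_full<double>(f, p, c, yy, g);
    out["grads"] = grads_to_list<double>(g, c);
  }
  return out;
}

// ---------------------------------------------------------------------------
// exported: batched forward (single precision)

// [[Rcpp::export]]
Rcpp::List nn_forward_cpp(Rcpp::List params, Rcpp::List cfg, Rcpp::IntegerMatrix pi_seqs,
                          Rcpp::IntegerMatrix mr_seqs, bool training = false,
                          bool return_attention = false, int seed = 1) {
  Cfg c = cfg_from_list(cfg);
  ParamsT<float> p = params_from_list<float>(params, c);
  imat pi = Rcpp::as<imat>(pi_seqs), mr = Rcpp::as<imat>(mr_seqs);
  if ((int)pi.n_cols != c.Lp || (int)mr.n_cols != c.Lm)
    Rcpp::stop("sequence lengths do not match the network configuration");
  Rng rng((uint64_t)seed);
  Rcpp::List out;
  if (return_attention && !c.pure_cnn) {
    FwdCache<float> f;
    fmat probs = forward_full<float>(pi, mr, p, c, training, &rng, f, true);
    out["prob"] = Rcpp::wrap(conv_to<mat>::from(probs));
    cube attn = conv_to<cube>::from(f.attn);
    Rcpp::NumericVector a(attn.begin(), attn.end());
    a.attr("dim") = Rcpp::IntegerVector::create(c.Lm, c.Lp, c.heads, pi.n_rows);
    out["attention"] = a;
    out["H"] = Rcpp::wrap(conv_to<mat>::from(fmat(f.Kin - f.Mbig)));
    out["R"] = Rcpp::wrap(conv_to<mat>::from(f.Rout));
  } else {
    const int B = pi.n_rows, chunk = 512;
    mat probs(B, 2);
    for (int s = 0; s < B; s += chunk) {
      int e = std::min(B, s + chunk) - 1;
      FwdCache<float> f;
      fmat pr = forward_full<float>(pi.rows(s, e), mr.rows(s, e), p, c,
                                    training, &rng, f, false);
      probs.rows(s, e) = conv_to<mat>::from(pr);
    }
    out["prob"] = probs;
  }
  if (training) out["params"] = params_to_list<float>(p, c);
  return out;
}

// ---------------------------------------------------------------------------
// exported: training loop (single precision)

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(Rcpp::List params, Rcpp::List cfg,
                        Rcpp::IntegerMatrix pi_tr, Rcpp::IntegerMatrix mr_tr,
                        Rcpp::IntegerVector y_tr,
                        Rcpp::IntegerMatrix pi_va, Rcpp::IntegerMatrix mr_va,
                        Rcpp::IntegerVector y_va,
                        int epochs, int batch_size, double lr,
                        int patience, double factor, double min_lr,
                        int seed, bool verbose) {
  typedef float eT;
  Cfg c = cfg_from_list(cfg);
  ParamsT<eT> p = params_from_list<eT>(params, c);
  imat Xp = Rcpp::as<imat>(pi_tr), Xm = Rcpp::as<imat>(mr_tr);
  imat Vp = Rcpp::as<imat>(pi_va), Vm = Rcpp::as<imat>(mr_va);
  ivec y = Rcpp::as<ivec>(y_tr), yv = Rcpp::as<ivec>(y_va);
  const int n = Xp.n_rows, nv = Vp.n_rows;
  if (n == 0) Rcpp::stop("empty training split");

  std::vector<Mat<eT>*> tp; collect_trainables<eT>(p, c, tp);
  Adam<eT> opt; opt.init(tp, lr);
  Rng rng((uint64_t)seed * 2654435761ULL + 13ULL);
  std::mt19937_64 shuf((uint64_t)seed + 977ULL);
  std::vector<int> idx(n); for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> tr_loss, tr_acc, va_loss, va_acc, lr_log;
  double best_val = datum::inf; int wait = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), shuf);
    double lsum = 0; long lcnt = 0, correct = 0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(n, s + batch_size);
      int B = e - s;
      if (B < 2) continue;               // batch-norm needs >1 example
      imat bp(B, Xp.n_cols), bm(B, Xm.n_cols); ivec by(B);
      for (int i = 0; i < B; ++i) {
        bp.row(i) = Xp.row(idx[s + i]);
        bm.row(i) = Xm.row(idx[s + i]);
        by[i] = y[idx[s + i]];
      }
      FwdCache<eT> f;
      fmat probs = forward_full<eT>(bp, bm, p, c, true, &rng, f, !c.pure_cnn);
      for (int i = 0; i < B; ++i) {
        double pc = std::max((double)probs(i, by[i]), 1e-12);
        lsum += -std::log(pc); ++lcnt;
        if ((probs(i, 1) > probs(i, 0) ? 1 : 0) == by[i]) ++correct;
      }
      if (!std::isfinite(lsum))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      Grads<eT> g;
      backward_full<eT>(f, p, c, by, g);
      std::vector<const Mat<eT>*> gp; collect_grads<eT>(g, c, gp);
      opt.step(tp, gp);
    }
    tr_loss.push_back(lsum / std::max(1L, lcnt));
    tr_acc.push_back((double)correct / std::max(1L, lcnt));

    // validation in eval mode
    double vl = datum::nan, va = datum::nan;
    if (nv > 0) {
      vl = 0; long vc = 0;
      const int chunk = 1024;
      for (int s = 0; s < nv; s += chunk) {
        int e = std::min(nv, s + chunk) - 1;
        FwdCache<eT> f;
        fmat probs = forward_full<eT>(Vp.rows(s, e), Vm.rows(s, e), p, c,
                                      false, &rng, f, false);
        for (int i = 0; i <= e - s; ++i) {
          vl += -std::log(std::max((double)probs(i, yv[s + i]), 1e-12));
          if ((probs(i, 1) > probs(i, 0) ? 1 : 0) == yv[s + i]) ++vc;
        }
      }
      vl /= nv; va = (double)vc / nv;
      // reduce-on-plateau scheduler
      if (vl < best_val - 1e-8) { best_val = vl; wait = 0; }
      else if (++wait > patience) {
        opt.lr = std::max(opt.lr * factor, min_lr);
        wait = 0;
      }
    }
    va_loss.push_back(vl); va_acc.push_back(va); lr_log.push_back(opt.lr);
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << "  train loss " << tr_loss.back()
                  << "  acc " << tr_acc.back() << "  val loss " << vl
                  << "  val acc " << va << "  lr " << opt.lr << "\n";
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = params_to_list<eT>(p, c),
    Rcpp::Named("train_loss") = tr_loss, Rcpp::Named("train_acc") = tr_acc,
    Rcpp::Named("val_loss") = va_loss, Rcpp::Named("val_acc") = va_acc,
    Rcpp::Named("lr") = lr_log);
}

// ---------------------------------------------------------------------------
// exported component operations (double precision, eval mode, single example)

// [[Rcpp::export]]
arma::mat nn_conv_cpp(arma::mat E, arma::mat W, arma::vec b, arma::vec gamma,
                      arma::vec beta, arma::vec rmean, arma::vec rvar,
                      arma::vec slope, bool with_bn = true, bool with_act = true) {
  int ks = W.n_cols / 4;
  if ((int)E.n_rows < ks) Rcpp::stop("sequence shorter than the kernel");
  mat out = real_im2col<double>(E, ks) * W.t();
  out.each_row() += b.t();
  if (with_bn) out = bn_forward<double>(out, gamma, beta, rmean, rvar, false, nullptr);
  if (with_act) out = prelu_forward<double>(out, slope);
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_se_cpp(arma::mat C, arma::mat W1, arma::vec b1, arma::mat W2, arma::vec b2) {
  if (W1.n_cols != C.n_cols) Rcpp::stop("SE weight width does not match channel count");
  rowvec s = mean(C, 0);
  rowvec z1 = clamp(s * W1.t() + b1.t(), 0.0, datum::inf);
  rowvec e = 1.0 / (1.0 + exp(-(z1 * W2.t() + b2.t())));
  mat F = C.each_row() % e;
  return Rcpp::List::create(Rcpp::Named("F") = F,
                            Rcpp::Named("excitation") = vec(e.t()),
                            Rcpp::Named("squeeze") = vec(s.t()));
}

// [[Rcpp::export]]
Rcpp::List nn_attention_head_cpp(arma::mat M, arma::mat P, arma::mat Wq,
                                 arma::mat Wk, arma::mat Wv, double d) {
  if (d <= 0) Rcpp::stop("attention scale d must be positive");
  mat Q = M * Wq, K = P * Wk, V = P * Wv;
  mat A = softmax_rows<double>(Q * K.t() / std::sqrt(d));
  return Rcpp::List::create(Rcpp::Named("H") = mat(A * V), Rcpp::Named("weights") = A);
}

// [[Rcpp::export]]
Rcpp::List nn_multi_head_cpp(arma::mat M, arma::mat P, arma::mat Wq, arma::mat Wk,
                             arma::mat Wv, arma::mat Wh, arma::vec bh, int heads,
                             double d) {
  const int F = M.n_cols, hd = F / heads;
  if (F % heads != 0) Rcpp::stop("channel count not divisible by head count");
  if ((int)Wq.n_cols != F) Rcpp::stop("head projections inconsistent with n_filters");
  mat Q = M * Wq, K = P * Wk, V = P * Wv;
  mat Hcat(M.n_rows, F);
  cube W(M.n_rows, P.n_rows, heads);
  for (int h = 0; h < heads; ++h) {
    span cs(h * hd, (h + 1) * hd - 1);
    mat A = softmax_rows<double>(Q.cols(cs) * K.cols(cs).t() / std::sqrt(d));
    Hcat.cols(cs) = A * V.cols(cs);
    W.slice(h) = A;
  }
  mat H = Hcat * Wh.t();
  H.each_row() += bh.t();
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("weights") = W);
}

// [[Rcpp::export]]
arma::mat nn_residual_ff_cpp(arma::mat H, arma::mat M, arma::vec ln1G, arma::vec ln1B,
                             arma::mat W1, arma::vec b1, arma::vec pr1,
                             arma::mat W2, arma::vec b2, arma::vec pr2,
                             arma::vec ln2G, arma::vec ln2B) {
  if (H.n_rows != M.n_rows || H.n_cols != M.n_cols) Rcpp::stop("H and M shapes differ");
  mat K = H + M;
  mat Kn = ln_forward<double>(K, ln1G, ln1B, nullptr);
  mat A1 = Kn * W1.t(); A1.each_row() += b1.t();
  A1 = prelu_forward<double>(A1, pr1);
  mat A2 = A1 * W2.t(); A2.each_row() += b2.t();
  A2 = prelu_forward<double>(A2, pr2);
  return ln_forward<double>(Kn + A2, ln2G, ln2B, nullptr);
}

// [[Rcpp::export]]
arma::mat nn_classify_cpp(arma::mat X, arma::mat W1, arma::vec b1,
                          arma::vec bn1G, arma::vec bn1B, arma::vec bn1M, arma::vec bn1V,
                          arma::vec pr1,
                          arma::mat W2, arma::vec b2,
                          arma::vec bn2G, arma::vec bn2B, arma::vec bn2M, arma::vec bn2V,
                          arma::vec pr2,
                          arma::mat W3, arma::vec b3) {
  if (X.n_cols != W1.n_cols) Rcpp::stop("flatten size does not match classifier input");
  mat h = X * W1.t(); h.each_row() += b1.t();
  h = bn_forward<double>(h, bn1G, bn1B, bn1M, bn1V, false, nullptr);
  h = prelu_forward<double>(h, pr1);
  h = h * W2.t(); h.each_row() += b2.t();
  h = bn_forward<double>(h, bn2G, bn2B, bn2M, bn2V, false, nullptr);
  h = prelu_forward<double>(h, pr2);
  h = h * W3.t(); h.each_row() += b3.t();
  return softmax_rows<double>(h);
}
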