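// Self-contained 1-D CNN and stacked bidirectional LSTM with AdamW and
// class-weighted binary cross entropy. Minibatch training with
// best-checkpoint selection by average precision on a held-out tune set.
// All randomness (initial weights, epoch shuffles, dropout draws) comes
// from the R side / R's RNG, so training is deterministic given a seed.
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::cube;
using arma::uvec;
using arma::uword;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;
static const double P_EPS = 1e-7;  // probability clipping in the loss

// ---------------------------------------------------------------------
// shared helpers

static inline mat sigmoid_m(const mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }
static inline vec sigmoid_v(const vec& z) { return 1.0 / (1.0 + arma::exp(-z)); }

// tie-grouped average precision (same estimator as the R auprc())
static double average_precision(const vec& s, const vec& y) {
  double P = arma::accu(y);
  uword n = s.n_elem;
  if (P <= 0 || P >= (double)n) return -1.0;  // single class: undefined
  uvec ord = arma::stable_sort_index(s, "descend");
  double tp = 0, ap = 0;
  uword i = 0;
  while (i < n) {
    uword j = i;
    double tpg = 0;
    while (j < n && s(ord(j)) == s(ord(i))) { tpg += y(ord(j)); ++j; }
    tp += tpg;
    ap += (tpg / P) * (tp / (double)j);
    i = j;
  }
  return ap;
}

// mean over the batch of w(y) * BCE, probabilities clipped at P_EPS
static double weighted_bce_loss(const vec& p, const vec& y,
                                double w_neg, double w_pos) {
  vec pc = arma::clamp(p, P_EPS, 1.0 - P_EPS);
  vec w = w_neg + (w_pos - w_neg) * y;
  return arma::mean(w % (-y % arma::log(pc) - (1 - y) % arma::log(1 - pc)));
}

struct AdamW {
  std::vector<mat> m, v;
  double lr, b1, b2, wd, eps;
  long t = 0;
  void init(const std::vector<mat*>& params, double lr_, double b1_,
            double b2_, double wd_) {
    lr = lr_; b1 = b1_; b2 = b2_; wd = wd_; eps = 1e-8;
    m.clear(); v.clear();
    for (auto* p : params) {
      m.push_back(arma::zeros<mat>(p->n_rows, p->n_cols));
      v.push_back(arma::zeros<mat>(p->n_rows, p->n_cols));
    }
  }
  void step(std::vector<mat*>& params, const std::vector<mat*>& grads) {
    ++t;
    double bc1 = 1.0 - std::pow(b1, (double)t);
    double bc2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * (*grads[i]);
      v[i] = b2 * v[i] + (1 - b2) * arma::square(*grads[i]);
      *params[i] -= lr * ((m[i] / bc1) / (arma::sqrt(v[i] / bc2) + eps)
                          + wd * (*params[i]));
    }
  }
};

static void clip_grads(std::vector<mat*>& grads, double clip) {
  if (clip <= 0) return;
  double ss = 0;
  for (auto* g : grads) ss += arma::accu(arma::square(*g));
  double nrm = std::sqrt(ss);
  if (nrm > clip) for (auto* g : grads) *g *= clip / nrm;
}

// ---------------------------------------------------------------------
// 1-D CNN: [conv -> batchnorm -> ReLU -> maxpool] x B, GAP, FC, sigmoid

struct CnnSpec {
  std::vector<int> k, f, pool;
  double dropout = 0.0;
  int n_blocks() const { return (int)k.size(); }
};

struct CnnParams {
  std::vector<mat> W;                       // (cout x cin*k)
  std::vector<vec> b, g, beta, rmean, rvar; // per-channel
  vec fcW;
  double fcb = 0.0;
};

static CnnParams cnn_params_from_list(const List& init, const CnnSpec& spec) {
  CnnParams P;
  for (int l = 0; l < spec.n_blocks(); ++l) {
    std::string s = std::to_string(l + 1);
    P.W.push_back(as<mat>(init["W" + s]));
    P.b.push_back(as<vec>(init["b" + s]));
    P.g.push_back(as<vec>(init["g" + s]));
    P.beta.push_back(as<vec>(init["beta" + s]));
    P.rmean.push_back(as<vec>(init["rmean" + s]));
    P.rvar.push_back(as<vec>(init["rvar" + s]));
  }
  P.fcW = as<vec>(init["fcW"]);
  P.fcb = as<double>(init["fcb"]);
  return P;
}

static List cnn_params_to_list(const CnnParams& P, const CnnSpec& spec) {
  List out;
  for (int l = 0; l < spec.n_blocks(); ++l) {
    std::string s = std::to_string(l + 1);
    out["W" + s] = P.W[l]; out["b" + s] = P.b[l];
    out["g" + s] = P.g[l]; out["beta" + s] = P.beta[l];
    out["rmean" + s] = P.rmean[l]; out["rvar" + s] = P.rvar[l];
  }
  out["fcW"] = P.fcW;
  out["fcb"] = P.fcb;
  return out;
}

// zero-padded 'same' im2col: A (cin x L) -> (cin*k x L)
static mat im2col(const mat& A, int k) {
  int cin = A.n_rows, L = A.n_cols, pad = (k - 1) / 2;
  mat C(cin * k, L, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    int off = j - pad;
    int lo = std::max(0, -off), hi = std::min(L, L - off);
    if (hi <= lo) continue;
    C.rows(arma::span(j * cin, j * cin + cin - 1)).cols(lo, hi - 1) =
      A.cols(lo + off, hi - 1 + off);
  }
  return C;
}

static void col2im_add(mat& dA, const mat& dC, int k) {
  int cin = dA.n_rows, L = dA.n_cols, pad = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    int off = j - pad;
    int lo = std::max(0, -off), hi = std::min(L, L - off);
    if (hi <= lo) continue;
    dA.cols(lo + off, hi - 1 + off) +=
      dC.rows(arma::span(j * cin, j * cin + cin - 1)).cols(lo, hi - 1);
  }
}

struct CnnCache {
  std::vector<std::vector<mat>> Ain;   // block -> per-sample input (cin x L)
  std::vector<cube> xhat;              // BN normalized pre-activation
  std::vector<vec> invstd;
  std::vector<cube> relu_out;          // post-ReLU (mask = >0)
  std::vector<cube> pooled;
  std::vector<arma::Cube<uword>> argmax;
  mat gap;                             // (B x cout_last)
  mat gap_mask;                        // dropout mask applied to gap
  vec logits, probs;
};

// forward one minibatch; training mode uses batch statistics and
// updates running BN moments
static void cnn_forward(const CnnSpec& spec, CnnParams& P,
                        const mat& X, const uvec& idx, bool train,
                        CnnCache& cc, bool use_dropout) {
  int B = idx.n_elem;
  int nb = spec.n_blocks();
  cc.Ain.assign(nb, {});
  cc.xhat.resize(nb); cc.invstd.resize(nb);
  cc.relu_out.resize(nb); cc.pooled.resize(nb); cc.argmax.resize(nb);

  std::vector<mat> A(B);
  for (int s = 0; s < B; ++s) A[s] = X.row(idx(s));  // (1 x 2000)

  for (int l = 0; l < nb; ++l) {
    int cout = spec.f[l], k = spec.k[l], pool = spec.pool[l];
    int L = A[0].n_cols;
    cc.Ain[l] = A;
    cube Z(cout, L, B);
    for (int s = 0; s < B; ++s) {
      Z.slice(s) = P.W[l] * im2col(A[s], k);
      Z.slice(s).each_col() += P.b[l];
    }
    // batch norm per channel over batch x length
    vec mu(cout), var(cout);
    double cnt = (double)L * B;
    if (train) {
      for (int c = 0; c < cout; ++c) {
        double sm = 0, sq = 0;
        for (int s = 0; s < B; ++s) {
          sm += arma::accu(Z.slice(s).row(c));
          sq += arma::accu(arma::square(Z.slice(s).row(c)));
        }
        mu(c) = sm / cnt;
        var(c) = sq / cnt - mu(c) * mu(c);
        if (var(c) < 0) var(c) = 0;
      }
      P.rmean[l] = (1 - BN_MOMENTUM) * P.rmean[l] + BN_MOMENTUM * mu;
      P.rvar[l] = (1 - BN_MOMENTUM) * P.rvar[l] + BN_MOMENTUM * var;
    } else {
      mu = P.rmean[l];
      var = P.rvar[l];
    }
    vec istd = 1.0 / arma::sqrt(var + BN_EPS);
    cc.invstd[l] = istd;
    cube xhat(cout, L, B), act(cout, L, B);
    for (int s = 0; s < B; ++s) {
      mat zh = Z.slice(s);
      zh.each_col() -= mu;
      zh.each_col() %= istd;
      xhat.slice(s) = zh;
      zh.each_col() %= P.g[l];
      zh.each_col() += P.beta[l];
      act.slice(s) = arma::clamp(zh, 0.0, arma::datum::inf);  // ReLU
    }
    cc.xhat[l] = xhat;
    cc.relu_out[l] = act;
    // max pool
    int Lp = L / pool;
    cube Pl(cout, Lp, B);
    arma::Cube<uword> am(cout, Lp, B);
    for (int s = 0; s < B; ++s) {
      for (int q = 0; q < Lp; ++q) {
        for (int c = 0; c < cout; ++c) {
          uword best = q * pool;
          double bv = act(c, best, s);
          for (int r = 1; r < pool; ++r) {
            if (act(c, q * pool + r, s) > bv) {
              bv = act(c, q * pool + r, s); best = q * pool + r;
            }
          }
          Pl(c, q, s) = bv; am(c, q, s) = best;
        }
      }
    }
    cc.pooled[l] = Pl;
    cc.argmax[l] = am;
    for (int s = 0; s < B; ++s) A[s] = Pl.slice(s);
  }

  int cl = spec.f[nb - 1];
  int Lp = cc.pooled[nb - 1].n_cols;
  cc.gap.set_size(B, cl);
  for (int s = 0; s < B; ++s) {
    cc.gap.row(s) = arma::mean(cc.pooled[nb - 1].slice(s), 1).t();
  }
  if (train && use_dropout && spec.dropout > 0) {
    cc.gap_mask.set_size(B, cl);
    for (uword i = 0; i < cc.gap_mask.n_elem; ++i) {
      cc.gap_mask(i) = (R::unif_rand() >= spec.dropout)
                         ? 1.0 / (1.0 - spec.dropout) : 0.0;
    }
    cc.gap %= cc.gap_mask;
  } else {
    cc.gap_mask.reset();
  }
  cc.logits = cc.gap * P.fcW + P.fcb;
  cc.probs = sigmoid_v(cc.logits);
}

// backward pass; fills gradient structure (same shapes as params)
static void cnn_backward(const CnnSpec& spec, const CnnParams& P,
                         const CnnCache& cc, const vec& dlogit,
                         CnnParams& G) {
  int nb = spec.n_blocks();
  int B = dlogit.n_elem;
  // head
  G.fcW = cc.gap.t() * dlogit;
  G.fcb = arma::accu(dlogit);
  mat dgap = dlogit * P.fcW.t();   // (B x cout)
  if (cc.gap_mask.n_elem > 0) dgap %= cc.gap_mask;

  int Lp_last = cc.pooled[nb - 1].n_cols;
  cube dP(spec.f[nb - 1], Lp_last, B);
  for (int s = 0; s < B; ++s) {
    dP.slice(s) = arma::repmat(dgap.row(s).t() / (double)Lp_last, 1, Lp_last);
  }

  for (int l = nb - 1; l >= 0; --l) {
    int cout = spec.f[l], k = spec.k[l], pool = spec.pool[l];
    int L = cc.relu_out[l].n_cols;
    int Lp = L / pool;
    // unpool
    cube dAct(cout, L, B, arma::fill::zeros);
    for (int s = 0; s < B; ++s) {
      for (int q = 0; q < Lp; ++q) {
        for (int c = 0; c < cout; ++c) {
          dAct(c, cc.argmax[l](c, q, s), s) += dP(c, q, s);
        }
      }
    }
    // ReLU
    for (int s = 0; s < B; ++s) {
      dAct.slice(s) %= arma::conv_to<mat>::from(cc.relu_out[l].slice(s) > 0);
    }
    // batch norm backward (batch statistics)
    double cnt = (double)L * B;
    vec sum_dy(cout, arma::fill::zeros), sum_dyx(cout, arma::fill::zeros);
    for (int s = 0; s < B; ++s) {
      sum_dy += arma::sum(dAct.slice(s), 1);
      sum_dyx += arma::sum(dAct.slice(s) % cc.xhat[l].slice(s), 1);
    }
    G.g[l] = sum_dyx;
    G.beta[l] = sum_dy;
    cube dZ(cout, L, B);
    for (int s = 0; s < B; ++s) {
      mat dxhat = dAct.slice(s);
      dxhat.each_col() %= P.g[l];
      mat t1 = dxhat * cnt;
      t1.each_col() -= sum_dy % P.g[l];
      mat t2 = cc.xhat[l].slice(s);
      t2.each_col() %= sum_dyx % P.g[l];
      mat dz = (t1 - t2) / cnt;
      dz.each_col() %= cc.invstd[l];
      dZ.slice(s) = dz;
    }
    // conv backward
    G.W[l].zeros(P.W[l].n_rows, P.W[l].n_cols);
    G.b[l].zeros(P.b[l].n_elem);
    bool need_dx = l > 0;
    cube dPrev;
    if (need_dx) {
      dPrev.set_size(spec.f[l - 1], L, B);
      dPrev.zeros();
    }
    for (int s = 0; s < B; ++s) {
      mat col = im2col(cc.Ain[l][s], k);
      G.W[l] += dZ.slice(s) * col.t();
      G.b[l] += arma::sum(dZ.slice(s), 1);
      if (need_dx) {
        mat dcol = P.W[l].t() * dZ.slice(s);
        mat dA(spec.f[l - 1], L, arma::fill::zeros);
        col2im_add(dA, dcol, k);
        dPrev.slice(s) = dA;
      }
    }
    if (need_dx) dP = dPrev;
  }
}

// [[Rcpp::export]]
List cnn_train_cpp(const arma::mat& X, const arma::vec& y,
                   const arma::mat& Xtune, const arma::vec& ytune,
                   List spec_list, List train_cfg, List init,
                   const arma::umat& perms) {
  CnnSpec spec;
  spec.k = as<std::vector<int>>(spec_list["kernels"]);
  spec.f = as<std::vector<int>>(spec_list["filters"]);
  spec.pool = as<std::vector<int>>(spec_list["pool"]);
  spec.dropout = as<double>(spec_list["dropout"]);
  double lr = as<double>(train_cfg["learning_rate"]);
  double b1 = as<double>(train_cfg["adam_beta1"]);
  double b2 = as<double>(train_cfg["adam_beta2"]);
  double wd = as<double>(train_cfg["weight_decay"]);
  double w_neg = as<double>(train_cfg["w_neg"]);
  double w_pos = as<double>(train_cfg["w_pos"]);
  int epochs = as<int>(train_cfg["epochs"]);
  int bs = as<int>(train_cfg["batch_size"]);

  CnnParams P = cnn_params_from_list(init, spec);
  CnnParams G = P;  // shapes

  // register trainable parameters (BN running stats are not trained)
  std::vector<mat> pw, gw;  // wrap vecs/scalars as mats for AdamW
  std::vector<mat*> params, grads;
  mat fcWm(P.fcW.n_elem, 1), fcbm(1, 1);
  for (size_t l = 0; l < P.W.size(); ++l) {
    params.push_back(&P.W[l]); grads.push_back(&G.W[l]);
  }
  std::vector<mat> vb(P.b.size()), vg(P.g.size()), vbe(P.beta.size());
  std::vector<mat> gb(P.b.size()), gg(P.g.size()), gbe(P.beta.size());
  for (size_t l = 0; l < P.b.size(); ++l) {
    vb[l] = P.b[l]; vg[l] = P.g[l]; vbe[l] = P.beta[l];
    gb[l] = vb[l]; gg[l] = vg[l]; gbe[l] = vbe[l];
    params.push_back(&vb[l]); grads.push_back(&gb[l]);
    params.push_back(&vg[l]); grads.push_back(&gg[l]);
    params.push_back(&vbe[l]); grads.push_back(&gbe[l]);
  }
  fcWm.col(0) = P.fcW; fcbm(0, 0) = P.fcb;
  mat gfcWm = fcWm, gfcbm = fcbm;
  params.push_back(&fcWm); grads.push_back(&gfcWm);
  params.push_back(&fcbm); grads.push_back(&gfcbm);

  AdamW opt;
  opt.init(params, lr, b1, b2, wd);

  int n = X.n_rows;
  CnnCache cc;
  NumericVector h_loss(epochs), h_tune(epochs);
  List best_params;
  double best_ap = -2.0;
  int best_epoch = 1;

  for (int e = 0; e < epochs; ++e) {
    double ep_loss = 0;
    int nb_batches = 0;
    for (int start = 0; start < n; start += bs) {
      int end = std::min(n, start + bs);
      uvec idx(end - start);
      for (int i = start; i < end; ++i) idx(i - start) = perms(e, i);
      // sync vec params from AdamW-owned mats
      for (size_t l = 0; l < P.b.size(); ++l) {
        P.b[l] = vb[l].col(0); P.g[l] = vg[l].col(0); P.beta[l] = vbe[l].col(0);
      }
      P.fcW = fcWm.col(0); P.fcb = fcbm(0, 0);
      cnn_forward(spec, P, X, idx, true, cc, true);
      vec yb(idx.n_elem);
      for (uword i = 0; i < idx.n_elem; ++i) yb(i) = y(idx(i));
      ep_loss += weighted_bce_loss(cc.probs, yb, w_neg, w_pos);
      ++nb_batches;
      vec w = w_neg + (w_pos - w_neg) * yb;
      vec dlogit = w % (cc.probs - yb) / (double)idx.n_elem;
      cnn_backward(spec, P, cc, dlogit, G);
      for (size_t l = 0; l < P.b.size(); ++l) {
        gb[l].col(0) = G.b[l]; gg[l].col(0) = G.g[l]; gbe[l].col(0) = G.beta[l];
      }
      gfcWm.col(0) = G.fcW; gfcbm(0, 0) = G.fcb;
      opt.step(params, grads);
    }
    for (size_t l = 0; l < P.b.size(); ++l) {
      P.b[l] = vb[l].col(0); P.g[l] = vg[l].col(0); P.beta[l] = vbe[l].col(0);
    }
    P.fcW = fcWm.col(0); P.fcb = fcbm(0, 0);
    h_loss[e] = ep_loss / std::max(1, nb_batches);
    double ap = -1.0;
    if (Xtune.n_rows > 0) {
      uvec all = arma::regspace<uvec>(0, Xtune.n_rows - 1);
      CnnCache tc;
      cnn_forward(spec, P, Xtune, all, false, tc, false);
      ap = average_precision(tc.probs, ytune);
    }
    h_tune[e] = ap;
    // ap < 0 means no usable tune set: fall back to the final epoch
    if (e == 0 || ap > best_ap || ap < 0) {
      best_ap = ap;
      best_epoch = e + 1;
      best_params = cnn_params_to_list(P, spec);
    }
  }
  return List::create(_["params"] = best_params,
                      _["train_loss"] = h_loss,
                      _["tune_auprc"] = h_tune,
                      _["best_epoch"] = best_epoch);
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(const arma::mat& X, List spec_list, List params) {
  CnnSpec spec;
  spec.k = as<std::vector<int>>(spec_list["kernels"]);
  spec.f = as<std::vector<int>>(spec_list["filters"]);
  spec.pool = as<std::vector<int>>(spec_list["pool"]);
  spec.dropout = as<double>(spec_list["dropout"]);
  CnnParams P = cnn_params_from_list(params, spec);
  if (X.n_rows == 0) return vec();
  CnnCache cc;
  uvec all = arma::regspace<uvec>(0, X.n_rows - 1);
  cnn_forward(spec, P, X, all, false, cc, false);
  return cc.probs;
}

// ---------------------------------------------------------------------
// stacked bidirectional LSTM

struct LstmSpec {
  int n_layers, hidden, input_dim, T;
  double dropout = 0.0, clip = 5.0;
};

struct LstmDir {
  mat W, U;       // (Din x 4H), (H x 4H)
  rowvec b;       // (1 x 4H)
};

struct LstmParams {
  std::vector<LstmDir> fwd, bwd;
  vec fcW;
  double fcb = 0.0;
};

static LstmParams lstm_params_from_list(const List& init, const LstmSpec& spec) {
  LstmParams P;
  for (int l = 0; l < spec.n_layers; ++l) {
    std::string s = std::to_string(l + 1);
    LstmDir f, b;
    f.W = as<mat>(init["W_f" + s]); f.U = as<mat>(init["U_f" + s]);
    f.b = as<rowvec>(init["b_f" + s]);
    b.W = as<mat>(init["W_b" + s]); b.U = as<mat>(init["U_b" + s]);
    b.b = as<rowvec>(init["b_b" + s]);
    P.fwd.push_back(f); P.bwd.push_back(b);
  }
  P.fcW = as<vec>(init["fcW"]);
  P.fcb = as<double>(init["fcb"]);
  return P;
}

static List lstm_params_to_list(const LstmParams& P, const LstmSpec& spec) {
  List out;
  for (int l = 0; l < spec.n_layers; ++l) {
    std::string s = std::to_string(l + 1);
    out["W_f" + s] = P.fwd[l].W; out["U_f" + s] = P.fwd[l].U;
    out["b_f" + s] = P.fwd[l].b;
    out["W_b" + s] = P.bwd[l].W; out["U_b" + s] = P.bwd[l].U;
    out["b_b" + s] = P.bwd[l].b;
  }
  out["fcW"] = P.fcW;
  out["fcb"] = P.fcb;
  return out;
}

struct DirCache {
  std::vector<mat> i, f, g, o, c, tc, hprev, cprev;
  std::vector<mat> h;  // outputs indexed by original time
};

// run one direction over the sequence; xs indexed by original time
static void lstm_run_dir(const std::vector<mat>& xs, const LstmDir& D,
                         bool reverse, int H, DirCache& cc) {
  int T = xs.size();
  int B = xs[0].n_rows;
  cc.i.assign(T, {}); cc.f.assign(T, {}); cc.g.assign(T, {});
  cc.o.assign(T, {}); cc.c.assign(T, {}); cc.tc.assign(T, {});
  cc.hprev.assign(T, {}); cc.cprev.assign(T, {});
  cc.h.assign(T, {});
  mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  for (int step = 0; step < T; ++step) {
    int t = reverse ? (T - 1 - step) : step;
    cc.hprev[t] = h; cc.cprev[t] = c;
    mat A = xs[t] * D.W + h * D.U;
    A.each_row() += D.b;
    mat ig = sigmoid_m(A.cols(0, H - 1));
    mat fg = sigmoid_m(A.cols(H, 2 * H - 1));
    mat gg = arma::tanh(A.cols(2 * H, 3 * H - 1));
    mat og = sigmoid_m(A.cols(3 * H, 4 * H - 1));
    c = fg % c + ig % gg;
    mat tc = arma::tanh(c);
    h = og % tc;
    cc.i[t] = ig; cc.f[t] = fg; cc.g[t] = gg; cc.o[t] = og;
    cc.c[t] = c; cc.tc[t] = tc; cc.h[t] = h;
  }
}

// BPTT for one direction. dh_seq: upstream gradient on h at each original
// time. Returns per-time gradient w.r.t. the inputs and accumulates
// parameter gradients.
static void lstm_back_dir(const std::vector<mat>& xs, const LstmDir& D,
                          const DirCache& cc, bool reverse, int H,
                          const std::vector<mat>& dh_seq,
                          LstmDir& Gd, std::vector<mat>& dx_seq) {
  int T = xs.size();
  int B = xs[0].n_rows;
  Gd.W.zeros(D.W.n_rows, D.W.n_cols);
  Gd.U.zeros(D.U.n_rows, D.U.n_cols);
  Gd.b.zeros(D.b.n_elem);
  dx_seq.assign(T, mat(B, D.W.n_rows, arma::fill::zeros));
  mat dh_next(B, H, arma::fill::zeros), dc_next(B, H, arma::fill::zeros);
  for (int step = T - 1; step >= 0; --step) {
    int t = reverse ? (T - 1 - step) : step;
    mat dh = dh_seq[t] + dh_next;
    mat dc = dh % cc.o[t] % (1 - arma::square(cc.tc[t])) + dc_next;
    mat di = dc % cc.g[t];
    mat df = dc % cc.cprev[t];
    mat dg = dc % cc.i[t];
    mat do_ = dh % cc.tc[t];
    mat dA(B, 4 * H);
    dA.cols(0, H - 1) = di % cc.i[t] % (1 - cc.i[t]);
    dA.cols(H, 2 * H - 1) = df % cc.f[t] % (1 - cc.f[t]);
    dA.cols(2 * H, 3 * H - 1) = dg % (1 - arma::square(cc.g[t]));
    dA.cols(3 * H, 4 * H - 1) = do_ % cc.o[t] % (1 - cc.o[t]);
    Gd.W += xs[t].t() * dA;
    Gd.U += cc.hprev[t].t() * dA;
    Gd.b += arma::sum(dA, 0);
    dx_seq[t] = dA * D.W.t();
    dh_next = dA * D.U.t();
    dc_next = dc % cc.f[t];
  }
}

struct LstmCache {
  std::vector<std::vector<mat>> layer_in;        // per layer, per time
  std::vector<DirCache> fcache, bcache;
  mat z;        // (B x 2H) head input
  mat z_mask;
  vec logits, probs;
};

static void lstm_forward(const LstmSpec& spec, const LstmParams& P,
                         const cube& X, const uvec& idx, bool train,
                         LstmCache& cc) {
  int T = spec.T, H = spec.hidden, B = idx.n_elem;
  std::vector<mat> xs(T);
  for (int t = 0; t < T; ++t) {
    xs[t].set_size(B, spec.input_dim);
    for (int s = 0; s < B; ++s) xs[t].row(s) = X.slice(idx(s)).row(t);
  }
  cc.layer_in.assign(spec.n_layers, {});
  cc.fcache.assign(spec.n_layers, {});
  cc.bcache.assign(spec.n_layers, {});
  for (int l = 0; l < spec.n_layers; ++l) {
    cc.layer_in[l] = xs;
    lstm_run_dir(xs, P.fwd[l], false, H, cc.fcache[l]);
    lstm_run_dir(xs, P.bwd[l], true, H, cc.bcache[l]);
    if (l + 1 < spec.n_layers) {
      std::vector<mat> nxt(T);
      for (int t = 0; t < T; ++t) {
        nxt[t] = arma::join_rows(cc.fcache[l].h[t], cc.bcache[l].h[t]);
      }
      xs = nxt;
    }
  }
  int L = spec.n_layers - 1;
  cc.z = arma::join_rows(cc.fcache[L].h[T - 1], cc.bcache[L].h[0]);
  if (train && spec.dropout > 0) {
    cc.z_mask.set_size(cc.z.n_rows, cc.z.n_cols);
    for (uword i = 0; i < cc.z_mask.n_elem; ++i) {
      cc.z_mask(i) = (R::unif_rand() >= spec.dropout)
                       ? 1.0 / (1.0 - spec.dropout) : 0.0;
    }
    cc.z %= cc.z_mask;
  } else {
    cc.z_mask.reset();
  }
  cc.logits = cc.z * P.fcW + P.fcb;
  cc.probs = sigmoid_v(cc.logits);
}

static void lstm_backward(const LstmSpec& spec, const LstmParams& P,
                          const LstmCache& cc, const vec& dlogit,
                          LstmParams& G) {
  int T = spec.T, H = spec.hidden;
  int B = dlogit.n_elem;
  G.fcW = cc.z.t() * dlogit;
  G.fcb = arma::accu(dlogit);
  mat dz = dlogit * P.fcW.t();
  if (cc.z_mask.n_elem > 0) dz %= cc.z_mask;

  // upstream gradient per layer/time, split by direction
  std::vector<mat> dhf(T, mat(B, H, arma::fill::zeros));
  std::vector<mat> dhb(T, mat(B, H, arma::fill::zeros));
  dhf[T - 1] += dz.cols(0, H - 1);
  dhb[0] += dz.cols(H, 2 * H - 1);

  G.fwd.resize(spec.n_layers);
  G.bwd.resize(spec.n_layers);
  for (int l = spec.n_layers - 1; l >= 0; --l) {
    std::vector<mat> dxf, dxb;
    lstm_back_dir(cc.layer_in[l], P.fwd[l], cc.fcache[l], false, H,
                  dhf, G.fwd[l], dxf);
    lstm_back_dir(cc.layer_in[l], P.bwd[l], cc.bcache[l], true, H,
                  dhb, G.bwd[l], dxb);
    if (l > 0) {
      for (int t = 0; t < T; ++t) {
        mat dx = dxf[t] + dxb[t];          // (B x 2H)
        dhf[t] = dx.cols(0, H - 1);
        dhb[t] = dx.cols(H, 2 * H - 1);
      }
    }
  }
}

// [[Rcpp::export]]
List lstm_train_cpp(const arma::cube& X, const arma::vec& y,
                    const arma::cube& Xtune, const arma::vec& ytune,
                    List spec_list, List train_cfg, List init,
                    const arma::umat& perms) {
  LstmSpec spec;
  spec.n_layers = as<int>(spec_list["n_layers"]);
  spec.hidden = as<int>(spec_list["hidden"]);
  spec.dropout = as<double>(spec_list["dropout"]);
  spec.clip = as<double>(spec_list["clip"]);
  spec.T = X.n_rows;
  spec.input_dim = X.n_cols;
  double lr = as<double>(train_cfg["learning_rate"]);
  double b1 = as<double>(train_cfg["adam_beta1"]);
  double b2 = as<double>(train_cfg["adam_beta2"]);
  double wd = as<double>(train_cfg["weight_decay"]);
  double w_neg = as<double>(train_cfg["w_neg"]);
  double w_pos = as<double>(train_cfg["w_pos"]);
  int epochs = as<int>(train_cfg["epochs"]);
  int bs = as<int>(train_cfg["batch_size"]);

  LstmParams P = lstm_params_from_list(init, spec);
  LstmParams G = P;

  std::vector<mat*> params, grads;
  std::vector<mat> bf_hold(spec.n_layers), bb_hold(spec.n_layers);
  std::vector<mat> gbf_hold(spec.n_layers), gbb_hold(spec.n_layers);
  mat fcWm(P.fcW.n_elem, 1), fcbm(1, 1);
  for (int l = 0; l < spec.n_layers; ++l) {
    params.push_back(&P.fwd[l].W); params.push_back(&P.fwd[l].U);
    params.push_back(&P.bwd[l].W); params.push_back(&P.bwd[l].U);
    grads.push_back(&G.fwd[l].W); grads.push_back(&G.fwd[l].U);
    grads.push_back(&G.bwd[l].W); grads.push_back(&G.bwd[l].U);
    bf_hold[l] = mat(P.fwd[l].b.t()); bb_hold[l] = mat(P.bwd[l].b.t());
    gbf_hold[l] = bf_hold[l]; gbb_hold[l] = bb_hold[l];
    params.push_back(&bf_hold[l]); grads.push_back(&gbf_hold[l]);
    params.push_back(&bb_hold[l]); grads.push_back(&gbb_hold[l]);
  }
  fcWm.col(0) = P.fcW; fcbm(0, 0) = P.fcb;
  mat gfcWm = fcWm, gfcbm = fcbm;
  params.push_back(&fcWm); grads.push_back(&gfcWm);
  params.push_back(&fcbm); grads.push_back(&gfcbm);

  AdamW opt;
  opt.init(params, lr, b1, b2, wd);

  int n = X.n_slices;
  LstmCache cc;
  NumericVector h_loss(epochs), h_tune(epochs);
  List best_params;
  double best_ap = -2.0;
  int best_epoch = 1;

  for (int e = 0; e < epochs; ++e) {
    double ep_loss = 0;
    int nb_batches = 0;
    for (int start = 0; start < n; start += bs) {
      int end = std::min(n, start + bs);
      uvec idx(end - start);
      for (int i = start; i < end; ++i) idx(i - start) = perms(e, i);
      for (int l = 0; l < spec.n_layers; ++l) {
        P.fwd[l].b = bf_hold[l].col(0).t();
        P.bwd[l].b = bb_hold[l].col(0).t();
      }
      P.fcW = fcWm.col(0); P.fcb = fcbm(0, 0);
      lstm_forward(spec, P, X, idx, true, cc);
      vec yb(idx.n_elem);
      for (uword i = 0; i < idx.n_elem; ++i) yb(i) = y(idx(i));
      ep_loss += weighted_bce_loss(cc.probs, yb, w_neg, w_pos);
      ++nb_batches;
      vec w = w_neg + (w_pos - w_neg) * yb;
      vec dlogit = w % (cc.probs - yb) / (double)idx.n_elem;
      lstm_backward(spec, P, cc, dlogit, G);
      for (int l = 0; l < spec.n_layers; ++l) {
        gbf_hold[l].col(0) = G.fwd[l].b.t();
        gbb_hold[l].col(0) = G.bwd[l].b.t();
      }
      gfcWm.col(0) = G.fcW; gfcbm(0, 0) = G.fcb;
      clip_grads(grads, spec.clip);
      opt.step(params, grads);
    }
    for (int l = 0; l < spec.n_layers; ++l) {
      P.fwd[l].b = bf_hold[l].col(0).t();
      P.bwd[l].b = bb_hold[l].col(0).t();
    }
    P.fcW = fcWm.col(0); P.fcb = fcbm(0, 0);
    h_loss[e] = ep_loss / std::max(1, nb_batches);
    double ap = -1.0;
    if (Xtune.n_slices > 0) {
      uvec all = arma::regspace<uvec>(0, Xtune.n_slices - 1);
      LstmCache tc;
      lstm_forward(spec, P, Xtune, all, false, tc);
      ap = average_precision(tc.probs, ytune);
    }
    h_tune[e] = ap;
    if (e == 0 || ap > best_ap || ap < 0) {
      best_ap = ap;
      best_epoch = e + 1;
      best_params = lstm_params_to_list(P, spec);
    }
  }
  return List::create(_["params"] = best_params,
                      _["train_loss"] = h_loss,
                      _["tune_auprc"] = h_tune,
                      _["best_epoch"] = best_epoch);
}

// [[Rcpp::export]]
arma::vec lstm_predict_cpp(const arma::cube& X, List spec_list, List params) {
  LstmSpec spec;
  spec.n_layers = as<int>(spec_list["n_layers"]);
  spec.hidden = as<int>(spec_list["hidden"]);
  spec.dropout = as<double>(spec_list["dropout"]);
  spec.clip = as<double>(spec_list["clip"]);
  spec.T = X.n_rows;
  spec.input_dim = X.n_cols;
  LstmParams P = lstm_params_from_list(params, spec);
  if (X.n_slices == 0) return vec();
  LstmCache cc;
  uvec all = arma::regspace<uvec>(0, X.n_slices - 1);
  lstm_forward(spec, P, X, all, false, cc);
  return cc.probs;
}

// [[Rcpp::export]]
double average_precision_cpp(const arma::vec& scores, const arma::vec& labels) {
  return average_precision(scores, labels);
}
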