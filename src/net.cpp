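// CNN-LSTM binary sequence classifier: embedding -> 1-D conv blocks
// (ReLU + max-pool) -> LSTM (configurable readout) -> dense ReLU -> logit.
// Hand-written forward/backward so conv-layer activations and their
// gradients are available for Grad-CAM.
//
// Sequences are processed at their true length (tokens are sliced by the
// per-record length); padding therefore never enters the computation.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

struct NetConfig {
  int vocab, emb;
  std::vector<int> cf, ck, cp; // filters, kernel, pool per conv block
  int lstm, dense;
  double lr, dropout, weight_decay;
  int batch, epochs;
  int pad_idx; // 0-based
  // 0 = final hidden state, 1 = mean over time, 2 = max over time,
  // 3 = concatenated [mean; max], 4 = sum over time
  int readout;
};

static NetConfig read_config(const Rcpp::List& cfg) {
  NetConfig c;
  c.vocab   = Rcpp::as<int>(cfg["vocab"]);
  c.emb     = Rcpp::as<int>(cfg["embedding"]);
  c.cf      = Rcpp::as<std::vector<int>>(cfg["conv_filters"]);
  c.ck      = Rcpp::as<std::vector<int>>(cfg["conv_kernel"]);
  c.cp      = Rcpp::as<std::vector<int>>(cfg["conv_pool"]);
  c.lstm    = Rcpp::as<int>(cfg["lstm_units"]);
  c.dense   = Rcpp::as<int>(cfg["dense_units"]);
  c.lr      = Rcpp::as<double>(cfg["learning_rate"]);
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  c.weight_decay = Rcpp::as<double>(cfg["weight_decay"]);
  c.batch   = Rcpp::as<int>(cfg["batch_size"]);
  c.epochs  = Rcpp::as<int>(cfg["epochs"]);
  c.pad_idx = Rcpp::as<int>(cfg["pad_index"]) - 1;
  std::string ro = Rcpp::as<std::string>(cfg["lstm_readout"]);
  c.readout = (ro == "mean") ? 1 : (ro == "max") ? 2 : (ro == "mean_max") ? 3
              : (ro == "sum") ? 4 : 0;
  if (c.cf.size() == 0) Rcpp::stop("at least one conv block is required");
  for (size_t b = 0; b < c.ck.size(); ++b)
    if (c.ck[b] % 2 == 0) Rcpp::stop("conv kernel widths must be odd");
  return c;
}

struct Params {
  mat E;                   // emb x vocab, PAD column frozen at zero
  std::vector<mat> Wc;     // filters x (k * in_ch)
  std::vector<vec> bc;
  mat Wx, Wh;              // 4H x in, 4H x H
  vec bl;                  // 4H, forget slice init 1
  mat Wd; vec bd;          // dense x H
  rowvec wo; double bo;    // 1 x dense
};

static mat glorot(int r, int cdim, std::mt19937& eng) {
  double s = std::sqrt(6.0 / (r + cdim));
  std::uniform_real_distribution<double> u(-s, s);
  mat m(r, cdim);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = u(eng);
  return m;
}

static Params init_params(const NetConfig& c, std::mt19937& eng) {
  Params p;
  std::uniform_real_distribution<double> ue(-0.5, 0.5);
  p.E.set_size(c.emb, c.vocab);
  for (uword j = 0; j < p.E.n_cols; ++j)
    for (uword i = 0; i < p.E.n_rows; ++i) p.E(i, j) = ue(eng);
  p.E.col(c.pad_idx).zeros();
  int in_ch = c.emb;
  for (size_t b = 0; b < c.cf.size(); ++b) {
    p.Wc.push_back(glorot(c.cf[b], c.ck[b] * in_ch, eng));
    p.bc.push_back(vec(c.cf[b], fill::zeros));
    in_ch = c.cf[b];
  }
  int H = c.lstm;
  p.Wx = glorot(4 * H, in_ch, eng);
  p.Wh = glorot(4 * H, H, eng);
  p.bl = vec(4 * H, fill::zeros);
  p.bl.subvec(H, 2 * H - 1).ones(); // forget-gate bias
  p.Wd = glorot(c.dense, c.readout == 3 ? 2 * H : H, eng);
  p.bd = vec(c.dense, fill::zeros);
  p.wo = glorot(1, c.dense, eng);
  p.bo = 0.0;
  return p;
}

// ---- params <-> R list ----

static Rcpp::List params_to_list(const Params& p) {
  Rcpp::List Wc(p.Wc.size()), bc(p.bc.size());
  for (size_t i = 0; i < p.Wc.size(); ++i) Wc[i] = p.Wc[i];
  for (size_t i = 0; i < p.bc.size(); ++i) bc[i] = p.bc[i];
  return Rcpp::List::create(
    Rcpp::Named("E") = p.E, Rcpp::Named("Wc") = Wc, Rcpp::Named("bc") = bc,
    Rcpp::Named("Wx") = p.Wx, Rcpp::Named("Wh") = p.Wh, Rcpp::Named("bl") = p.bl,
    Rcpp::Named("Wd") = p.Wd, Rcpp::Named("bd") = p.bd,
    Rcpp::Named("wo") = p.wo, Rcpp::Named("bo") = p.bo);
}

static Params params_from_list(const Rcpp::List& l) {
  Params p;
  p.E = Rcpp::as<mat>(l["E"]);
  Rcpp::List Wc = l["Wc"], bc = l["bc"];
  for (int i = 0; i < Wc.size(); ++i) p.Wc.push_back(Rcpp::as<mat>(Wc[i]));
  for (int i = 0; i < bc.size(); ++i) p.bc.push_back(Rcpp::as<vec>(bc[i]));
  p.Wx = Rcpp::as<mat>(l["Wx"]); p.Wh = Rcpp::as<mat>(l["Wh"]);
  p.bl = Rcpp::as<vec>(l["bl"]);
  p.Wd = Rcpp::as<mat>(l["Wd"]); p.bd = Rcpp::as<vec>(l["bd"]);
  p.wo = Rcpp::as<rowvec>(l["wo"]); p.bo = Rcpp::as<double>(l["bo"]);
  return p;
}

// ---- layer primitives ----

static mat im2col(const mat& X, int k) {
  int C = X.n_rows, L = X.n_cols, pad = (k - 1) / 2;
  mat col(k * C, L, fill::zeros);
  for (int j = 0; j < k; ++j) {
    int shift = j - pad;
    int lo = std::max(0, -shift), hi = std::min(L - 1, L - 1 - shift);
    if (lo <= hi)
      col.rows(j * C, (j + 1) * C - 1).cols(lo, hi) = X.cols(lo + shift, hi + shift);
  }
  return col;
}

static mat col2im(const mat& dcol, int k, int C, int L) {
  int pad = (k - 1) / 2;
  mat dX(C, L, fill::zeros);
  for (int j = 0; j < k; ++j) {
    int shift = j - pad;
    int lo = std::max(0, -shift), hi = std::min(L - 1, L - 1 - shift);
    if (lo <= hi)
      dX.cols(lo + shift, hi + shift) += dcol.rows(j * C, (j + 1) * C - 1).cols(lo, hi);
  }
  return dX;
}

static void maxpool(const mat& A, int p, mat& P, umat& AM) {
  int C = A.n_rows, L = A.n_cols, T = (L + p - 1) / p;
  P.set_size(C, T); AM.set_size(C, T);
  for (int t = 0; t < T; ++t) {
    int a = t * p, b = std::min(L, (t + 1) * p) - 1;
    for (int cch = 0; cch < C; ++cch) {
      uword best = a;
      double bv = A(cch, a);
      for (int s = a + 1; s <= b; ++s)
        if (A(cch, s) > bv) { bv = A(cch, s); best = s; }
      P(cch, t) = bv; AM(cch, t) = best;
    }
  }
}

struct Cache {
  ivec tokens;               // 0-based
  mat X0;
  std::vector<mat> conv_in;  // input to each conv block
  std::vector<mat> conv_col; // im2col of conv_in
  std::vector<mat> conv_act; // post-ReLU, pre-pool
  std::vector<mat> pooled;
  std::vector<umat> argmax;
  mat F;                     // LSTM input (channels x T)
  mat gi, gf, gg, go, cs, hs; // gate/state caches (H x T)
  vec h_read, d;
  uvec read_arg; // argmax timestep per unit (max readout)
  vec drop_mask;             // dense dropout mask (already scaled), empty if none
  double logit;
};

static double forward(const Params& p, const NetConfig& c, const ivec& tokens,
                      Cache& K, bool training, std::mt19937* eng) {
  int L = tokens.n_elem;
  K.tokens = tokens;
  K.X0.set_size(c.emb, L);
  for (int t = 0; t < L; ++t) K.X0.col(t) = p.E.col(tokens[t]);

  K.conv_in.clear(); K.conv_col.clear(); K.conv_act.clear();
  K.pooled.clear(); K.argmax.clear();
  mat cur = K.X0;
  for (size_t b = 0; b < p.Wc.size(); ++b) {
    K.conv_in.push_back(cur);
    mat col = im2col(cur, c.ck[b]);
    mat A = p.Wc[b] * col;
    A.each_col() += p.bc[b];
    A.transform([](double v) { return v > 0 ? v : 0.0; });
    K.conv_col.push_back(std::move(col));
    K.conv_act.push_back(A);
    mat P; umat AM;
    maxpool(A, c.cp[b], P, AM);
    K.pooled.push_back(P); K.argmax.push_back(AM);
    cur = K.pooled.back();
  }
  K.F = cur;

  int H = c.lstm, T = K.F.n_cols;
  K.gi.set_size(H, T); K.gf.set_size(H, T); K.gg.set_size(H, T);
  K.go.set_size(H, T); K.cs.set_size(H, T); K.hs.set_size(H, T);
  vec h(H, fill::zeros), cst(H, fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec a = p.Wx * K.F.col(t) + p.Wh * h + p.bl;
    vec i = 1.0 / (1.0 + exp(-a.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + exp(-a.subvec(H, 2 * H - 1)));
    vec g = tanh(a.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + exp(-a.subvec(3 * H, 4 * H - 1)));
    cst = f % cst + i % g;
    h = o % tanh(cst);
    K.gi.col(t) = i; K.gf.col(t) = f; K.gg.col(t) = g; K.go.col(t) = o;
    K.cs.col(t) = cst; K.hs.col(t) = h;
  }
  if (c.readout == 1) {
    K.h_read = mean(K.hs, 1);
  } else if (c.readout == 2) {
    K.h_read = max(K.hs, 1);
    K.read_arg = index_max(K.hs, 1);
  } else if (c.readout == 3) {
    K.h_read = join_cols(vec(mean(K.hs, 1)), vec(max(K.hs, 1)));
    K.read_arg = index_max(K.hs, 1);
  } else if (c.readout == 4) {
    K.h_read = sum(K.hs, 1);
  } else {
    K.h_read = h;
  }

  vec d = p.Wd * K.h_read + p.bd;
  d.transform([](double v) { return v > 0 ? v : 0.0; });
  if (training && c.dropout > 0 && eng) {
    std::uniform_real_distribution<double> u(0.0, 1.0);
    double keep = 1.0 - c.dropout;
    K.drop_mask.set_size(d.n_elem);
    for (uword i = 0; i < d.n_elem; ++i)
      K.drop_mask[i] = (u(*eng) < keep) ? 1.0 / keep : 0.0;
    d %= K.drop_mask;
  } else {
    K.drop_mask.reset();
  }
  K.d = d;
  K.logit = as_scalar(p.wo * d) + p.bo;
  return K.logit;
}

struct Grads {
  mat E;
  std::vector<mat> Wc; std::vector<vec> bc;
  mat Wx, Wh; vec bl;
  mat Wd; vec bd;
  rowvec wo; double bo;
  void zero_like(const Params& p) {
    E = zeros(size(p.E));
    Wc.clear(); bc.clear();
    for (auto& w : p.Wc) Wc.push_back(zeros(size(w)));
    for (auto& b : p.bc) bc.push_back(zeros(size(b)));
    Wx = zeros(size(p.Wx)); Wh = zeros(size(p.Wh)); bl = zeros(size(p.bl));
    Wd = zeros(size(p.Wd)); bd = zeros(size(p.bd));
    wo = zeros<rowvec>(p.wo.n_elem); bo = 0.0;
  }
};

// Backprop from d(logit) = dlogit through dense+LSTM, returning the gradient
// with respect to the last conv block's post-ReLU activation. When G is
// non-null, also accumulates full parameter gradients down to the embedding.
static mat backward(const Params& p, const NetConfig& c, const Cache& K,
                    double dlogit, Grads* G) {
  int H = c.lstm, T = K.F.n_cols;

  vec dd = p.wo.t() * dlogit;
  if (K.drop_mask.n_elem) dd %= K.drop_mask;
  for (uword i = 0; i < dd.n_elem; ++i) if (K.d[i] <= 0) dd[i] = 0;
  if (G) {
    G->wo += dlogit * K.d.t();
    G->bo += dlogit;
    G->Wd += dd * K.h_read.t();
    G->bd += dd;
  }
  vec dh_read = p.Wd.t() * dd;
  vec dh_mean, dh_max;
  if (c.readout == 3) {
    dh_mean = dh_read.subvec(0, H - 1);
    dh_max = dh_read.subvec(H, 2 * H - 1);
  } else if (c.readout == 1 || c.readout == 4) {
    dh_mean = dh_read * (c.readout == 4 ? (double)T : 1.0); // undone below
  } else if (c.readout == 2) {
    dh_max = dh_read;
  }
  vec dh;
  if (c.readout == 0) {
    dh = dh_read;
  } else {
    dh = zeros<vec>(H);
    if (dh_mean.n_elem) dh += dh_mean / T;
    if (dh_max.n_elem)
      for (int u = 0; u < H; ++u)
        if ((int)K.read_arg[u] == T - 1) dh[u] += dh_max[u];
  }
  vec dc(H, fill::zeros);
  mat dF(K.F.n_rows, T, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec i = K.gi.col(t), f = K.gf.col(t), g = K.gg.col(t), o = K.go.col(t);
    vec cst = K.cs.col(t);
    vec tc = tanh(cst);
    vec do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    vec cprev = (t > 0) ? vec(K.cs.col(t - 1)) : vec(H, fill::zeros);
    vec di = dc % g, df = dc % cprev, dg = dc % i;
    vec da(4 * H);
    da.subvec(0, H - 1)         = di % i % (1.0 - i);
    da.subvec(H, 2 * H - 1)     = df % f % (1.0 - f);
    da.subvec(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    da.subvec(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    vec hprev = (t > 0) ? vec(K.hs.col(t - 1)) : vec(H, fill::zeros);
    if (G) {
      G->Wx += da * K.F.col(t).t();
      G->Wh += da * hprev.t();
      G->bl += da;
    }
    dF.col(t) = p.Wx.t() * da;
    dh = p.Wh.t() * da;
    if (t > 0 && c.readout != 0) {
      if (dh_mean.n_elem) dh += dh_mean / T;
      if (dh_max.n_elem)
        for (int u = 0; u < H; ++u)
          if ((int)K.read_arg[u] == t - 1) dh[u] += dh_max[u];
    }
    dc %= f;
  }

  // unpool into last conv activation
  int nb = p.Wc.size();
  mat dP = dF;
  mat dA_last;
  for (int b = nb - 1; b >= 0; --b) {
    const mat& A = K.conv_act[b];
    mat dA(A.n_rows, A.n_cols, fill::zeros);
    const umat& AM = K.argmax[b];
    for (uword t = 0; t < AM.n_cols; ++t)
      for (uword ch = 0; ch < AM.n_rows; ++ch)
        dA(ch, AM(ch, t)) += dP(ch, t);
    if (b == nb - 1) dA_last = dA;
    if (!G) break;
    // through ReLU
    for (uword j = 0; j < dA.n_elem; ++j) if (A[j] <= 0) dA[j] = 0;
    G->Wc[b] += dA * K.conv_col[b].t();
    G->bc[b] += sum(dA, 1);
    mat dcol = p.Wc[b].t() * dA;
    mat dX = col2im(dcol, c.ck[b], K.conv_in[b].n_rows, K.conv_in[b].n_cols);
    dP = dX; // for b-1 this is gradient wrt its pooled output
    if (b == 0) {
      for (uword t = 0; t < K.tokens.n_elem; ++t)
        G->E.col(K.tokens[t]) += dX.col(t);
      G->E.col(c.pad_idx).zeros(); // PAD embedding frozen
    }
  }
  return dA_last;
}

static double bce_loss(double z, double y) {
  // stable log(1+exp(z)) - y z
  return std::max(z, 0.0) - y * z + std::log1p(std::exp(-std::abs(z)));
}

// ---- Adam ----

struct Adam {
  std::vector<mat> m, v; std::vector<vec> mv, vv;
  double mo = 0, vo = 0, ms = 0, vs = 0; // wo handled as mat? use rowvec slots
  rowvec mwo, vwo; double mbo = 0, vbo = 0;
  long t = 0;
  void init(const Params& p) {
    auto z = [](const mat& x) { return zeros(size(x)); };
    m.push_back(z(p.E)); v.push_back(z(p.E));
    for (auto& w : p.Wc) { m.push_back(z(w)); v.push_back(z(w)); }
    m.push_back(z(p.Wx)); v.push_back(z(p.Wx));
    m.push_back(z(p.Wh)); v.push_back(z(p.Wh));
    m.push_back(z(p.Wd)); v.push_back(z(p.Wd));
    for (auto& b : p.bc) { mv.push_back(zeros(size(b))); vv.push_back(zeros(size(b))); }
    mv.push_back(zeros(size(p.bl))); vv.push_back(zeros(size(p.bl)));
    mv.push_back(zeros(size(p.bd))); vv.push_back(zeros(size(p.bd)));
    mwo = zeros<rowvec>(p.wo.n_elem); vwo = zeros<rowvec>(p.wo.n_elem);
  }
  template <typename M>
  void upd(M& w, const M& g, M& mm, M& vv_, double lr, double b1c, double b2c) {
    mm = 0.9 * mm + 0.1 * g;
    vv_ = 0.999 * vv_ + 0.001 * (g % g);
    w -= lr * (mm / b1c) / (sqrt(vv_ / b2c) + 1e-8);
  }
  // Decoupled (AdamW-style) weight decay applied to weight matrices only.
  void decay(Params& p, double lr, double wd, int pad_idx) {
    if (wd <= 0) return;
    double f = lr * wd;
    p.E *= (1.0 - f); p.E.col(pad_idx).zeros();
    for (auto& w : p.Wc) w *= (1.0 - f);
    p.Wx *= (1.0 - f); p.Wh *= (1.0 - f);
    p.Wd *= (1.0 - f); p.wo *= (1.0 - f);
  }
  void step(Params& p, const Grads& g, double lr) {
    ++t;
    double b1c = 1.0 - std::pow(0.9, (double)t);
    double b2c = 1.0 - std::pow(0.999, (double)t);
    size_t i = 0;
    upd(p.E, g.E, m[i], v[i], lr, b1c, b2c); ++i;
    for (size_t b = 0; b < p.Wc.size(); ++b) { upd(p.Wc[b], g.Wc[b], m[i], v[i], lr, b1c, b2c); ++i; }
    upd(p.Wx, g.Wx, m[i], v[i], lr, b1c, b2c); ++i;
    upd(p.Wh, g.Wh, m[i], v[i], lr, b1c, b2c); ++i;
    upd(p.Wd, g.Wd, m[i], v[i], lr, b1c, b2c); ++i;
    size_t j = 0;
    for (size_t b = 0; b < p.bc.size(); ++b) { upd(p.bc[b], g.bc[b], mv[j], vv[j], lr, b1c, b2c); ++j; }
    upd(p.bl, g.bl, mv[j], vv[j], lr, b1c, b2c); ++j;
    upd(p.bd, g.bd, mv[j], vv[j], lr, b1c, b2c); ++j;
    upd(p.wo, g.wo, mwo, vwo, lr, b1c, b2c);
    mbo = 0.9 * mbo + 0.1 * g.bo;
    vbo = 0.999 * vbo + 0.001 * g.bo * g.bo;
    p.bo -= lr * (mbo / b1c) / (std::sqrt(vbo / b2c) + 1e-8);
  }
};

static ivec slice_tokens(const Rcpp::IntegerMatrix& X, int row, int len) {
  ivec t(len);
  for (int j = 0; j < len; ++j) t[j] = X(row, j) - 1; // to 0-based
  return t;
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::IntegerMatrix X, Rcpp::IntegerVector lengths,
                     Rcpp::NumericVector y, Rcpp::List cfg, int seed) {
  NetConfig c = read_config(cfg);
  std::mt19937 eng(static_cast<unsigned>(seed));
  Params p = init_params(c, eng);
  Adam opt; opt.init(p);
  int n = X.nrow();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> ep_loss, ep_acc;
  Cache K;
  for (int e = 0; e < c.epochs; ++e) {
    std::shuffle(order.begin(), order.end(), eng);
    double tot = 0; int correct = 0;
    for (int s = 0; s < n; s += c.batch) {
      int bend = std::min(n, s + c.batch), bs = bend - s;
      Grads G; G.zero_like(p);
      for (int bi = s; bi < bend; ++bi) {
        int i = order[bi];
        ivec tok = slice_tokens(X, i, lengths[i]);
        double z = forward(p, c, tok, K, true, &eng);
        double loss = bce_loss(z, y[i]);
        if (!std::isfinite(loss))
          Rcpp::stop("training diverged (non-finite loss) at epoch %d", e + 1);
        tot += loss;
        double sig = 1.0 / (1.0 + std::exp(-z));
        if ((sig > 0.5 ? 1.0 : 0.0) == y[i]) ++correct;
        backward(p, c, K, sig - y[i], &G);
      }
      double inv = 1.0 / bs;
      G.E *= inv;
      for (auto& w : G.Wc) w *= inv;
      for (auto& b : G.bc) b *= inv;
      G.Wx *= inv; G.Wh *= inv; G.bl *= inv;
      G.Wd *= inv; G.bd *= inv; G.wo *= inv; G.bo *= inv;
      opt.step(p, G, c.lr);
      opt.decay(p, c.lr, c.weight_decay, c.pad_idx);
      Rcpp::checkUserInterrupt();
    }
    ep_loss.push_back(tot / n);
    ep_acc.push_back((double)correct / n);
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = params_to_list(p),
    Rcpp::Named("loss") = ep_loss,
    Rcpp::Named("accuracy") = ep_acc);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_predict(Rcpp::List params, Rcpp::IntegerMatrix X,
                                Rcpp::IntegerVector lengths, Rcpp::List cfg) {
  NetConfig c = read_config(cfg);
  Params p = params_from_list(params);
  int n = X.nrow();
  Rcpp::NumericVector out(n);
  Cache K;
  for (int i = 0; i < n; ++i) {
    ivec tok = slice_tokens(X, i, lengths[i]);
    double z = forward(p, c, tok, K, false, nullptr);
    out[i] = 1.0 / (1.0 + std::exp(-z));
  }
  return out;
}

// Grad-CAM on the last conv block's post-ReLU activation: channel weights
// are position-means of d(logit)/dA; the CAM is the rectified weighted sum.
// Returned at conv resolution (one value per pooled position of that layer).
// [[Rcpp::export]]
Rcpp::List cpp_gradcam(Rcpp::List params, Rcpp::IntegerVector tokens, Rcpp::List cfg) {
  NetConfig c = read_config(cfg);
  Params p = params_from_list(params);
  ivec tok(tokens.size());
  for (int j = 0; j < tokens.size(); ++j) tok[j] = tokens[j] - 1;
  Cache K;
  double z = forward(p, c, tok, K, false, nullptr);
  mat dA = backward(p, c, K, 1.0, nullptr);
  const mat& A = K.conv_act.back();
  vec alpha = mean(dA, 1);
  rowvec cam = alpha.t() * A;
  cam.transform([](double v) { return v > 0 ? v : 0.0; });
  return Rcpp::List::create(
    Rcpp::Named("cam") = Rcpp::NumericVector(cam.begin(), cam.end()),
    Rcpp::Named("score") = 1.0 / (1.0 + std::exp(-z)),
    Rcpp::Named("stride") = (int)std::ceil((double)tok.n_elem / cam.n_elem));
}

// Single-sequence loss and full analytic gradients; used by the
// finite-difference gradient tests.
// [[Rcpp::export]]
double cpp_loss(Rcpp::List params, Rcpp::IntegerVector tokens, double y, Rcpp::List cfg) {
  NetConfig c = read_config(cfg);
  Params p = params_from_list(params);
  ivec tok(tokens.size());
  for (int j = 0; j < tokens.size(); ++j) tok[j] = tokens[j] - 1;
  Cache K;
  double z = forward(p, c, tok, K, false, nullptr);
  return bce_loss(z, y);
}

// [[Rcpp::export]]
Rcpp::List cpp_grads(Rcpp::List params, Rcpp::IntegerVector tokens, double y, Rcpp::List cfg) {
  NetConfig c = read_config(cfg);
  Params p = params_from_list(params);
  ivec tok(tokens.size());
  for (int j = 0; j < tokens.size(); ++j) tok[j] = tokens[j] - 1;
  Cache K;
  double z = forward(p, c, tok, K, false, nullptr);
  double sig = 1.0 / (1.0 + std::exp(-z));
  Grads G; G.zero_like(p);
  backward(p, c, K, sig - y, &G);
  Rcpp::List Wc(G.Wc.size()), bc(G.bc.size());
  for (size_t i = 0; i < G.Wc.size(); ++i) Wc[i] = G.Wc[i];
  for (size_t i = 0; i < G.bc.size(); ++i) bc[i] = G.bc[i];
  return Rcpp::List::create(
    Rcpp::Named("E") = G.E, Rcpp::Named("Wc") = Wc, Rcpp::Named("bc") = bc,
    Rcpp::Named("Wx") = G.Wx, Rcpp::Named("Wh") = G.Wh, Rcpp::Named("bl") = G.bl,
    Rcpp::Named("Wd") = G.Wd, Rcpp::Named("bd") = G.bd,
    Rcpp::Named("wo") = G.wo, Rcpp::Named("bo") = G.bo);
}

// [[Rcpp::export]]
Rcpp::List cpp_init_params(Rcpp::List cfg, int seed) {
  NetConfig c = read_config(cfg);
  std::mt19937 eng(static_cast<unsigned>(seed));
  return params_to_list(init_params(c, eng));
}
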