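// Masked stacked-GRU sequence classifier with two sigmoid heads
// (current-status and next-year status), weighted binary cross-entropy,
// L2 penalty and Adam, trained by back-propagation through time.
//
// Layout conventions:
//   X     : cube (F x T x N)  features per slot per participant
//   mask  : imat (N x T)      1 = observed slot, 0 = masked slot
//   y/w   : mat  (N x T)      labels / sample weights per head
//   params: per layer l, W_l (3H x D), U_l (3H x H), b_l (3H x 1) with gate
//           rows ordered [r; z; c]; then head weight vectors (H x 1) and
//           head biases (1 x 1) for the current and next-year heads.
//
// Masked slots are skipped exactly: the hidden state is carried through
// unchanged and neither the slot's features nor its labels enter the loss
// or any gradient, so perturbing them cannot change training bit-for-bit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct GruDims {
  int layers, hidden, n_features, T;
};

// parameters as a flat vector of matrices: for l in 0..L-1: W,U,b; then
// uc (Hx1), bc (1x1), un (Hx1), bn (1x1)
typedef std::vector<mat> ParamSet;

static ParamSet init_params(const GruDims& d, std::mt19937& rng) {
  ParamSet p;
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  for (int l = 0; l < d.layers; ++l) {
    int D = (l == 0) ? d.n_features : d.hidden;
    double limW = std::sqrt(6.0 / (D + d.hidden));
    double limU = std::sqrt(6.0 / (2.0 * d.hidden));
    mat W(3 * d.hidden, D), U(3 * d.hidden, d.hidden);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = limW * unif(rng);
    for (uword i = 0; i < U.n_elem; ++i) U(i) = limU * unif(rng);
    p.push_back(W);
    p.push_back(U);
    p.push_back(zeros<mat>(3 * d.hidden, 1));
  }
  // heads start at zero: early updates align them with the informative
  // hidden directions instead of fighting a random readout
  p.push_back(zeros<mat>(d.hidden, 1));
  p.push_back(zeros<mat>(1, 1));
  p.push_back(zeros<mat>(d.hidden, 1));
  p.push_back(zeros<mat>(1, 1));
  return p;
}

struct LayerCache {
  std::vector<mat> h;        // T+1 states (H x B), h[0] = 0
  std::vector<mat> r, z, c;  // gate activations per t (zero cols if masked)
  std::vector<uvec> active;  // active column indices per t
};

// forward through all layers for a batch; returns caches per layer
static void forward_batch(const ParamSet& p, const GruDims& d,
                          const cube& X, const imat& mask,
                          const uvec& idx,
                          std::vector<LayerCache>& caches,
                          std::vector<std::vector<mat>>& inputs) {
  int B = idx.n_elem, H = d.hidden, T = d.T;
  caches.assign(d.layers, LayerCache());
  inputs.assign(d.layers, std::vector<mat>());
  // layer-0 inputs
  std::vector<mat> in0(T);
  for (int t = 0; t < T; ++t) {
    mat xt(d.n_features, B);
    for (int j = 0; j < B; ++j) xt.col(j) = X.slice(idx(j)).col(t);
    in0[t] = xt;
  }
  std::vector<mat> cur = in0;
  for (int l = 0; l < d.layers; ++l) {
    const mat& W = p[3 * l], &U = p[3 * l + 1], &b = p[3 * l + 2];
    LayerCache& cc = caches[l];
    inputs[l] = cur;
    cc.h.assign(T + 1, zeros<mat>(H, B));
    cc.r.assign(T, zeros<mat>(H, B));
    cc.z.assign(T, zeros<mat>(H, B));
    cc.c.assign(T, zeros<mat>(H, B));
    cc.active.assign(T, uvec());
    std::vector<mat> out(T);
    for (int t = 0; t < T; ++t) {
      std::vector<uword> act;
      for (int j = 0; j < B; ++j)
        if (mask(idx(j), t) == 1) act.push_back(j);
      uvec a = conv_to<uvec>::from(act);
      cc.active[t] = a;
      mat hnew = cc.h[t];
      if (a.n_elem > 0) {
        mat Xa = cur[t].cols(a);
        mat ha = cc.h[t].cols(a);
        mat pre = W * Xa;
        pre.each_col() += b.col(0);
        mat rec_rz = U.rows(0, 2 * H - 1) * ha;
        mat r = sigm(pre.rows(0, H - 1) + rec_rz.rows(0, H - 1));
        mat z = sigm(pre.rows(H, 2 * H - 1) + rec_rz.rows(H, 2 * H - 1));
        mat cg = tanh(pre.rows(2 * H, 3 * H - 1) +
                      U.rows(2 * H, 3 * H - 1) * (r % ha));
        mat hn = (1.0 - z) % ha + z % cg;
        for (uword k = 0; k < a.n_elem; ++k) {
          cc.r[t].col(a(k)) = r.col(k);
          cc.z[t].col(a(k)) = z.col(k);
          cc.c[t].col(a(k)) = cg.col(k);
          hnew.col(a(k)) = hn.col(k);
        }
      }
      cc.h[t + 1] = hnew;
      out[t] = hnew;
    }
    cur = out;
  }
}

// loss + head logit gradients for a batch; returns weighted BCE sum and
// fills dlogit matrices (H-agnostic, (B x T) per head); wsum is batch
// weight total used for normalisation
static double batch_loss(const ParamSet& p, const GruDims& d,
                         const std::vector<LayerCache>& caches,
                         const mat& y_cur, const mat& y_next,
                         const mat& w_cur, const mat& w_next,
                         const uvec& idx,
                         mat& dlc, mat& dln, double& wsum) {
  int B = idx.n_elem, T = d.T, H = d.hidden;
  const mat& uc = p[3 * d.layers], &bc = p[3 * d.layers + 1];
  const mat& un = p[3 * d.layers + 2], &bn = p[3 * d.layers + 3];
  const LayerCache& top = caches[d.layers - 1];
  dlc = zeros<mat>(B, T);
  dln = zeros<mat>(B, T);
  wsum = 0.0;
  for (int t = 0; t < T; ++t)
    for (uword k = 0; k < top.active[t].n_elem; ++k) {
      uword j = top.active[t](k);
      uword i = idx(j);
      wsum += w_cur(i, t) + w_next(i, t);
    }
  if (wsum <= 0) wsum = 1.0;
  double loss = 0.0;
  const double eps = 1e-12;
  for (int t = 0; t < T; ++t) {
    const uvec& a = top.active[t];
    for (uword k = 0; k < a.n_elem; ++k) {
      uword j = a(k);
      uword i = idx(j);
      vec h = top.h[t + 1].col(j).head(H);
      double pc = 1.0 / (1.0 + std::exp(-(dot(uc.col(0), h) + bc(0, 0))));
      double pn = 1.0 / (1.0 + std::exp(-(dot(un.col(0), h) + bn(0, 0))));
      double wc = w_cur(i, t), wn = w_next(i, t);
      if (wc > 0) {
        double yc = y_cur(i, t);
        loss += -wc * (yc * std::log(pc + eps) + (1 - yc) * std::log(1 - pc + eps));
        dlc(j, t) = wc * (pc - yc) / wsum;
      }
      if (wn > 0) {
        double yn = y_next(i, t);
        loss += -wn * (yn * std::log(pn + eps) + (1 - yn) * std::log(1 - pn + eps));
        dln(j, t) = wn * (pn - yn) / wsum;
      }
    }
  }
  return loss / wsum;
}

// full backward pass; returns gradients in the same layout as params
static ParamSet backward_batch(const ParamSet& p, const GruDims& d,
                               const std::vector<LayerCache>& caches,
                               const std::vector<std::vector<mat>>& inputs,
                               const mat& dlc, const mat& dln,
                               const imat& mask, const uvec& idx) {
  int B = idx.n_elem, H = d.hidden, T = d.T, L = d.layers;
  ParamSet g;
  for (size_t q = 0; q < p.size(); ++q) g.push_back(zeros<mat>(p[q].n_rows, p[q].n_cols));
  const mat& uc = p[3 * L], &un = p[3 * L + 2];
  mat& guc = g[3 * L]; mat& gbc = g[3 * L + 1];
  mat& gun = g[3 * L + 2]; mat& gbn = g[3 * L + 3];

  // head gradients and dh injections on the top layer
  const LayerCache& top = caches[L - 1];
  std::vector<mat> dtop(T, zeros<mat>(H, B));
  for (int t = 0; t < T; ++t) {
    const uvec& a = top.active[t];
    for (uword k = 0; k < a.n_elem; ++k) {
      uword j = a(k);
      double gc = dlc(j, t), gn = dln(j, t);
      if (gc != 0.0 || gn != 0.0) {
        vec h = top.h[t + 1].col(j);
        guc.col(0) += gc * h;
        gbc(0, 0) += gc;
        gun.col(0) += gn * h;
        gbn(0, 0) += gn;
        dtop[t].col(j) += gc * uc.col(0) + gn * un.col(0);
      }
    }
  }

  // BPTT per layer, top to bottom; dinput becomes dh injection one below
  std::vector<mat> dinject = dtop;
  for (int l = L - 1; l >= 0; --l) {
    const mat& W = p[3 * l], &U = p[3 * l + 1];
    mat& gW = g[3 * l]; mat& gU = g[3 * l + 1]; mat& gb = g[3 * l + 2];
    const LayerCache& cc = caches[l];
    std::vector<mat> dlower(T, zeros<mat>((l == 0) ? d.n_features : H, B));
    mat dh = zeros<mat>(H, B);
    for (int t = T - 1; t >= 0; --t) {
      dh += dinject[t];
      const uvec& a = cc.active[t];
      if (a.n_elem == 0) continue;  // dh carries to t-1 unchanged
      mat dha = dh.cols(a);
      mat ha = cc.h[t].cols(a);
      mat r = cc.r[t].cols(a), z = cc.z[t].cols(a), cg = cc.c[t].cols(a);
      mat da_z = dha % (cg - ha) % z % (1.0 - z);
      mat da_c = dha % z % (1.0 - cg % cg);
      mat Uc_daC = U.rows(2 * H, 3 * H - 1).t() * da_c;
      mat da_r = (Uc_daC % ha) % r % (1.0 - r);
      mat dh_prev = dha % (1.0 - z)
        + U.rows(0, H - 1).t() * da_r
        + U.rows(H, 2 * H - 1).t() * da_z
        + Uc_daC % r;
      mat Xa = inputs[l][t].cols(a);
      mat da_all = join_cols(da_r, join_cols(da_z, da_c));
      gW += da_all * Xa.t();
      gU.rows(0, H - 1) += da_r * ha.t();
      gU.rows(H, 2 * H - 1) += da_z * ha.t();
      gU.rows(2 * H, 3 * H - 1) += da_c * (r % ha).t();
      gb.col(0) += sum(da_all, 1);
      mat dx = W.t() * da_all;
      for (uword k = 0; k < a.n_elem; ++k) {
        dlower[t].col(a(k)) = dx.col(k);
        dh.col(a(k)) = dh_prev.col(k);
      }
    }
    dinject = dlower;
  }
  return g;
}

static void add_l2(const ParamSet& p, ParamSet& g, const GruDims& d, double l2) {
  if (l2 <= 0) return;
  for (int l = 0; l < d.layers; ++l) {
    g[3 * l] += 2.0 * l2 * p[3 * l];
    g[3 * l + 1] += 2.0 * l2 * p[3 * l + 1];
  }
  g[3 * d.layers] += 2.0 * l2 * p[3 * d.layers];
  g[3 * d.layers + 2] += 2.0 * l2 * p[3 * d.layers + 2];
}

static double l2_penalty(const ParamSet& p, const GruDims& d, double l2) {
  if (l2 <= 0) return 0.0;
  double s = 0.0;
  for (int l = 0; l < d.layers; ++l)
    s += accu(square(p[3 * l])) + accu(square(p[3 * l + 1]));
  s += accu(square(p[3 * d.layers])) + accu(square(p[3 * d.layers + 2]));
  return l2 * s;
}

static ParamSet params_from_list(Rcpp::List lst) {
  ParamSet p;
  for (int i = 0; i < lst.size(); ++i)
    p.push_back(Rcpp::as<mat>(lst[i]));
  return p;
}

// [[Rcpp::export]]
Rcpp::List gru_train_cpp(const arma::cube& X, const arma::imat& mask,
                         const arma::mat& y_cur, const arma::mat& y_next,
                         const arma::mat& w_cur, const arma::mat& w_next,
                         int layers, int hidden, double l2, double lr,
                         int epochs, int batch, int seed,
                         Rcpp::Nullable<Rcpp::List> init = R_NilValue) {
  GruDims d;
  d.layers = layers; d.hidden = hidden;
  d.n_features = X.n_rows; d.T = X.n_cols;
  int N = X.n_slices;
  std::mt19937 rng(seed);
  ParamSet p = init.isNotNull() ? params_from_list(Rcpp::List(init))
                                : init_params(d, rng);
  ParamSet m, v;
  for (size_t q = 0; q < p.size(); ++q) {
    m.push_back(zeros<mat>(p[q].n_rows, p[q].n_cols));
    v.push_back(zeros<mat>(p[q].n_rows, p[q].n_cols));
  }
  double b1 = 0.9, b2 = 0.999, adeps = 1e-8;
  long step = 0;
  std::vector<double> history;
  std::vector<uword> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0; int nb = 0;
    for (int s0 = 0; s0 < N; s0 += batch) {
      int s1 = std::min(N, s0 + batch);
      uvec idx(s1 - s0);
      for (int i = s0; i < s1; ++i) idx(i - s0) = order[i];
      std::vector<LayerCache> caches;
      std::vector<std::vector<mat>> inputs;
      forward_batch(p, d, X, mask, idx, caches, inputs);
      mat dlc, dln; double wsum;
      double loss = batch_loss(p, d, caches, y_cur, y_next, w_cur, w_next,
                               idx, dlc, dln, wsum);
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d", e + 1);
      ParamSet g = backward_batch(p, d, caches, inputs, dlc, dln, mask, idx);
      add_l2(p, g, d, l2);
      ++step;
      double c1 = 1.0 - std::pow(b1, (double)step);
      double c2 = 1.0 - std::pow(b2, (double)step);
      for (size_t q = 0; q < p.size(); ++q) {
        m[q] = b1 * m[q] + (1.0 - b1) * g[q];
        v[q] = b2 * v[q] + (1.0 - b2) * square(g[q]);
        p[q] -= lr * (m[q] / c1) / (sqrt(v[q] / c2) + adeps);
      }
      ep_loss += loss + l2_penalty(p, d, l2);
      ++nb;
    }
    history.push_back(ep_loss / std::max(nb, 1));
    if (e % 20 == 0) Rcpp::checkUserInterrupt();
  }
  Rcpp::List plist(p.size());
  for (size_t q = 0; q < p.size(); ++q) plist[q] = p[q];
  return Rcpp::List::create(Rcpp::Named("params") = plist,
                            Rcpp::Named("loss_history") = history);
}

// [[Rcpp::export]]
arma::cube gru_predict_cpp(Rcpp::List params, const arma::cube& X,
                           const arma::imat& mask, int layers, int hidden) {
  GruDims d;
  d.layers = layers; d.hidden = hidden;
  d.n_features = X.n_rows; d.T = X.n_cols;
  int N = X.n_slices, T = d.T;
  ParamSet p = params_from_list(params);
  uvec idx = regspace<uvec>(0, N - 1);
  std::vector<LayerCache> caches;
  std::vector<std::vector<mat>> inputs;
  forward_batch(p, d, X, mask, idx, caches, inputs);
  const mat& uc = p[3 * layers], &bc = p[3 * layers + 1];
  const mat& un = p[3 * layers + 2], &bn = p[3 * layers + 3];
  cube out(N, T, 2);
  const LayerCache& top = caches[layers - 1];
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < N; ++i) {
      vec h = top.h[t + 1].col(i);
      out(i, t, 0) = 1.0 / (1.0 + std::exp(-(dot(uc.col(0), h) + bc(0, 0))));
      out(i, t, 1) = 1.0 / (1.0 + std::exp(-(dot(un.col(0), h) + bn(0, 0))));
    }
  return out;
}

// [[Rcpp::export]]
double gru_loss_cpp(Rcpp::List params, const arma::cube& X,
                    const arma::imat& mask,
                    const arma::mat& y_cur, const arma::mat& y_next,
                    const arma::mat& w_cur, const arma::mat& w_next,
                    int layers, int hidden, double l2) {
  GruDims d;
  d.layers = layers; d.hidden = hidden;
  d.n_features = X.n_rows; d.T = X.n_cols;
  int N = X.n_slices;
  ParamSet p = params_from_list(params);
  uvec idx = regspace<uvec>(0, N - 1);
  std::vector<LayerCache> caches;
  std::vector<std::vector<mat>> inputs;
  forward_batch(p, d, X, mask, idx, caches, inputs);
  mat dlc, dln; double wsum;
  double loss = batch_loss(p, d, caches, y_cur, y_next, w_cur, w_next,
                           idx, dlc, dln, wsum);
  return loss + l2_penalty(p, d, l2);
}

// [[Rcpp::export]]
Rcpp::List gru_gradients_cpp(Rcpp::List params, const arma::cube& X,
                             const arma::imat& mask,
                             const arma::mat& y_cur, const arma::mat& y_next,
                             const arma::mat& w_cur, const arma::mat& w_next,
                             int layers, int hidden, double l2) {
  GruDims d;
  d.layers = layers; d.hidden = hidden;
  d.n_features = X.n_rows; d.T = X.n_cols;
  int N = X.n_slices;
  ParamSet p = params_from_list(params);
  uvec idx = regspace<uvec>(0, N - 1);
  std::vector<LayerCache> caches;
  std::vector<std::vector<mat>> inputs;
  forward_batch(p, d, X, mask, idx, caches, inputs);
  mat dlc, dln; double wsum;
  batch_loss(p, d, caches, y_cur, y_next, w_cur, w_next, idx, dlc, dln, wsum);
  ParamSet g = backward_batch(p, d, caches, inputs, dlc, dln, mask, idx);
  add_l2(p, g, d, l2);
  Rcpp::List glist(g.size());
  for (size_t q = 0; q < g.size(); ++q) glist[q] = g[q];
  return glist;
}
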