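// Two-layer GRU sequence regressor with an FC + linear head, trained by
// Adam on MAE loss. Gate layout follows the common reset/update/new-gate
// convention with separate input and hidden biases, so the parameter count
// for input dimension d is
//   3(d*h + h^2 + 2h) + 3(h*h + h^2 + 2h) + (h*f + f) + (f + 1).
// All randomness (init, batch shuffling, dropout) comes from a private
// 64-bit RNG seeded explicitly: results are bit-reproducible for a given
// seed and independent of R's RNG state.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// splitmix64-based generator: deterministic across platforms, unlike
// std::shuffle / std::uniform_*_distribution.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uword unif_int(uword n) { return static_cast<uword>(unif() * n) % n; }
  void shuffle(std::vector<uword>& v) {
    for (uword i = v.size(); i > 1; --i) std::swap(v[i - 1], v[unif_int(i)]);
  }
};

struct Params {
  mat Wi1, Wh1, bi1, bh1;  // layer 1: (3h x d), (3h x h), (3h x 1), (3h x 1)
  mat Wi2, Wh2, bi2, bh2;  // layer 2: input dim h
  mat Wfc, bfc;            // (f x h), (f x 1)
  mat Wout, bout;          // (1 x f), (1 x 1)
  std::vector<mat*> all() {
    return {&Wi1, &Wh1, &bi1, &bh1, &Wi2, &Wh2, &bi2, &bh2,
            &Wfc, &bfc, &Wout, &bout};
  }
  std::vector<mat*> head() { return {&Wfc, &bfc, &Wout, &bout}; }
};

Params from_list(const Rcpp::List& L) {
  Params p;
  p.Wi1 = Rcpp::as<mat>(L["Wi1"]); p.Wh1 = Rcpp::as<mat>(L["Wh1"]);
  p.bi1 = Rcpp::as<mat>(L["bi1"]); p.bh1 = Rcpp::as<mat>(L["bh1"]);
  p.Wi2 = Rcpp::as<mat>(L["Wi2"]); p.Wh2 = Rcpp::as<mat>(L["Wh2"]);
  p.bi2 = Rcpp::as<mat>(L["bi2"]); p.bh2 = Rcpp::as<mat>(L["bh2"]);
  p.Wfc = Rcpp::as<mat>(L["Wfc"]); p.bfc = Rcpp::as<mat>(L["bfc"]);
  p.Wout = Rcpp::as<mat>(L["Wout"]); p.bout = Rcpp::as<mat>(L["bout"]);
  return p;
}

template <typename T>
Rcpp::List to_list(const T& p) {
  return Rcpp::List::create(
      Rcpp::Named("Wi1") = p.Wi1, Rcpp::Named("Wh1") = p.Wh1,
      Rcpp::Named("bi1") = p.bi1, Rcpp::Named("bh1") = p.bh1,
      Rcpp::Named("Wi2") = p.Wi2, Rcpp::Named("Wh2") = p.Wh2,
      Rcpp::Named("bi2") = p.bi2, Rcpp::Named("bh2") = p.bh2,
      Rcpp::Named("Wfc") = p.Wfc, Rcpp::Named("bfc") = p.bfc,
      Rcpp::Named("Wout") = p.Wout, Rcpp::Named("bout") = p.bout);
}

mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Caches for one GRU layer over a batch, needed for backprop through time.
struct LayerCache {
  cube R, Z, N, HH, Hprev;  // each (h x B x T)
  LayerCache(uword h, uword B, uword T)
      : R(h, B, T), Z(h, B, T), N(h, B, T), HH(h, B, T), Hprev(h, B, T) {}
};

// Forward pass of one GRU layer for timestep input x (in_dim x B).
mat gru_step(const mat& Wi, const mat& Wh, const mat& bi, const mat& bh,
             const mat& x, const mat& h_prev, uword h, LayerCache* cache,
             uword t) {
  mat Ai = Wi * x;  Ai.each_col() += bi.col(0);
  mat Ah = Wh * h_prev;  Ah.each_col() += bh.col(0);
  mat r = sigmoid(Ai.rows(0, h - 1) + Ah.rows(0, h - 1));
  mat z = sigmoid(Ai.rows(h, 2 * h - 1) + Ah.rows(h, 2 * h - 1));
  mat hh = Ah.rows(2 * h, 3 * h - 1);
  mat n = tanh(Ai.rows(2 * h, 3 * h - 1) + r % hh);
  mat hnew = (1.0 - z) % n + z % h_prev;
  if (cache) {
    cache->R.slice(t) = r; cache->Z.slice(t) = z; cache->N.slice(t) = n;
    cache->HH.slice(t) = hh; cache->Hprev.slice(t) = h_prev;
  }
  return hnew;
}

// Full forward over a batch. X is (d x T x n); idx selects samples.
// Returns predictions (1 x B); fills caches when provided.
mat forward_batch(const cube& X, const std::vector<uword>& idx,
                  const Params& p, LayerCache* c1, LayerCache* c2,
                  cube* H1seq, mat* Fpre, mat* Fpost, mat* H2last,
                  const mat* drop_mask) {
  const uword h = p.Wh1.n_cols, T = X.n_cols, B = idx.size();
  mat h1(h, B, fill::zeros), h2(h, B, fill::zeros);
  mat xt(X.n_rows, B);
  for (uword t = 0; t < T; ++t) {
    for (uword b = 0; b < B; ++b) xt.col(b) = X.slice(idx[b]).col(t);
    h1 = gru_step(p.Wi1, p.Wh1, p.bi1, p.bh1, xt, h1, h, c1, t);
    if (H1seq) H1seq->slice(t) = h1;
    h2 = gru_step(p.Wi2, p.Wh2, p.bi2, p.bh2, h1, h2, h, c2, t);
  }
  mat fpre = p.Wfc * h2;  fpre.each_col() += p.bfc.col(0);
  mat f = clamp(fpre, 0.0, datum::inf);  // ReLU
  if (drop_mask) f %= *drop_mask;        // inverted dropout (training only)
  if (Fpre) *Fpre = fpre;
  if (Fpost) *Fpost = f;
  if (H2last) *H2last = h2;
  mat out = p.Wout * f;  out.each_col() += p.bout.col(0);
  return out;
}

// Backward through one GRU layer. dH_ext holds the external gradient
// arriving at each timestep's hidden state (zeros where none). Xin gives the
// layer inputs per timestep ((in_dim x B) slices). Accumulates parameter
// gradients into g and returns d(input) per timestep in dXin.
void gru_backward(const mat& Wi, const mat& Wh, const LayerCache& c,
                  const cube& Xin, const cube& dH_ext, uword h,
                  mat& dWi, mat& dWh, mat& dbi, mat& dbh, cube& dXin) {
  const uword T = Xin.n_slices, B = Xin.n_cols;
  mat dh_next(h, B, fill::zeros);
  for (uword t = T; t-- > 0;) {
    mat dh = dh_next + dH_ext.slice(t);
    const mat& r = c.R.slice(t);  const mat& z = c.Z.slice(t);
    const mat& n = c.N.slice(t);  const mat& hh = c.HH.slice(t);
    const mat& hp = c.Hprev.slice(t);
    mat dn = dh % (1.0 - z);
    mat dz = dh % (hp - n);
    mat dhp = dh % z;
    mat da_n = dn % (1.0 - n % n);
    mat dr = da_n % hh;
    mat dhh = da_n % r;
    mat da_r = dr % r % (1.0 - r);
    mat da_z = dz % z % (1.0 - z);
    mat da_i = join_cols(da_r, join_cols(da_z, da_n));
    mat da_h = join_cols(da_r, join_cols(da_z, dhh));
    dWi += da_i * Xin.slice(t).t();
    dWh += da_h * hp.t();
    dbi += sum(da_i, 1);
    dbh += sum(da_h, 1);
    dXin.slice(t) = Wi.t() * da_i;
    dh_next = dhp + Wh.t() * da_h;
  }
}

struct Grads {
  mat Wi1, Wh1, bi1, bh1, Wi2, Wh2, bi2, bh2, Wfc, bfc, Wout, bout;
  explicit Grads(const Params& p) {
    Wi1 = zeros(size(p.Wi1)); Wh1 = zeros(size(p.Wh1));
    bi1 = zeros(size(p.bi1)); bh1 = zeros(size(p.bh1));
    Wi2 = zeros(size(p.Wi2)); Wh2 = zeros(size(p.Wh2));
    bi2 = zeros(size(p.bi2)); bh2 = zeros(size(p.bh2));
    Wfc = zeros(size(p.Wfc)); bfc = zeros(size(p.bfc));
    Wout = zeros(size(p.Wout)); bout = zeros(size(p.bout));
  }
  std::vector<mat*> all() {
    return {&Wi1, &Wh1, &bi1, &bh1, &Wi2, &Wh2, &bi2, &bh2,
            &Wfc, &bfc, &Wout, &bout};
  }
  std::vector<mat*> head() { return {&Wfc, &bfc, &Wout, &bout}; }
};

// MAE loss and full gradient for a batch; dropout mask optional.
double loss_and_grad(const cube& X, const vec& y,
                     const std::vector<uword>& idx, const Params& p,
                     const mat* drop_mask, Grads& g, bool backbone_too) {
  const uword h = p.Wh1.n_cols, T = X.n_cols, B = idx.size(), d = X.n_rows;
  LayerCache c1(h, B, T), c2(h, B, T);
  cube H1seq(h, B, T);
  mat fpre, fpost, h2last;
  mat out = forward_batch(X, idx, p, &c1, &c2, &H1seq, &fpre, &fpost,
                          &h2last, drop_mask);
  rowvec yb(B);
  for (uword b = 0; b < B; ++b) yb(b) = y(idx[b]);
  rowvec err = out.row(0) - yb;
  double loss = mean(abs(err));
  rowvec dout = sign(err) / static_cast<double>(B);

  g.Wout += dout * fpost.t();  // (1 x f)
  g.bout(0, 0) += accu(dout);
  mat df = p.Wout.t() * dout;          // (f x B)
  if (drop_mask) df %= *drop_mask;
  mat da_fc = df % conv_to<mat>::from(fpre > 0.0);
  g.Wfc += da_fc * h2last.t();
  g.bfc += sum(da_fc, 1);
  if (!backbone_too) return loss;

  cube dH2(h, B, T, fill::zeros);
  dH2.slice(T - 1) = p.Wfc.t() * da_fc;
  cube dH1(h, B, T);
  gru_backward(p.Wi2, p.Wh2, c2, H1seq, dH2, h,
               g.Wi2, g.Wh2, g.bi2, g.bh2, dH1);
  cube Xin(d, B, T);
  for (uword t = 0; t < T; ++t)
    for (uword b = 0; b < B; ++b) Xin.slice(t).col(b) = X.slice(idx[b]).col(t);
  cube dX(d, B, T);
  gru_backward(p.Wi1, p.Wh1, c1, Xin, dH1, h,
               g.Wi1, g.Wh1, g.bi1, g.bh1, dX);
  return loss;
}

struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(std::vector<mat*> ps) {
    for (auto* p : ps) { m.push_back(zeros(size(*p))); v.push_back(zeros(size(*p))); }
  }
  void step(std::vector<mat*> ps, std::vector<mat*> gs, double lr) {
    ++t;
    double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * (*gs[i]);
      v[i] = b2 * v[i] + (1.0 - b2) * square(*gs[i]);
      *ps[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

vec predict_all(const cube& X, const Params& p) {
  const uword n = X.n_slices;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  mat out = forward_batch(X, idx, p, nullptr, nullptr, nullptr, nullptr,
                          nullptr, nullptr, nullptr);
  return out.row(0).t();
}

double mae_of(const vec& yhat, const vec& y) { return mean(abs(yhat - y)); }

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_gru_init(int input_dim, int hidden, int fc, uint64_t seed) {
  Rng rng(seed);
  auto runif_mat = [&](uword r, uword c, double k) {
    mat M(r, c);
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i) M(i, j) = (2.0 * rng.unif() - 1.0) * k;
    return M;
  };
  double k1 = 1.0 / std::sqrt(static_cast<double>(hidden));
  double kf = 1.0 / std::sqrt(static_cast<double>(fc));
  Params p;
  p.Wi1 = runif_mat(3 * hidden, input_dim, k1);
  p.Wh1 = runif_mat(3 * hidden, hidden, k1);
  p.bi1 = runif_mat(3 * hidden, 1, k1);
  p.bh1 = runif_mat(3 * hidden, 1, k1);
  p.Wi2 = runif_mat(3 * hidden, hidden, k1);
  p.Wh2 = runif_mat(3 * hidden, hidden, k1);
  p.bi2 = runif_mat(3 * hidden, 1, k1);
  p.bh2 = runif_mat(3 * hidden, 1, k1);
  p.Wfc = runif_mat(fc, hidden, k1);
  p.bfc = runif_mat(fc, 1, k1);
  p.Wout = runif_mat(1, fc, kf);
  p.bout = runif_mat(1, 1, kf);
  return to_list(p);
}

// [[Rcpp::export]]
arma::vec cpp_gru_predict(const arma::cube& X, const Rcpp::List& params) {
  Params p = from_list(params);
  return predict_all(X, p);
}

// Last hidden state of the second GRU layer for every sample: the frozen
// "backbone" representation used by per-subject head fine-tuning.
// [[Rcpp::export]]
arma::mat cpp_gru_backbone(const arma::cube& X, const Rcpp::List& params) {
  Params p = from_list(params);
  const uword n = X.n_slices;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  mat h2last;
  forward_batch(X, idx, p, nullptr, nullptr, nullptr, nullptr, nullptr,
                &h2last, nullptr);
  return h2last;  // (h x n)
}

// Loss + analytic gradient on the full set, no dropout: the hook for
// finite-difference gradient verification.
// [[Rcpp::export]]
Rcpp::List cpp_gru_loss_grad(const arma::cube& X, const arma::vec& y,
                             const Rcpp::List& params) {
  Params p = from_list(params);
  Grads g(p);
  std::vector<uword> idx(X.n_slices);
  for (uword i = 0; i < idx.size(); ++i) idx[i] = i;
  double loss = loss_and_grad(X, y, idx, p, nullptr, g, true);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = to_list(g));
}

// [[Rcpp::export]]
Rcpp::List cpp_gru_train(const arma::cube& X, const arma::vec& y,
                         const arma::cube& Xdev, const arma::vec& ydev,
                         const Rcpp::List& params0, int epochs,
                         int batch_size, double lr, double dropout,
                         uint64_t seed, bool freeze_backbone) {
  Params p = from_list(params0);
  Rng rng(seed);
  const uword n = X.n_slices;
  const uword fdim = p.Wfc.n_rows;
  Adam adam;
  std::vector<mat*> tensors = freeze_backbone ? p.head() : p.all();
  adam.init(tensors);

  Params best = p;
  double best_dev = mae_of(predict_all(Xdev, p), ydev);
  int best_epoch = 0;
  std::vector<double> dev_hist, train_hist;
  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  // With a frozen backbone the recurrent representation of every sample is
  // constant; caching it makes per-subject fine-tuning cheap and exact.
  mat Htr, Hdev;
  if (freeze_backbone) {
    Htr = cpp_gru_backbone(X, params0);
    Hdev = cpp_gru_backbone(Xdev, params0);
  }

  for (int e = 1; e <= epochs; ++e) {
    rng.shuffle(order);
    double eloss = 0.0; uword nb = 0;
    for (uword s = 0; s < n; s += batch_size) {
      uword B = std::min<uword>(batch_size, n - s);
      std::vector<uword> idx(order.begin() + s, order.begin() + s + B);
      mat mask(fdim, B);
      double keep = 1.0 - dropout;
      for (uword j = 0; j < B; ++j)
        for (uword i = 0; i < fdim; ++i)
          mask(i, j) = (rng.unif() < keep) ? 1.0 / keep : 0.0;
      Grads g(p);
      double loss;
      if (freeze_backbone) {
        mat hb(Htr.n_rows, B);
        for (uword b = 0; b < B; ++b) hb.col(b) = Htr.col(idx[b]);
        mat fpre = p.Wfc * hb;  fpre.each_col() += p.bfc.col(0);
        mat f = clamp(fpre, 0.0, datum::inf) % mask;
        mat out = p.Wout * f;  out.each_col() += p.bout.col(0);
        rowvec yb(B);
        for (uword b = 0; b < B; ++b) yb(b) = y(idx[b]);
        rowvec err = out.row(0) - yb;
        loss = mean(abs(err));
        rowvec dout = sign(err) / static_cast<double>(B);
        g.Wout += dout * f.t();
        g.bout(0, 0) += accu(dout);
        mat df = (p.Wout.t() * dout) % mask;
        mat da = df % conv_to<mat>::from(fpre > 0.0);
        g.Wfc += da * hb.t();
        g.bfc += sum(da, 1);
        std::vector<mat*> gh = g.head();
        adam.step(tensors, gh, lr);
      } else {
        loss = loss_and_grad(X, y, idx, p, &mask, g, true);
        std::vector<mat*> ga = g.all();
        adam.step(tensors, ga, lr);
      }
      eloss += loss; ++nb;
    }
    double dev_mae;
    if (freeze_backbone) {
      mat fpre = p.Wfc * Hdev;  fpre.each_col() += p.bfc.col(0);
      mat out = p.Wout * clamp(fpre, 0.0, datum::inf);
      out.each_col() += p.bout.col(0);
      dev_mae = mae_of(out.row(0).t(), ydev);
    } else {
      dev_mae = mae_of(predict_all(Xdev, p), ydev);
    }
    train_hist.push_back(eloss / nb);
    dev_hist.push_back(dev_mae);
    if (dev_mae < best_dev) { best_dev = dev_mae; best = p; best_epoch = e; }
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = to_list(best),
      Rcpp::Named("selected_epoch") = best_epoch,
      Rcpp::Named("dev_mae") = best_dev,
      Rcpp::Named("dev_history") = dev_hist,
      Rcpp::Named("train_history") = train_hist);
}
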