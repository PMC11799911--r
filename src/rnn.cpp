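// Stacked LSTM/GRU sequence regressors with batch normalization, Monte Carlo
// dropout, Adam, and full backpropagation through time.
//
// The whole engine is templated on the element type: training and prediction
// run in single precision (the standard working precision for this kind of
// network, and twice the throughput of double on the same BLAS), while the
// double instantiation backs the finite-difference gradient verification in
// the test suite.
//
// Layout conventions:
//  - minibatch activations are stacked over time: a (B*T x H) matrix whose
//    rows [t*B, (t+1)*B) hold time step t for the B samples;
//  - LSTM gate order [i f g o], GRU gate order [z r n];
//  - batch norm follows every recurrent layer except the last; a dropout
//    stage follows each recurrent block and stays active at inference when
//    MC mode is on (one mask per sample and pass, shared across time);
//  - the last recurrent layer contributes its final hidden state only,
//    which feeds a linear dense map to the outputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BN_EPS = 1e-3;
static const double BN_MOMENTUM = 0.99;

// Deterministic portable RNG (mt19937_64 + Box-Muller) so results do not
// depend on library-specific distribution implementations.
struct Rng {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    while (u1 <= 1e-300) u1 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
  int integer(int n) { return (int)(unif() * n) % n; }
};

template <typename T>
struct Layer {
  arma::Mat<T> W, U, b;                    // b is 1 x G*H
  bool bn = false;
  arma::Mat<T> gamma, beta, rmean, rvar;   // 1 x H
};

template <typename T>
struct Net {
  std::string cell;  // "lstm" or "gru"
  int L = 0, H = 0, nin = 0, nout = 0, G = 0;
  std::vector<Layer<T>> layers;
  arma::Mat<T> Wout, bout;
};

template <typename T>
static arma::Mat<T> to_T(SEXP x) {
  return arma::conv_to<arma::Mat<T>>::from(as<arma::mat>(x));
}

template <typename T>
static Net<T> net_from_list(List lst) {
  Net<T> net;
  net.cell = as<std::string>(lst["cell"]);
  net.G = net.cell == "lstm" ? 4 : 3;
  List layers = lst["layers"];
  net.L = layers.size();
  for (int l = 0; l < net.L; ++l) {
    List ll = layers[l];
    Layer<T> lay;
    lay.W = to_T<T>(ll["W"]);
    lay.U = to_T<T>(ll["U"]);
    lay.b = to_T<T>(ll["b"]);
    lay.bn = as<bool>(ll["bn"]);
    if (lay.bn) {
      lay.gamma = to_T<T>(ll["gamma"]);
      lay.beta = to_T<T>(ll["beta"]);
      lay.rmean = to_T<T>(ll["rmean"]);
      lay.rvar = to_T<T>(ll["rvar"]);
    }
    net.layers.push_back(lay);
  }
  net.H = net.layers[0].U.n_rows;
  net.nin = net.layers[0].W.n_rows;
  net.Wout = to_T<T>(lst["Wout"]);
  net.bout = to_T<T>(lst["bout"]);
  net.nout = net.Wout.n_cols;
  return net;
}

template <typename T>
static List net_to_list(const Net<T>& net) {
  List layers(net.L);
  for (int l = 0; l < net.L; ++l) {
    const Layer<T>& lay = net.layers[l];
    auto dm = [](const arma::Mat<T>& m) {
      return arma::conv_to<arma::mat>::from(m);
    };
    if (lay.bn) {
      layers[l] = List::create(
          _["W"] = dm(lay.W), _["U"] = dm(lay.U), _["b"] = dm(lay.b),
          _["bn"] = true, _["gamma"] = dm(lay.gamma), _["beta"] = dm(lay.beta),
          _["rmean"] = dm(lay.rmean), _["rvar"] = dm(lay.rvar));
    } else {
      layers[l] = List::create(_["W"] = dm(lay.W), _["U"] = dm(lay.U),
                               _["b"] = dm(lay.b), _["bn"] = false);
    }
  }
  return List::create(
      _["cell"] = net.cell, _["layers"] = layers,
      _["Wout"] = arma::conv_to<arma::mat>::from(net.Wout),
      _["bout"] = arma::conv_to<arma::mat>::from(net.bout));
}

static arma::mat glorot(int nr, int nc, Rng& rng) {
  double lim = std::sqrt(6.0 / (nr + nc));
  arma::mat m(nr, nc);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (2.0 * rng.unif() - 1.0) * lim;
  return m;
}

// [[Rcpp::export]]
List cpp_rnn_init(std::string cell, int n_layers, int hidden, int n_in,
                  int n_out, int seed) {
  if (cell != "lstm" && cell != "gru") stop("unknown cell type: " + cell);
  Rng rng((uint64_t)seed);
  int G = cell == "lstm" ? 4 : 3;
  List layers(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    int din = l == 0 ? n_in : hidden;
    arma::mat b(1, G * hidden, arma::fill::zeros);
    if (cell == "lstm")  // forget-gate bias of 1 stabilises early training
      b.cols(hidden, 2 * hidden - 1).fill(1.0);
    bool bn = l < n_layers - 1;
    if (bn) {
      layers[l] = List::create(
          _["W"] = glorot(din, G * hidden, rng),
          _["U"] = glorot(hidden, G * hidden, rng), _["b"] = b, _["bn"] = true,
          _["gamma"] = arma::mat(1, hidden, arma::fill::ones),
          _["beta"] = arma::mat(1, hidden, arma::fill::zeros),
          _["rmean"] = arma::mat(1, hidden, arma::fill::zeros),
          _["rvar"] = arma::mat(1, hidden, arma::fill::ones));
    } else {
      layers[l] = List::create(_["W"] = glorot(din, G * hidden, rng),
                               _["U"] = glorot(hidden, G * hidden, rng),
                               _["b"] = b, _["bn"] = false);
    }
  }
  return List::create(_["cell"] = cell, _["layers"] = layers,
                      _["Wout"] = glorot(hidden, n_out, rng),
                      _["bout"] = arma::mat(1, n_out, arma::fill::zeros));
}

template <typename M>
static M sigmoid(const M& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

template <typename T>
struct LayerCache {
  arma::Mat<T> Hs;                     // stacked (B*T x H) hidden sequence
  arma::Mat<T> I, F, Gg, O, Cs, TanhC; // LSTM (stacked)
  arma::Mat<T> Z, Rr, Nn, RH;          // GRU (stacked)
  arma::Mat<T> xhat;                   // batch-norm cache
  arma::Row<T> istd;
  arma::Mat<T> mask;                   // dropout mask (B x H); empty if off
  arma::Mat<T> out;                    // block output fed to the next layer
};

// Forward one recurrent layer over the stacked input.
template <typename T>
static void layer_forward(const Net<T>& net, int l, const arma::Mat<T>& Xs,
                          int B, int Tn, LayerCache<T>& cc) {
  typedef arma::Mat<T> M;
  const Layer<T>& lay = net.layers[l];
  int H = net.H;
  M XW = Xs * lay.W;
  XW.each_row() += lay.b.row(0);
  cc.Hs.set_size(B * Tn, H);
  M h(B, H, arma::fill::zeros);
  if (net.cell == "lstm") {
    cc.I.set_size(B * Tn, H); cc.F.set_size(B * Tn, H);
    cc.Gg.set_size(B * Tn, H); cc.O.set_size(B * Tn, H);
    cc.Cs.set_size(B * Tn, H); cc.TanhC.set_size(B * Tn, H);
    M c(B, H, arma::fill::zeros);
    for (int t = 0; t < Tn; ++t) {
      arma::span rows(t * B, (t + 1) * B - 1);
      M a = XW.rows(rows) + h * lay.U;
      M i = sigmoid(M(a.cols(0, H - 1)));
      M f = sigmoid(M(a.cols(H, 2 * H - 1)));
      M g = arma::tanh(a.cols(2 * H, 3 * H - 1));
      M o = sigmoid(M(a.cols(3 * H, 4 * H - 1)));
      c = f % c + i % g;
      M tc = arma::tanh(c);
      h = o % tc;
      cc.I.rows(rows) = i; cc.F.rows(rows) = f;
      cc.Gg.rows(rows) = g; cc.O.rows(rows) = o;
      cc.Cs.rows(rows) = c; cc.TanhC.rows(rows) = tc;
      cc.Hs.rows(rows) = h;
    }
  } else {  // gru
    cc.Z.set_size(B * Tn, H); cc.Rr.set_size(B * Tn, H);
    cc.Nn.set_size(B * Tn, H); cc.RH.set_size(B * Tn, H);
    const M Uzr = lay.U.cols(0, 2 * H - 1);
    const M Un = lay.U.cols(2 * H, 3 * H - 1);
    for (int t = 0; t < Tn; ++t) {
      arma::span rows(t * B, (t + 1) * B - 1);
      M azr = XW.submat(rows, arma::span(0, 2 * H - 1)) + h * Uzr;
      M z = sigmoid(M(azr.cols(0, H - 1)));
      M r = sigmoid(M(azr.cols(H, 2 * H - 1)));
      M rh = r % h;
      M n = arma::tanh(XW.submat(rows, arma::span(2 * H, 3 * H - 1)) +
                       rh * Un);
      h = z % h + (1.0 - z) % n;
      cc.Z.rows(rows) = z; cc.Rr.rows(rows) = r;
      cc.Nn.rows(rows) = n; cc.RH.rows(rows) = rh;
      cc.Hs.rows(rows) = h;
    }
  }
}

// Batch norm over stacked rows. training: batch statistics + running-stat
// update in place; otherwise the stored statistics.
template <typename T>
static arma::Mat<T> bn_forward(Layer<T>& lay, const arma::Mat<T>& X,
                               bool training, LayerCache<T>& cc) {
  arma::Row<T> mu, v;
  if (training) {
    mu = arma::mean(X, 0);
    arma::Mat<T> cent = X.each_row() - mu;
    v = arma::mean(arma::square(cent), 0);
    lay.rmean = (T)BN_MOMENTUM * lay.rmean + (T)(1 - BN_MOMENTUM) * mu;
    lay.rvar = (T)BN_MOMENTUM * lay.rvar + (T)(1 - BN_MOMENTUM) * v;
    cc.xhat = std::move(cent);
  } else {
    mu = lay.rmean.row(0);
    v = lay.rvar.row(0);
    cc.xhat = X.each_row() - mu;
  }
  cc.istd = 1.0 / arma::sqrt(v + (T)BN_EPS);
  cc.xhat.each_row() %= cc.istd;
  arma::Mat<T> y = cc.xhat;
  y.each_row() %= lay.gamma.row(0);
  y.each_row() += lay.beta.row(0);
  return y;
}

template <typename T>
static arma::Mat<T> bn_backward(const Layer<T>& lay, const LayerCache<T>& cc,
                                const arma::Mat<T>& dY, arma::Mat<T>& dgamma,
                                arma::Mat<T>& dbeta) {
  dgamma = arma::sum(dY % cc.xhat, 0);
  dbeta = arma::sum(dY, 0);
  arma::Mat<T> dxhat = dY;
  dxhat.each_row() %= lay.gamma.row(0);
  arma::Row<T> m1 = arma::mean(dxhat, 0);
  arma::Row<T> m2 = arma::mean(dxhat % cc.xhat, 0);
  arma::Mat<T> dX = dxhat;
  dX.each_row() -= m1;
  arma::Mat<T> t2 = cc.xhat;
  t2.each_row() %= m2;
  dX -= t2;
  dX.each_row() %= cc.istd;
  return dX;
}

// Full network forward. Returns predictions (B x nout).
template <typename T>
static arma::Mat<T> net_forward(Net<T>& net, const arma::Mat<T>& Xs, int B,
                                int Tn, double dropout, bool dropout_active,
                                bool bn_training, Rng& rng,
                                std::vector<LayerCache<T>>& caches) {
  caches.assign(net.L, LayerCache<T>());
  const arma::Mat<T>* cur = &Xs;
  for (int l = 0; l < net.L; ++l) {
    LayerCache<T>& cc = caches[l];
    layer_forward(net, l, *cur, B, Tn, cc);
    bool last = l == net.L - 1;
    arma::Mat<T> out =
        last ? arma::Mat<T>(cc.Hs.rows((Tn - 1) * B, Tn * B - 1))
             : (net.layers[l].bn
                    ? bn_forward(net.layers[l], cc.Hs, bn_training, cc)
                    : cc.Hs);
    if (dropout > 0 && dropout_active) {
      cc.mask.set_size(B, net.H);
      T keep = (T)(1.0 - dropout);
      for (arma::uword j = 0; j < cc.mask.n_cols; ++j)
        for (arma::uword i = 0; i < cc.mask.n_rows; ++i)
          cc.mask(i, j) = rng.unif() < keep ? (T)1.0 / keep : (T)0.0;
      if (last) {
        out %= cc.mask;
      } else {
        for (int t = 0; t < Tn; ++t)
          out.rows(t * B, (t + 1) * B - 1) %= cc.mask;
      }
    }
    cc.out = std::move(out);
    cur = &cc.out;
  }
  arma::Mat<T> Y = caches[net.L - 1].out * net.Wout;
  Y.each_row() += net.bout.row(0);
  return Y;
}

template <typename T>
static Net<T> zero_grads(const Net<T>& net) {
  Net<T> g = net;
  for (int l = 0; l < g.L; ++l) {
    g.layers[l].W.zeros();
    g.layers[l].U.zeros();
    g.layers[l].b.zeros();
    if (g.layers[l].bn) {
      g.layers[l].gamma.zeros();
      g.layers[l].beta.zeros();
    }
  }
  g.Wout.zeros();
  g.bout.zeros();
  return g;
}

// BPTT through one recurrent layer. dHext: stacked external gradient on the
// hidden sequence (already through dropout/BN). Accumulates weight gradients
// into `g`; returns the stacked gradient w.r.t. the layer input (skipped for
// the bottom layer).
template <typename T>
static arma::Mat<T> layer_backward(const Net<T>& net, int l,
                                   const arma::Mat<T>& Xs,
                                   const LayerCache<T>& cc,
                                   const arma::Mat<T>& dHext, int B, int Tn,
                                   Layer<T>& g, bool need_dx) {
  typedef arma::Mat<T> M;
  const Layer<T>& lay = net.layers[l];
  int H = net.H;
  M dA(B * Tn, net.G * H);
  M dh(B, H, arma::fill::zeros);
  if (net.cell == "lstm") {
    M dc(B, H, arma::fill::zeros);
    const M Ut = lay.U.t();
    for (int t = Tn - 1; t >= 0; --t) {
      arma::span rows(t * B, (t + 1) * B - 1);
      dh += dHext.rows(rows);
      const M i = cc.I.rows(rows), f = cc.F.rows(rows),
              gg = cc.Gg.rows(rows), o = cc.O.rows(rows),
              tc = cc.TanhC.rows(rows);
      M cp = t > 0 ? M(cc.Cs.rows((t - 1) * B, t * B - 1))
                   : M(B, H, arma::fill::zeros);
      dc += dh % o % (1.0 - tc % tc);
      M da(B, 4 * H);
      da.cols(0, H - 1) = dc % gg % i % (1.0 - i);
      da.cols(H, 2 * H - 1) = dc % cp % f % (1.0 - f);
      da.cols(2 * H, 3 * H - 1) = dc % i % (1.0 - gg % gg);
      da.cols(3 * H, 4 * H - 1) = dh % tc % o % (1.0 - o);
      dc %= f;
      dh = da * Ut;
      dA.rows(rows) = da;
    }
    if (Tn > 1)  // dU = sum_t h_{t-1}^T da_t, via one shifted GEMM
      g.U += cc.Hs.rows(0, (Tn - 1) * B - 1).t() * dA.rows(B, Tn * B - 1);
  } else {  // gru
    const M Uzrt = lay.U.cols(0, 2 * H - 1).t();
    const M Unt = lay.U.cols(2 * H, 3 * H - 1).t();
    for (int t = Tn - 1; t >= 0; --t) {
      arma::span rows(t * B, (t + 1) * B - 1);
      dh += dHext.rows(rows);
      const M z = cc.Z.rows(rows), r = cc.Rr.rows(rows), n = cc.Nn.rows(rows);
      M hp = t > 0 ? M(cc.Hs.rows((t - 1) * B, t * B - 1))
                   : M(B, H, arma::fill::zeros);
      M dzr(B, 2 * H);
      dzr.cols(0, H - 1) = (dh % (hp - n)) % z % (1.0 - z);   // da_z
      M da_n = dh % (1.0 - z) % (1.0 - n % n);
      M t1 = da_n * Unt;
      dzr.cols(H, 2 * H - 1) = (t1 % hp) % r % (1.0 - r);     // da_r
      dh = dh % z + t1 % r + dzr * Uzrt;
      dA.submat(rows, arma::span(0, 2 * H - 1)) = dzr;
      dA.submat(rows, arma::span(2 * H, 3 * H - 1)) = da_n;
    }
    if (Tn > 1) {
      g.U.cols(0, 2 * H - 1) +=
          cc.Hs.rows(0, (Tn - 1) * B - 1).t() *
          dA.submat(arma::span(B, Tn * B - 1), arma::span(0, 2 * H - 1));
    }
    g.U.cols(2 * H, 3 * H - 1) += cc.RH.t() * dA.cols(2 * H, 3 * H - 1);
  }
  g.W += Xs.t() * dA;
  g.b += arma::sum(dA, 0);
  return need_dx ? M(dA * lay.W.t()) : M();
}

// Backward through the whole network given dY (B x nout).
template <typename T>
static void net_backward(Net<T>& net, const arma::Mat<T>& Xs, int B, int Tn,
                         const std::vector<LayerCache<T>>& caches,
                         const arma::Mat<T>& dY, Net<T>& g) {
  g.Wout += caches[net.L - 1].out.t() * dY;
  g.bout += arma::sum(dY, 0);
  arma::Mat<T> dcur = dY * net.Wout.t();  // gradient on last block (B x H)
  for (int l = net.L - 1; l >= 0; --l) {
    const LayerCache<T>& cc = caches[l];
    bool last = l == net.L - 1;
    arma::Mat<T> dHext;
    if (last) {
      if (!cc.mask.is_empty()) dcur %= cc.mask;
      dHext.zeros(B * Tn, net.H);
      dHext.rows((Tn - 1) * B, Tn * B - 1) = dcur;
    } else {
      dHext = std::move(dcur);  // stacked (B*T x H) from the layer above
      if (!cc.mask.is_empty())
        for (int t = 0; t < Tn; ++t)
          dHext.rows(t * B, (t + 1) * B - 1) %= cc.mask;
      if (net.layers[l].bn) {
        arma::Mat<T> dgamma, dbeta;
        dHext = bn_backward(net.layers[l], cc, dHext, dgamma, dbeta);
        g.layers[l].gamma += dgamma;
        g.layers[l].beta += dbeta;
      }
    }
    const arma::Mat<T>& Xin = l == 0 ? Xs : caches[l - 1].out;
    dcur = layer_backward(net, l, Xin, cc, dHext, B, Tn, g.layers[l], l > 0);
  }
}

// Gather a stacked (B*T x C) matrix from the (n, T, C) R array for the given
// sample indices.
template <typename T>
static arma::Mat<T> gather_stacked(const double* X, int n, int Tn, int C,
                                   const std::vector<int>& idx) {
  int B = idx.size();
  arma::Mat<T> Xs(B * Tn, C);
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < Tn; ++t) {
      const double* col = X + (size_t)t * n + (size_t)c * n * Tn;
      for (int b = 0; b < B; ++b) Xs(t * B + b, c) = (T)col[idx[b]];
    }
  return Xs;
}

// --- Adam ------------------------------------------------------------------

template <typename T>
struct Adam {
  double lr0, decay, b1 = 0.9, b2 = 0.999, eps = 1e-7;  // Keras defaults
  long t = 0;
  Net<T> m, v;
  Adam(const Net<T>& net, double lr0_, double decay_)
      : lr0(lr0_), decay(decay_), m(zero_grads(net)), v(zero_grads(net)) {}
  void upd(arma::Mat<T>& w, const arma::Mat<T>& gr, arma::Mat<T>& mm,
           arma::Mat<T>& vv, double lr) {
    mm = (T)b1 * mm + (T)(1 - b1) * gr;
    vv = (T)b2 * vv + (T)(1 - b2) * (gr % gr);
    T c1 = (T)(1 - std::pow(b1, (double)t));
    T c2 = (T)(1 - std::pow(b2, (double)t));
    w -= (T)lr * (mm / c1) / (arma::sqrt(vv / c2) + (T)eps);
  }
  void step(Net<T>& net, Net<T>& g, int epoch) {
    ++t;
    double lr = lr0 / (1.0 + decay * epoch);
    for (int l = 0; l < net.L; ++l) {
      upd(net.layers[l].W, g.layers[l].W, m.layers[l].W, v.layers[l].W, lr);
      upd(net.layers[l].U, g.layers[l].U, m.layers[l].U, v.layers[l].U, lr);
      upd(net.layers[l].b, g.layers[l].b, m.layers[l].b, v.layers[l].b, lr);
      if (net.layers[l].bn) {
        upd(net.layers[l].gamma, g.layers[l].gamma, m.layers[l].gamma,
            v.layers[l].gamma, lr);
        upd(net.layers[l].beta, g.layers[l].beta, m.layers[l].beta,
            v.layers[l].beta, lr);
      }
    }
    upd(net.Wout, g.Wout, m.Wout, v.Wout, lr);
    upd(net.bout, g.bout, m.bout, v.bout, lr);
  }
};

template <typename T>
static double mse(const arma::Mat<T>& Y, const arma::Mat<T>& Tgt) {
  return arma::accu(arma::square(
             arma::conv_to<arma::mat>::from(Y - Tgt))) /
         (Y.n_rows * Y.n_cols);
}

// Inference-mode loss over a whole set, in chunks.
template <typename T>
static double eval_loss(Net<T>& net, const double* X, const arma::Mat<T>& Y,
                        int n, int Tn, int C, int chunk) {
  Rng dummy(0);
  std::vector<LayerCache<T>> caches;
  double acc = 0;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    std::vector<int> idx(e - s);
    for (int i = s; i < e; ++i) idx[i - s] = i;
    arma::Mat<T> Xs = gather_stacked<T>(X, n, Tn, C, idx);
    arma::Mat<T> P =
        net_forward(net, Xs, e - s, Tn, 0.0, false, false, dummy, caches);
    acc += arma::accu(arma::square(
        arma::conv_to<arma::mat>::from(P - Y.rows(s, e - 1))));
  }
  return acc / ((double)n * Y.n_cols);
}

// [[Rcpp::export]]
List cpp_rnn_train(List net_lst, NumericVector Xtr, NumericMatrix Ytr,
                   NumericVector Xval, NumericMatrix Yval, double dropout,
                   int batch_size, int epochs, double lr0, double decay,
                   int seed, bool verbose) {
  typedef float T;
  Net<T> net = net_from_list<T>(net_lst);
  IntegerVector dim = Xtr.attr("dim");
  int n = dim[0], Tn = dim[1], C = dim[2];
  IntegerVector dimv = Xval.attr("dim");
  int nval = dimv[0];
  arma::Mat<T> Y = to_T<T>(Ytr), Yv = to_T<T>(Yval);
  if (n == 0) stop("empty training set");
  Rng rng((uint64_t)seed * 2654435761u + 17);
  Adam<T> opt(net, lr0, decay);
  std::vector<double> tr_loss, val_loss;
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  std::vector<LayerCache<T>> caches;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i)  // Fisher-Yates under the training RNG
      std::swap(perm[i], perm[rng.integer(i + 1)]);
    double acc = 0;
    long nbatch = 0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(n, s + batch_size);
      std::vector<int> idx(perm.begin() + s, perm.begin() + e);
      int B = e - s;
      arma::Mat<T> Xs = gather_stacked<T>(REAL(Xtr), n, Tn, C, idx);
      arma::Mat<T> Tg(B, net.nout);
      for (int b = 0; b < B; ++b) Tg.row(b) = Y.row(idx[b]);
      arma::Mat<T> P =
          net_forward(net, Xs, B, Tn, dropout, dropout > 0, true, rng, caches);
      double loss = mse(P, Tg);
      if (!std::isfinite(loss))
        stop("training diverged: non-finite loss at epoch %d", ep + 1);
      acc += loss;
      ++nbatch;
      arma::Mat<T> dY = (T)2.0 * (P - Tg) / (T)(B * net.nout);
      Net<T> g = zero_grads(net);
      net_backward(net, Xs, B, Tn, caches, dY, g);
      opt.step(net, g, ep);
    }
    tr_loss.push_back(acc / nbatch);
    val_loss.push_back(
        nval > 0 ? eval_loss(net, REAL(Xval), Yv, nval, Tn, C, 512) : NA_REAL);
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << "/" << epochs << "  loss "
                  << tr_loss.back() << "  val " << val_loss.back()
                  << std::endl;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["net"] = net_to_list(net), _["train_loss"] = tr_loss,
                      _["val_loss"] = val_loss);
}

// [[Rcpp::export]]
arma::cube cpp_rnn_predict(List net_lst, NumericVector X, double dropout,
                           int n_mc, bool mc, int seed, int chunk = 512) {
  typedef float T;
  Net<T> net = net_from_list<T>(net_lst);
  IntegerVector dim = X.attr("dim");
  int n = dim[0], Tn = dim[1], C = dim[2];
  Rng rng((uint64_t)seed * 2654435761u + 29);
  arma::cube out(n, net.nout, n_mc);
  std::vector<LayerCache<T>> caches;
  bool active = mc && dropout > 0;
  for (int k = 0; k < n_mc; ++k) {
    for (int s = 0; s < n; s += chunk) {
      int e = std::min(n, s + chunk);
      std::vector<int> idx(e - s);
      for (int i = s; i < e; ++i) idx[i - s] = i;
      arma::Mat<T> Xs = gather_stacked<T>(REAL(X), n, Tn, C, idx);
      arma::Mat<T> P =
          net_forward(net, Xs, e - s, Tn, dropout, active, false, rng, caches);
      out.slice(k).rows(s, e - 1) = arma::conv_to<arma::mat>::from(P);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Loss and analytic gradients for one batch in double precision
// (training-mode batch norm, optional dropout under a fixed seed); backs the
// finite-difference verification of the BPTT implementation.
// [[Rcpp::export]]
List cpp_rnn_loss_grad(List net_lst, NumericVector X, NumericMatrix Ymat,
                       double dropout, int seed) {
  typedef double T;
  Net<T> net = net_from_list<T>(net_lst);
  IntegerVector dim = X.attr("dim");
  int n = dim[0], Tn = dim[1], C = dim[2];
  arma::Mat<T> Y = to_T<T>(Ymat);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  arma::Mat<T> Xs = gather_stacked<T>(REAL(X), n, Tn, C, idx);
  Rng rng((uint64_t)seed);
  std::vector<LayerCache<T>> caches;
  Net<T> work = net;  // keep running stats of the input untouched
  arma::Mat<T> P =
      net_forward(work, Xs, n, Tn, dropout, dropout > 0, true, rng, caches);
  double loss = mse(P, Y);
  arma::Mat<T> dY = 2.0 * (P - Y) / (double)(n * net.nout);
  Net<T> g = zero_grads(net);
  net_backward(work, Xs, n, Tn, caches, dY, g);
  return List::create(_["loss"] = loss, _["grads"] = net_to_list(g));
}

// Number of trainable parameters.
// [[Rcpp::export]]
double cpp_rnn_n_params(List net_lst) {
  Net<double> net = net_from_list<double>(net_lst);
  double n = 0;
  for (int l = 0; l < net.L; ++l) {
    n += net.layers[l].W.n_elem + net.layers[l].U.n_elem +
         net.layers[l].b.n_elem;
    if (net.layers[l].bn)
      n += net.layers[l].gamma.n_elem + net.layers[l].beta.n_elem;
  }
  return n + net.Wout.n_elem + net.bout.n_elem;
}
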