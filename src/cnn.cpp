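// Small 1D CNN for fixed-length IMU windows:
//   Conv1D(F,K) -> ReLU -> Dropout -> Conv1D(F,K) -> ReLU -> Dropout ->
//   MaxPool(P) -> Dropout -> Flatten -> Dense(D) -> ReLU -> Dense(2) -> Softmax
// Trained with Adam on cross-entropy, mini-batches, early stopping on
// validation loss with best-weight restoration. Single precision throughout;
// convolutions are im2col + sgemm with workspaces allocated once per call.
// All randomness (init, shuffling, dropout) comes from an internal
// counter-based generator so results are exactly reproducible from the
// integer seed alone, independent of R's RNG state.
#include <RcppArmadillo.h>
#include <cstring>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::uword;

namespace {

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // Box-Muller; one draw per call keeps the stream simple and reproducible
  float gauss() {
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return (float)(std::sqrt(-2.0 * std::log(u1)) *
                   std::cos(6.283185307179586 * u2));
  }
};

struct Config {
  int C, W, F, K, P, D;
  float dropout, lr;
  int batch, max_epochs, patience, seed;
  int L1, L2, L3, flat;
};

Config parse_cfg(const List& cfg) {
  Config c;
  c.C = as<int>(cfg["n_channels"]);
  c.W = as<int>(cfg["window_len"]);
  c.F = as<int>(cfg["n_filters"]);
  c.K = as<int>(cfg["kernel_len"]);
  c.P = as<int>(cfg["pool_len"]);
  c.D = as<int>(cfg["dense_units"]);
  c.dropout = (float)as<double>(cfg["dropout_rate"]);
  c.lr = (float)as<double>(cfg["learning_rate"]);
  c.batch = as<int>(cfg["batch_size"]);
  c.max_epochs = as<int>(cfg["max_epochs"]);
  c.patience = as<int>(cfg["early_stop_patience"]);
  c.seed = as<int>(cfg["seed"]);
  c.L1 = c.W - c.K + 1;
  c.L2 = c.L1 - c.K + 1;
  c.L3 = c.L2 / c.P;
  c.flat = c.L3 * c.F;
  if (c.L1 < 1 || c.L2 < 1 || c.L3 < 1)
    stop("window_len too short for kernel/pool configuration");
  return c;
}

struct Net {
  fmat W1, b1, W2, b2, W3, b3, W4, b4;  // biases are 1 x units
};

Net net_from_list(const List& p) {
  Net n;
  n.W1 = arma::conv_to<fmat>::from(as<arma::mat>(p["W1"]));
  n.b1 = arma::conv_to<fmat>::from(as<arma::mat>(p["b1"]));
  n.W2 = arma::conv_to<fmat>::from(as<arma::mat>(p["W2"]));
  n.b2 = arma::conv_to<fmat>::from(as<arma::mat>(p["b2"]));
  n.W3 = arma::conv_to<fmat>::from(as<arma::mat>(p["W3"]));
  n.b3 = arma::conv_to<fmat>::from(as<arma::mat>(p["b3"]));
  n.W4 = arma::conv_to<fmat>::from(as<arma::mat>(p["W4"]));
  n.b4 = arma::conv_to<fmat>::from(as<arma::mat>(p["b4"]));
  return n;
}

List net_to_list(const Net& n) {
  return List::create(
      Named("W1") = arma::conv_to<arma::mat>::from(n.W1),
      Named("b1") = arma::conv_to<arma::mat>::from(n.b1),
      Named("W2") = arma::conv_to<arma::mat>::from(n.W2),
      Named("b2") = arma::conv_to<arma::mat>::from(n.b2),
      Named("W3") = arma::conv_to<arma::mat>::from(n.W3),
      Named("b3") = arma::conv_to<arma::mat>::from(n.b3),
      Named("W4") = arma::conv_to<arma::mat>::from(n.W4),
      Named("b4") = arma::conv_to<arma::mat>::from(n.b4));
}

// R array (n, W, C) -> cube W x C x n (one slice per window), float
arma::fcube to_cube(const NumericVector& X) {
  IntegerVector d = X.attr("dim");
  size_t n = d[0], W = d[1], C = d[2];
  arma::fcube out(W, C, n);
  const double* p = X.begin();
  for (size_t c = 0; c < C; ++c)
    for (size_t t = 0; t < W; ++t) {
      const double* col = p + t * n + c * n * W;
      for (size_t i = 0; i < n; ++i) out(t, c, i) = (float)col[i];
    }
  return out;
}

// All per-batch buffers, allocated lazily for each distinct batch size
// (one full-batch size plus at most one remainder per call).
struct Workspace {
  int b = -1;
  fmat A1, H1, M1;          // conv1: im2col, post-relu(+dropout), mask
  fmat A2, H2, M2;          // conv2
  fmat Pool, M3;            // max pooling (+dropout)
  arma::Mat<int> amax;
  fmat Fl, Z3, H3mask, Z4, Prob;
  fmat dZ4, dH3, dFl, dPd, dH2, dZ2o, dA2, dH1;
  void resize(int bb, const Config& c, bool training) {
    if (bb == b) return;
    b = bb;
    A1.set_size((uword)b * c.L1, (uword)c.K * c.C);
    H1.set_size((uword)b * c.L1, c.F);
    A2.set_size((uword)b * c.L2, (uword)c.K * c.F);
    H2.set_size((uword)b * c.L2, c.F);
    Pool.set_size((uword)b * c.L3, c.F);
    amax.set_size((uword)b * c.L3, c.F);
    Fl.set_size(b, c.flat);
    Z3.set_size(b, c.D);
    Z4.set_size(b, 2);
    Prob.set_size(b, 2);
    if (training) {
      M1.set_size(H1.n_rows, H1.n_cols);
      M2.set_size(H2.n_rows, H2.n_cols);
      M3.set_size(Pool.n_rows, Pool.n_cols);
      dPd.set_size(Pool.n_rows, Pool.n_cols);
      dH2.set_size(H2.n_rows, H2.n_cols);
      dA2.set_size(A2.n_rows, A2.n_cols);
      dH1.set_size(H1.n_rows, H1.n_cols);
    }
  }
};

void im2col_input(const arma::fcube& X, const uword* ids, int b,
                  const Config& c, fmat& A) {
  const int L1 = c.L1, K = c.K, C = c.C;
  for (int i = 0; i < b; ++i) {
    const fmat& x = X.slice(ids[i]);
    for (int ch = 0; ch < C; ++ch)
      for (int j = 0; j < K; ++j)
        std::memcpy(A.colptr(ch * K + j) + (size_t)i * L1, x.colptr(ch) + j,
                    L1 * sizeof(float));
  }
}

// H holds b per-sample feature maps stacked: (b*L1) x F; A: (b*L2) x (K*F)
void im2col_hidden(const fmat& H, int b, const Config& c, fmat& A) {
  const int L1 = c.L1, L2 = c.L2, K = c.K, F = c.F;
  for (int i = 0; i < b; ++i)
    for (int f = 0; f < F; ++f)
      for (int j = 0; j < K; ++j)
        std::memcpy(A.colptr(f * K + j) + (size_t)i * L2,
                    H.colptr(f) + (size_t)i * L1 + j, L2 * sizeof(float));
}

void col2im_hidden(const fmat& dA, int b, const Config& c, fmat& dH) {
  const int L1 = c.L1, L2 = c.L2, K = c.K, F = c.F;
  dH.zeros();
  for (int i = 0; i < b; ++i)
    for (int f = 0; f < F; ++f)
      for (int j = 0; j < K; ++j) {
        float* dst = dH.colptr(f) + (size_t)i * L1 + j;
        const float* src = dA.colptr(f * K + j) + (size_t)i * L2;
        for (int t = 0; t < L2; ++t) dst[t] += src[t];
      }
}

void add_bias_relu(fmat& Z, const fmat& b) {
  for (uword f = 0; f < Z.n_cols; ++f) {
    const float bf = b(0, f);
    float* z = Z.colptr(f);
    for (uword r = 0; r < Z.n_rows; ++r) {
      float v = z[r] + bf;
      z[r] = v > 0.0f ? v : 0.0f;
    }
  }
}

// inverted dropout applied in place; mask entries are 0 or 1/(1-p).
// For the standard rate 0.5 each unit costs one random bit, not one draw.
void apply_dropout(fmat& H, fmat& M, float p, SplitMix& rng) {
  const float scale = 1.0f / (1.0f - p);
  float* h = H.memptr();
  float* m = M.memptr();
  const size_t n = H.n_elem;
  if (p == 0.5f) {
    uint64_t bits = 0;
    int left = 0;
    for (size_t i = 0; i < n; ++i) {
      if (left == 0) { bits = rng.next(); left = 64; }
      const float mi = (bits & 1u) ? scale : 0.0f;
      bits >>= 1;
      --left;
      m[i] = mi;
      h[i] *= mi;
    }
  } else {
    for (size_t i = 0; i < n; ++i) {
      const float mi = (rng.unif() >= p) ? scale : 0.0f;
      m[i] = mi;
      h[i] *= mi;
    }
  }
}

// forward pass over one batch; fills ws; returns summed cross-entropy when
// y is given. In training mode applies dropout with rng.
double forward(const arma::fcube& X, const uword* ids, int b, const Net& net,
               const Config& c, bool training, SplitMix* rng, const int* y,
               Workspace& ws) {
  ws.resize(b, c, training);
  im2col_input(X, ids, b, c, ws.A1);
  ws.H1 = ws.A1 * net.W1;
  add_bias_relu(ws.H1, net.b1);
  if (training) apply_dropout(ws.H1, ws.M1, c.dropout, *rng);
  im2col_hidden(ws.H1, b, c, ws.A2);
  ws.H2 = ws.A2 * net.W2;
  add_bias_relu(ws.H2, net.b2);
  if (training) apply_dropout(ws.H2, ws.M2, c.dropout, *rng);
  // max pool over c.P consecutive time steps within each sample
  const int L2 = c.L2, L3 = c.L3, P = c.P;
  for (int f = 0; f < c.F; ++f) {
    const float* h = ws.H2.colptr(f);
    float* po = ws.Pool.colptr(f);
    int* am = ws.amax.colptr(f);
    for (int i = 0; i < b; ++i) {
      const float* hi = h + (size_t)i * L2;
      float* poi = po + (size_t)i * L3;
      int* ami = am + (size_t)i * L3;
      for (int u = 0; u < L3; ++u) {
        int base = u * P, best = 0;
        float v = hi[base];
        for (int q = 1; q < P; ++q)
          if (hi[base + q] > v) { v = hi[base + q]; best = q; }
        poi[u] = v;
        ami[u] = best;
      }
    }
  }
  if (training) apply_dropout(ws.Pool, ws.M3, c.dropout, *rng);
  // flatten: sample i -> row i, feature index f*L3 + u (column-major writes)
  for (int f = 0; f < c.F; ++f) {
    const float* pd = ws.Pool.colptr(f);
    for (int u = 0; u < L3; ++u) {
      float* dst = ws.Fl.colptr(f * L3 + u);
      const float* src = pd + u;
      for (int i = 0; i < b; ++i) dst[i] = src[(size_t)i * L3];
    }
  }
  ws.Z3 = ws.Fl * net.W3;
  add_bias_relu(ws.Z3, net.b3);
  ws.Z4 = ws.Z3 * net.W4;
  ws.Z4.col(0) += net.b4(0, 0);
  ws.Z4.col(1) += net.b4(0, 1);
  double loss = 0.0;
  for (int i = 0; i < b; ++i) {
    const float m = std::max(ws.Z4(i, 0), ws.Z4(i, 1));
    const float e0 = std::exp(ws.Z4(i, 0) - m), e1 = std::exp(ws.Z4(i, 1) - m);
    const float s = e0 + e1;
    ws.Prob(i, 0) = e0 / s;
    ws.Prob(i, 1) = e1 / s;
    if (y) loss -= std::log(std::max((double)ws.Prob(i, y[i]), 1e-12));
  }
  return loss;
}

struct Grads {
  fmat W1, b1, W2, b2, W3, b3, W4, b4;
};

// backward through the cached training-mode forward pass in ws.
// dropout + relu backward are fused: post-dropout activations H are > 0
// exactly where the pre-activation was positive AND the unit was kept, so
// the combined local derivative is M % (H > 0).
void backward(const Net& net, const Config& c, Workspace& ws, const int* y,
              Grads& g) {
  const int b = ws.b;
  fmat dZ4 = ws.Prob;
  for (int i = 0; i < b; ++i) dZ4(i, y[i]) -= 1.0f;
  dZ4 /= (float)b;
  g.W4 = ws.Z3.t() * dZ4;
  g.b4 = arma::sum(dZ4, 0);
  fmat dH3 = dZ4 * net.W4.t();
  {  // relu backward on dense layer (no dropout there)
    float* d = dH3.memptr();
    const float* z = ws.Z3.memptr();
    for (size_t i = 0; i < dH3.n_elem; ++i)
      if (z[i] <= 0.0f) d[i] = 0.0f;
  }
  g.W3 = ws.Fl.t() * dH3;
  g.b3 = arma::sum(dH3, 0);
  fmat dFl = dH3 * net.W3.t();  // b x flat
  // unflatten to (b*L3) x F and pass through the pool dropout mask
  const int L3 = c.L3, L2 = c.L2, P = c.P;
  for (int f = 0; f < c.F; ++f) {
    float* dst = ws.dPd.colptr(f);
    const float* m3 = ws.M3.colptr(f);
    for (int u = 0; u < L3; ++u) {
      const float* src = dFl.colptr(f * L3 + u);
      for (int i = 0; i < b; ++i)
        dst[(size_t)i * L3 + u] = src[i] * m3[(size_t)i * L3 + u];
    }
  }
  // pool backward, then fused dropout+relu backward for conv2
  ws.dH2.zeros();
  for (int f = 0; f < c.F; ++f) {
    const float* dp = ws.dPd.colptr(f);
    const int* am = ws.amax.colptr(f);
    float* dh = ws.dH2.colptr(f);
    for (int i = 0; i < b; ++i)
      for (int u = 0; u < L3; ++u)
        dh[(size_t)i * L2 + u * P + am[(size_t)i * L3 + u]] =
            dp[(size_t)i * L3 + u];
  }
  {
    float* d = ws.dH2.memptr();
    const float* h = ws.H2.memptr();
    const float* m = ws.M2.memptr();
    for (size_t i = 0; i < ws.dH2.n_elem; ++i)
      d[i] = (h[i] > 0.0f) ? d[i] * m[i] : 0.0f;
  }
  g.W2 = ws.A2.t() * ws.dH2;
  g.b2 = arma::sum(ws.dH2, 0);
  ws.dA2 = ws.dH2 * net.W2.t();
  col2im_hidden(ws.dA2, b, c, ws.dH1);
  {
    float* d = ws.dH1.memptr();
    const float* h = ws.H1.memptr();
    const float* m = ws.M1.memptr();
    for (size_t i = 0; i < ws.dH1.n_elem; ++i)
      d[i] = (h[i] > 0.0f) ? d[i] * m[i] : 0.0f;
  }
  g.W1 = ws.A1.t() * ws.dH1;
  g.b1 = arma::sum(ws.dH1, 0);
}

struct AdamState {
  fmat m, v;
  void init(const fmat& w) {
    m.zeros(w.n_rows, w.n_cols);
    v.zeros(w.n_rows, w.n_cols);
  }
};

// single fused pass over (w, g, m, v); bias correction folded into the step
void adam_step(fmat& w, const fmat& g, AdamState& s, float lr, int t) {
  const float mc = 1.0f - std::pow(0.9f, (float)t);
  const float vc = 1.0f - std::pow(0.999f, (float)t);
  const float inv_mc = 1.0f / mc;
  const float sq_vc = std::sqrt(1.0f / vc);
  float* wp = w.memptr();
  const float* gp = g.memptr();
  float* mp = s.m.memptr();
  float* vp = s.v.memptr();
  const size_t n = w.n_elem;
  for (size_t i = 0; i < n; ++i) {
    const float gi = gp[i];
    const float mi = 0.9f * mp[i] + 0.1f * gi;
    const float vi = 0.999f * vp[i] + 0.001f * gi * gi;
    mp[i] = mi;
    vp[i] = vi;
    wp[i] -= lr * (mi * inv_mc) / (std::sqrt(vi) * sq_vc + 1e-8f);
  }
}

double dataset_loss(const arma::fcube& X, const std::vector<int>& y,
                    const Net& net, const Config& c, Workspace& ws) {
  const size_t n = X.n_slices, chunk = 512;
  std::vector<uword> ids(std::min(n, chunk));
  double total = 0.0;
  for (size_t s = 0; s < n; s += chunk) {
    const size_t e = std::min(n, s + chunk);
    for (size_t i = s; i < e; ++i) ids[i - s] = i;
    total += forward(X, ids.data(), (int)(e - s), net, c, false, nullptr,
                     y.data() + s, ws);
  }
  return total / n;
}

}  // namespace

// [[Rcpp::export]]
List cnn_init_cpp(List cfg) {
  Config c = parse_cfg(cfg);
  SplitMix rng((uint64_t)c.seed * 0x9E3779B97F4A7C15ULL + 12345u);
  Net n;
  auto he = [&](fmat& w, int rows, int cols, int fan_in) {
    w.set_size(rows, cols);
    const float sd = std::sqrt(2.0f / (float)fan_in);
    for (uword i = 0; i < w.n_elem; ++i) w(i) = sd * rng.gauss();
  };
  he(n.W1, c.K * c.C, c.F, c.K * c.C);
  n.b1.zeros(1, c.F);
  he(n.W2, c.K * c.F, c.F, c.K * c.F);
  n.b2.zeros(1, c.F);
  he(n.W3, c.flat, c.D, c.flat);
  n.b3.zeros(1, c.D);
  he(n.W4, c.D, 2, c.D);
  n.b4.zeros(1, 2);
  return net_to_list(n);
}

// [[Rcpp::export]]
List cnn_train_cpp(NumericVector X_train, IntegerVector y_train,
                   NumericVector X_val, IntegerVector y_val, List cfg,
                   List params) {
  Config c = parse_cfg(cfg);
  arma::fcube Xtr = to_cube(X_train);
  arma::fcube Xva = to_cube(X_val);
  std::vector<int> ytr(y_train.begin(), y_train.end());
  std::vector<int> yva(y_val.begin(), y_val.end());
  const size_t n = Xtr.n_slices;
  if (n == 0) stop("empty training set");
  if (Xva.n_slices == 0) stop("empty validation set");

  Net net = net_from_list(params);
  AdamState aW1, ab1, aW2, ab2, aW3, ab3, aW4, ab4;
  aW1.init(net.W1); ab1.init(net.b1); aW2.init(net.W2); ab2.init(net.b2);
  aW3.init(net.W3); ab3.init(net.b3); aW4.init(net.W4); ab4.init(net.b4);

  SplitMix rng((uint64_t)c.seed * 0x2545F4914F6CDD1DULL + 777u);
  std::vector<uword> order(n);
  for (size_t i = 0; i < n; ++i) order[i] = i;

  Workspace ws_train, ws_eval;
  std::vector<double> tr_hist, va_hist;
  Net best = net;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, wait = 0, t = 0;
  std::vector<int> yb(c.batch);
  Grads g;

  for (int epoch = 1; epoch <= c.max_epochs; ++epoch) {
    // Fisher-Yates with the internal generator (portable determinism)
    for (size_t i = n - 1; i > 0; --i) {
      const size_t j = (size_t)(rng.next() % (i + 1));
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0.0;
    for (size_t s = 0; s < n; s += c.batch) {
      const size_t e = std::min(n, s + (size_t)c.batch);
      const int b = (int)(e - s);
      for (int i = 0; i < b; ++i) yb[i] = ytr[order[s + i]];
      ep_loss += forward(Xtr, order.data() + s, b, net, c, true, &rng,
                         yb.data(), ws_train);
      backward(net, c, ws_train, yb.data(), g);
      ++t;
      adam_step(net.W1, g.W1, aW1, c.lr, t);
      adam_step(net.b1, g.b1, ab1, c.lr, t);
      adam_step(net.W2, g.W2, aW2, c.lr, t);
      adam_step(net.b2, g.b2, ab2, c.lr, t);
      adam_step(net.W3, g.W3, aW3, c.lr, t);
      adam_step(net.b3, g.b3, ab3, c.lr, t);
      adam_step(net.W4, g.W4, aW4, c.lr, t);
      adam_step(net.b4, g.b4, ab4, c.lr, t);
    }
    ep_loss /= n;
    const double val = dataset_loss(Xva, yva, net, c, ws_eval);
    tr_hist.push_back(ep_loss);
    va_hist.push_back(val);
    if (val < best_val - 1e-6) {
      best_val = val;
      best = net;
      best_epoch = epoch;
      wait = 0;
    } else {
      ++wait;
      if (wait >= c.patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(Named("params") = net_to_list(best),
                      Named("train_loss") = wrap(tr_hist),
                      Named("val_loss") = wrap(va_hist),
                      Named("best_epoch") = best_epoch,
                      Named("best_val_loss") = best_val);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(NumericVector X, List cfg, List params) {
  Config c = parse_cfg(cfg);
  arma::fcube Xc = to_cube(X);
  Net net = net_from_list(params);
  const size_t n = Xc.n_slices, chunk = 512;
  NumericMatrix out(n, 2);
  Workspace ws;
  std::vector<uword> ids(std::min(n, chunk));
  for (size_t s = 0; s < n; s += chunk) {
    const size_t e = std::min(n, s + chunk);
    for (size_t i = s; i < e; ++i) ids[i - s] = i;
    forward(Xc, ids.data(), (int)(e - s), net, c, false, nullptr, nullptr, ws);
    for (size_t i = s; i < e; ++i) {
      out(i, 0) = ws.Prob(i - s, 0);
      out(i, 1) = ws.Prob(i - s, 1);
    }
  }
  return out;
}
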