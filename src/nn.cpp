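// Compact sequence-labelling network engine: token embedding, bidirectional
// LSTM, dropout, position-wise dense layers and a per-position softmax,
// trained with Adam under categorical cross-entropy. Templated on the
// floating type: training and prediction run in float (as deep-learning
// frameworks do), while the gradient-verification entry point instantiates
// the identical code in double so finite differences are meaningful.
//
// All randomness (weight draws, epoch shuffles, dropout masks) flows from a
// single std::mt19937_64, so a run is exactly reproducible from its seed.

#include <RcppArmadillo.h>
#include <random>
#include <array>
#include <vector>
#include <string>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int N_POS = 16;
static const int N_OUT = 4;

struct LayerSpec {
  std::string type;   // embedding | bilstm | dense | dropout
  int units = 0;
  double rate = 0.0;
  int activation = 0; // 0 linear, 1 relu, 2 softmax
};

static std::vector<LayerSpec> parse_spec(List layers) {
  std::vector<LayerSpec> out;
  for (R_xlen_t i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    LayerSpec s;
    s.type = as<std::string>(l["type"]);
    if (l.containsElementNamed("units") && !Rf_isNull(l["units"]))
      s.units = as<int>(l["units"]);
    if (l.containsElementNamed("rate") && !Rf_isNull(l["rate"]))
      s.rate = as<double>(l["rate"]);
    if (l.containsElementNamed("activation") && !Rf_isNull(l["activation"])) {
      std::string a = as<std::string>(l["activation"]);
      s.activation = (a == "relu") ? 1 : (a == "softmax") ? 2 : 0;
    }
    if (s.type != "embedding" && s.type != "bilstm" && s.type != "dense" &&
        s.type != "dropout")
      stop("unknown layer type '%s'", s.type.c_str());
    if (s.type != "dropout" && s.units <= 0)
      stop("layer '%s' needs a positive unit count", s.type.c_str());
    if (s.type == "dropout" && (s.rate < 0.0 || s.rate >= 1.0))
      stop("dropout rate must lie in [0, 1)");
    out.push_back(s);
  }
  if (out.empty() || out.front().type != "embedding")
    stop("the first layer must be an embedding");
  return out;
}

template <typename T>
class Engine {
public:
  typedef arma::Mat<T> Mat;
  typedef arma::Cube<T> Cube;
  typedef std::vector<std::vector<Mat>> Weights;

  std::vector<LayerSpec> spec;
  int vocab;
  size_t flat_at;      // first layer index operating on the flattened matrix
  Weights W;
  std::mt19937_64 rng;

  Engine(List layers, int vocab_) : spec(parse_spec(layers)), vocab(vocab_) {
    flat_at = 0;
    while (flat_at < spec.size() && (spec[flat_at].type == "embedding" ||
                                     spec[flat_at].type == "bilstm"))
      ++flat_at;
    if (spec.back().type != "dense" || spec.back().activation != 2 ||
        spec.back().units != N_OUT)
      stop("the last layer must be a dense softmax with 4 units");
  }

  // ---- weight handling -------------------------------------------------

  Mat runif_mat(int r, int c, double lim) {
    std::uniform_real_distribution<double> u(-lim, lim);
    Mat m(r, c);
    for (arma::uword j = 0; j < m.n_cols; ++j)
      for (arma::uword i = 0; i < m.n_rows; ++i)
        m(i, j) = (T)u(rng);
    return m;
  }

  Mat glorot(int fan_in, int fan_out) {
    return runif_mat(fan_in, fan_out, std::sqrt(6.0 / (fan_in + fan_out)));
  }

  // orthogonal recurrent kernel, one orthogonal U x U block per gate
  Mat orth_blocks(int U) {
    std::normal_distribution<double> nd(0.0, 1.0);
    Mat out(U, 4 * U);
    for (int g = 0; g < 4; ++g) {
      arma::mat A(U, U);
      for (arma::uword j = 0; j < A.n_cols; ++j)
        for (arma::uword i = 0; i < A.n_rows; ++i)
          A(i, j) = nd(rng);
      arma::mat Q, R;
      if (!arma::qr_econ(Q, R, A)) stop("QR decomposition failed");
      for (int j = 0; j < U; ++j) if (R(j, j) < 0) Q.col(j) *= -1.0;
      out.cols(g * U, g * U + U - 1) = arma::conv_to<Mat>::from(Q);
    }
    return out;
  }

  void init_weights(int seed) {
    rng.seed((uint64_t)seed);
    W.clear();
    int d = 0;
    for (const LayerSpec& l : spec) {
      std::vector<Mat> w;
      if (l.type == "embedding") {
        w.push_back(runif_mat(vocab, l.units, 0.05));
        d = l.units;
      } else if (l.type == "bilstm") {
        int U = l.units;
        for (int dir = 0; dir < 2; ++dir) {
          w.push_back(glorot(d, 4 * U));
          w.push_back(orth_blocks(U));
          Mat b(1, 4 * U, arma::fill::zeros);
          b.cols(U, 2 * U - 1).fill((T)1);  // unit forget-gate bias
          w.push_back(b);
        }
        d = 2 * U;
      } else if (l.type == "dense") {
        w.push_back(glorot(d, l.units));
        w.push_back(Mat(1, l.units, arma::fill::zeros));
        d = l.units;
      }
      W.push_back(w);
    }
  }

  Weights zeros_like(const Weights& src) const {
    Weights out(src.size());
    for (size_t k = 0; k < src.size(); ++k)
      for (const Mat& m : src[k])
        out[k].push_back(Mat(m.n_rows, m.n_cols, arma::fill::zeros));
    return out;
  }

  void set_weights(List w) {
    W.clear();
    for (R_xlen_t k = 0; k < w.size(); ++k) {
      List lk = w[k];
      std::vector<Mat> wk;
      for (R_xlen_t j = 0; j < lk.size(); ++j) {
        NumericMatrix m = lk[j];
        Mat a(m.nrow(), m.ncol());
        for (int cc = 0; cc < m.ncol(); ++cc)
          for (int rr = 0; rr < m.nrow(); ++rr)
            a(rr, cc) = (T)m(rr, cc);
        wk.push_back(a);
      }
      W.push_back(wk);
    }
  }

  List get_weights(const Weights& src) const {
    List out(src.size());
    for (size_t k = 0; k < src.size(); ++k) {
      List lk(src[k].size());
      for (size_t j = 0; j < src[k].size(); ++j) {
        const Mat& a = src[k][j];
        NumericMatrix m(a.n_rows, a.n_cols);
        for (arma::uword cc = 0; cc < a.n_cols; ++cc)
          for (arma::uword rr = 0; rr < a.n_rows; ++rr)
            m(rr, cc) = (double)a(rr, cc);
        lk[j] = m;
      }
      out[k] = lk;
    }
    return out;
  }

  // ---- forward / backward ----------------------------------------------

  static Mat sigmoid(const Mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

  struct LstmCache { Cube i, f, g, o, c; Cube h; };

  // One batch. Returns mean cross-entropy over B*16 positions when Y is
  // given. If grad is non-null, accumulates parameter gradients (fresh
  // zeroed structure expected). If probs_out is non-null, stores the
  // (16B x 4) softmax output (rows ordered position-major: r = t*B + b).
  double run_batch(const arma::umat& Xb, const arma::imat* Yb, bool training,
                   Weights* grad, Mat* probs_out) {
    const int B = Xb.n_rows;
    const size_t L = spec.size();

    // phase A: cubes (B x d x 16)
    std::vector<Cube> seqA(flat_at);
    std::vector<std::array<LstmCache, 2>> lstm(flat_at);
    {
      const Mat& E = W[0][0];
      int d0 = spec[0].units;
      Cube emb(B, d0, N_POS);
      for (int t = 0; t < N_POS; ++t) {
        Mat s(B, d0);
        for (int b = 0; b < B; ++b) s.row(b) = E.row(Xb(b, t));
        emb.slice(t) = s;
      }
      seqA[0] = emb;
    }
    for (size_t k = 1; k < flat_at; ++k)
      seqA[k] = bilstm_forward(k, seqA[k - 1], lstm[k]);

    // flatten: row r = t*B + b
    int dA = (flat_at == 1) ? spec[0].units : 2 * spec[flat_at - 1].units;
    Mat F((size_t)N_POS * B, dA);
    for (int t = 0; t < N_POS; ++t)
      F.rows((size_t)t * B, (size_t)t * B + B - 1) = seqA[flat_at - 1].slice(t);

    // phase B: flattened dense/dropout stack
    std::vector<Mat> acts(L + 1);   // acts[k] = input of layer k (k >= flat_at)
    std::vector<Mat> masks(L);
    acts[flat_at] = F;
    for (size_t k = flat_at; k < L; ++k) {
      const LayerSpec& l = spec[k];
      if (l.type == "dropout") {
        if (training && l.rate > 0.0) {
          std::uniform_real_distribution<double> u(0.0, 1.0);
          Mat m(acts[k].n_rows, acts[k].n_cols);
          T scale = (T)(1.0 / (1.0 - l.rate));
          for (arma::uword j = 0; j < m.n_cols; ++j)
            for (arma::uword i = 0; i < m.n_rows; ++i)
              m(i, j) = (u(rng) < l.rate) ? (T)0 : scale;
          masks[k] = m;
          acts[k + 1] = acts[k] % m;
        } else {
          acts[k + 1] = acts[k];
        }
      } else { // dense
        Mat Z = acts[k] * W[k][0];
        Z.each_row() += W[k][1];
        if (l.activation == 1) {
          acts[k + 1] = arma::clamp(Z, (T)0, std::numeric_limits<T>::max());
        } else if (l.activation == 2) {
          arma::Col<T> mx = arma::max(Z, 1);
          Z.each_col() -= mx;
          Z = arma::exp(Z);
          arma::Col<T> sm = arma::sum(Z, 1);
          Z.each_col() /= sm;
          acts[k + 1] = Z;
        } else {
          acts[k + 1] = Z;
        }
      }
    }
    const Mat& P = acts[L];
    if (probs_out) *probs_out = P;

    double loss = 0.0;
    if (Yb) {
      const double eps = 1e-7;
      for (int t = 0; t < N_POS; ++t)
        for (int b = 0; b < B; ++b) {
          double p = (double)P((size_t)t * B + b, (*Yb)(b, t));
          if (p < eps) p = eps;
          loss -= std::log(p);
        }
      loss /= (double)(N_POS * B);
    }

    if (grad) {
      const T inv = (T)(1.0 / (double)(N_POS * B));
      Mat dF = P;
      for (int t = 0; t < N_POS; ++t)
        for (int b = 0; b < B; ++b)
          dF((size_t)t * B + b, (*Yb)(b, t)) -= (T)1;
      dF *= inv;
      for (size_t k = L; k-- > flat_at;) {
        const LayerSpec& l = spec[k];
        if (l.type == "dropout") {
          if (masks[k].n_elem) dF = dF % masks[k];
        } else {
          Mat dZ = dF;               // softmax folds into the CE gradient
          if (l.activation == 1)
            dZ.elem(arma::find(acts[k + 1] <= (T)0)).zeros();
          (*grad)[k][0] += acts[k].t() * dZ;
          (*grad)[k][1] += arma::sum(dZ, 0);
          dF = dZ * W[k][0].t();
        }
      }
      // unflatten and run through recurrent phase
      Cube dC(B, dA, N_POS);
      for (int t = 0; t < N_POS; ++t)
        dC.slice(t) = dF.rows((size_t)t * B, (size_t)t * B + B - 1);
      for (size_t k = flat_at; k-- > 1;)
        dC = bilstm_backward(k, seqA[k - 1], lstm[k], dC, (*grad)[k]);
      Mat& gE = (*grad)[0][0];
      for (int t = 0; t < N_POS; ++t) {
        const Mat& sl = dC.slice(t);
        for (int b = 0; b < B; ++b) gE.row(Xb(b, t)) += sl.row(b);
      }
    }
    return loss;
  }

  // Flatten a (B x d x 16) cube into (16B x d), rows ordered r = t*B + b.
  static Mat flatten_cube(const Cube& X) {
    const int B = X.n_rows;
    Mat F((size_t)N_POS * B, X.n_cols);
    for (int t = 0; t < N_POS; ++t)
      F.rows((size_t)t * B, (size_t)t * B + B - 1) = X.slice(t);
    return F;
  }

  // The input projection (and in the backward pass the kernel gradients
  // and input gradient) have no sequential dependency, so they run as one
  // large GEMM over all 16 positions; only the recurrent products stay in
  // the per-step loop.
  Cube bilstm_forward(size_t k, const Cube& X, std::array<LstmCache, 2>& cache) {
    const int B = X.n_rows, U = spec[k].units;
    Cube out(B, 2 * U, N_POS);
    Mat Fin = flatten_cube(X);
    for (int dir = 0; dir < 2; ++dir) {
      const Mat& Wx = W[k][dir * 3 + 0];
      const Mat& Wh = W[k][dir * 3 + 1];
      const Mat& bb = W[k][dir * 3 + 2];
      Mat Xp = Fin * Wx;
      LstmCache& cc = cache[dir];
      cc.i.set_size(B, U, N_POS); cc.f.set_size(B, U, N_POS);
      cc.g.set_size(B, U, N_POS); cc.o.set_size(B, U, N_POS);
      cc.c.set_size(B, U, N_POS); cc.h.set_size(B, U, N_POS);
      Mat h(B, U, arma::fill::zeros), c(B, U, arma::fill::zeros);
      for (int s = 0; s < N_POS; ++s) {
        int t = (dir == 0) ? s : N_POS - 1 - s;
        Mat z = Xp.rows((size_t)t * B, (size_t)t * B + B - 1) + h * Wh;
        z.each_row() += bb;
        Mat gi = sigmoid(z.cols(0, U - 1));
        Mat gf = sigmoid(z.cols(U, 2 * U - 1));
        Mat gg = arma::tanh(z.cols(2 * U, 3 * U - 1));
        Mat go = sigmoid(z.cols(3 * U, 4 * U - 1));
        c = gf % c + gi % gg;
        h = go % arma::tanh(c);
        cc.i.slice(t) = gi; cc.f.slice(t) = gf; cc.g.slice(t) = gg;
        cc.o.slice(t) = go; cc.c.slice(t) = c;  cc.h.slice(t) = h;
        out.slice(t).cols(dir * U, dir * U + U - 1) = h;
      }
    }
    return out;
  }

  Cube bilstm_backward(size_t k, const Cube& X,
                       const std::array<LstmCache, 2>& cache,
                       const Cube& dOut, std::vector<Mat>& G) {
    const int B = X.n_rows, D = X.n_cols, U = spec[k].units;
    Mat Fin = flatten_cube(X);
    Mat dXflat((size_t)N_POS * B, D, arma::fill::zeros);
    for (int dir = 0; dir < 2; ++dir) {
      const Mat& Wx = W[k][dir * 3 + 0];
      const Mat& Wh = W[k][dir * 3 + 1];
      const LstmCache& cc = cache[dir];
      Mat DZ((size_t)N_POS * B, 4 * U);
      Mat Hprev((size_t)N_POS * B, U);
      Mat dh_rec(B, U, arma::fill::zeros), dc_next(B, U, arma::fill::zeros);
      for (int s = N_POS - 1; s >= 0; --s) {
        int t = (dir == 0) ? s : N_POS - 1 - s;
        int t_prev = (dir == 0) ? t - 1 : t + 1;  // previous processing step
        Mat dh = dOut.slice(t).cols(dir * U, dir * U + U - 1) + dh_rec;
        Mat tc = arma::tanh(cc.c.slice(t));
        Mat d_o = dh % tc;
        Mat dc = dc_next + dh % cc.o.slice(t) % (1.0 - tc % tc);
        Mat cprev = (s == 0) ? Mat(B, U, arma::fill::zeros)
                             : Mat(cc.c.slice(t_prev));
        Mat hprev = (s == 0) ? Mat(B, U, arma::fill::zeros)
                             : Mat(cc.h.slice(t_prev));
        Mat di = dc % cc.g.slice(t);
        Mat dg = dc % cc.i.slice(t);
        Mat df = dc % cprev;
        dc_next = dc % cc.f.slice(t);
        Mat dz(B, 4 * U);
        dz.cols(0, U - 1)         = di % cc.i.slice(t) % (1.0 - cc.i.slice(t));
        dz.cols(U, 2 * U - 1)     = df % cc.f.slice(t) % (1.0 - cc.f.slice(t));
        dz.cols(2 * U, 3 * U - 1) = dg % (1.0 - cc.g.slice(t) % cc.g.slice(t));
        dz.cols(3 * U, 4 * U - 1) = d_o % cc.o.slice(t) % (1.0 - cc.o.slice(t));
        DZ.rows((size_t)t * B, (size_t)t * B + B - 1) = dz;
        Hprev.rows((size_t)t * B, (size_t)t * B + B - 1) = hprev;
        dh_rec = dz * Wh.t();
      }
      G[dir * 3 + 0] += Fin.t() * DZ;
      G[dir * 3 + 1] += Hprev.t() * DZ;
      G[dir * 3 + 2] += arma::sum(DZ, 0);
      dXflat += DZ * Wx.t();
    }
    Cube dX(B, D, N_POS);
    for (int t = 0; t < N_POS; ++t)
      dX.slice(t) = dXflat.rows((size_t)t * B, (size_t)t * B + B - 1);
    return dX;
  }

  // mean loss over a whole (X, Y) set, evaluated without dropout
  double eval_loss(const arma::umat& X, const arma::imat& Y, int batch) {
    const int n = X.n_rows;
    double tot = 0.0;
    for (int s = 0; s < n; s += batch) {
      int e = std::min(n, s + batch);
      arma::umat Xb = X.rows(s, e - 1);
      arma::imat Yb = Y.rows(s, e - 1);
      tot += run_batch(Xb, &Yb, false, nullptr, nullptr) * (e - s);
    }
    return tot / n;
  }
};

static arma::umat as_umat(IntegerMatrix X) {
  arma::umat out(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i) {
      if (X(i, j) < 0) stop("token indices must be nonnegative");
      out(i, j) = (arma::uword)X(i, j);
    }
  return out;
}

static arma::imat as_imat(IntegerMatrix Y) {
  arma::imat out(Y.nrow(), Y.ncol());
  for (int j = 0; j < Y.ncol(); ++j)
    for (int i = 0; i < Y.nrow(); ++i) out(i, j) = Y(i, j);
  return out;
}

// [[Rcpp::export]]
List cpp_init_weights(List layers, int vocab, int seed) {
  Engine<float> eng(layers, vocab);
  eng.init_weights(seed);
  return eng.get_weights(eng.W);
}

// [[Rcpp::export]]
NumericVector cpp_forward(List layers, List weights, IntegerMatrix X,
                          int vocab, int batch = 512) {
  Engine<float> eng(layers, vocab);
  eng.set_weights(weights);
  const int n = X.nrow();
  arma::umat Xa = as_umat(X);
  NumericVector out((R_xlen_t)n * N_POS * N_OUT);
  out.attr("dim") = IntegerVector::create(n, N_POS, N_OUT);
  for (int s = 0; s < n; s += batch) {
    int e = std::min(n, s + batch);
    int B = e - s;
    arma::umat Xb = Xa.rows(s, e - 1);
    arma::fmat P;
    eng.run_batch(Xb, nullptr, false, nullptr, &P);
    for (int cls = 0; cls < N_OUT; ++cls)
      for (int t = 0; t < N_POS; ++t)
        for (int b = 0; b < B; ++b)
          out[(R_xlen_t)(s + b) + (R_xlen_t)n * t + (R_xlen_t)n * N_POS * cls] =
            (double)P((size_t)t * B + b, cls);
  }
  return out;
}

// Double-precision loss and full parameter gradient on one batch, without
// dropout; used to verify the backward pass against finite differences.
// [[Rcpp::export]]
List cpp_loss_grad(List layers, List weights, IntegerMatrix X,
                   IntegerMatrix Y, int vocab) {
  Engine<double> eng(layers, vocab);
  eng.set_weights(weights);
  arma::umat Xa = as_umat(X);
  arma::imat Ya = as_imat(Y);
  Engine<double>::Weights G = eng.zeros_like(eng.W);
  double loss = eng.run_batch(Xa, &Ya, false, &G, nullptr);
  return List::create(_["loss"] = loss, _["gradients"] = eng.get_weights(G));
}

// [[Rcpp::export]]
double cpp_count_params(List weights) {
  double n = 0;
  for (R_xlen_t k = 0; k < weights.size(); ++k) {
    List lk = weights[k];
    for (R_xlen_t j = 0; j < lk.size(); ++j) {
      NumericMatrix m = lk[j];
      n += (double)m.nrow() * m.ncol();
    }
  }
  return n;
}

// [[Rcpp::export]]
List cpp_train(List layers, List weights, IntegerMatrix X, IntegerMatrix Y,
               IntegerMatrix Xval, IntegerMatrix Yval, List config, int vocab,
               int seed) {
  typedef Engine<float>::Weights Weights;
  Engine<float> eng(layers, vocab);
  eng.set_weights(weights);
  eng.rng.seed((uint64_t)seed * 2654435761ULL + 1ULL);

  const double lr0        = as<double>(config["initial_lr"]);
  const double lr_factor  = as<double>(config["lr_factor"]);
  const int lr_patience   = as<int>(config["lr_patience"]);
  const double lr_floor   = as<double>(config["lr_floor"]);
  const int es_patience   = as<int>(config["early_stop_patience"]);
  const bool restore_best = as<bool>(config["restore_best"]);
  const int max_epochs    = as<int>(config["max_epochs"]);
  const int batch         = as<int>(config["batch_size"]);

  arma::umat Xa = as_umat(X);
  arma::imat Ya = as_imat(Y);
  arma::umat Xv = as_umat(Xval);
  arma::imat Yv = as_imat(Yval);
  const int n = Xa.n_rows;

  Weights M = eng.zeros_like(eng.W), V = eng.zeros_like(eng.W);
  Weights best_W = eng.W;
  const double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-7;
  long step = 0;

  double lr = lr0;
  double best_val = std::numeric_limits<double>::infinity();
  double plateau_best = std::numeric_limits<double>::infinity();
  int wait_es = 0, wait_lr = 0, best_epoch = 0, stopped_epoch = 0;
  std::vector<double> h_train, h_val, h_lr;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), eng.rng);
    double ep_loss = 0.0;
    for (int s = 0; s < n; s += batch) {
      int e = std::min(n, s + batch);
      int B = e - s;
      arma::umat Xb(B, N_POS);
      arma::imat Yb(B, N_POS);
      for (int b = 0; b < B; ++b) {
        Xb.row(b) = Xa.row(order[s + b]);
        Yb.row(b) = Ya.row(order[s + b]);
      }
      Weights G = eng.zeros_like(eng.W);
      double bl = eng.run_batch(Xb, &Yb, true, &G, nullptr);
      if (!std::isfinite(bl)) stop("non-finite training loss at epoch %d", epoch);
      ep_loss += bl * B;
      ++step;
      const float c1 = (float)(1.0 - std::pow(beta1, (double)step));
      const float c2 = (float)(1.0 - std::pow(beta2, (double)step));
      for (size_t k = 0; k < eng.W.size(); ++k)
        for (size_t j = 0; j < eng.W[k].size(); ++j) {
          arma::fmat& g = G[k][j];
          M[k][j] = (float)beta1 * M[k][j] + (float)(1.0 - beta1) * g;
          V[k][j] = (float)beta2 * V[k][j] + (float)(1.0 - beta2) * (g % g);
          eng.W[k][j] -= (float)lr * (M[k][j] / c1) /
                         (arma::sqrt(V[k][j] / c2) + (float)adam_eps);
        }
    }
    ep_loss /= n;
    double val_loss = eng.eval_loss(Xv, Yv, 512);
    if (!std::isfinite(val_loss)) stop("non-finite validation loss at epoch %d", epoch);
    h_train.push_back(ep_loss);
    h_val.push_back(val_loss);
    h_lr.push_back(lr);
    stopped_epoch = epoch;

    if (val_loss < best_val) {
      best_val = val_loss;
      best_W = eng.W;
      best_epoch = epoch;
      wait_es = 0;
    } else {
      ++wait_es;
    }
    if (val_loss < plateau_best) {
      plateau_best = val_loss;
      wait_lr = 0;
    } else {
      ++wait_lr;
      if (wait_lr >= lr_patience) {
        if (lr > lr_floor) lr = std::max(lr * lr_factor, lr_floor);
        wait_lr = 0;
      }
    }
    if (wait_es >= es_patience) break;
  }

  if (restore_best && best_epoch > 0) eng.W = best_W;
  return List::create(
    _["weights"] = eng.get_weights(eng.W),
    _["train_loss"] = wrap(h_train),
    _["val_loss"] = wrap(h_val),
    _["lr"] = wrap(h_lr),
    _["best_epoch"] = best_epoch,
    _["stopped_epoch"] = stopped_epoch,
    _["best_val_loss"] = best_val);
}
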