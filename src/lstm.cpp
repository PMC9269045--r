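// Forget-gate LSTM for sequence-to-sequence joint-angle regression:
//   f(t) = sigmoid(W1f x(t) + W2f h(t-1) + bf)
//   i(t) = sigmoid(W1i x(t) + W2i h(t-1) + bi)
//   o(t) = sigmoid(W1o x(t) + W2o h(t-1) + bo)
//   g(t) = tanh   (W1g x(t) + W2g h(t-1) + bg)
//   s(t) = g(t) % i(t) + s(t-1) % f(t)
//   h(t) = tanh(s(t)) % o(t)
//   y(t) = Wy h(t) + by
// trained by truncated-window BPTT with Adam on a mean-squared-error loss.
// Single-threaded and fully deterministic given the initial weights.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Weights {
  mat W1f, W2f, W1i, W2i, W1o, W2o, W1g, W2g;
  vec bf, bi, bo, bg;
  rowvec Wy;
  double by;
};

Weights from_list(const Rcpp::List& w) {
  Weights out;
  out.W1f = Rcpp::as<mat>(w["W1f"]); out.W2f = Rcpp::as<mat>(w["W2f"]);
  out.W1i = Rcpp::as<mat>(w["W1i"]); out.W2i = Rcpp::as<mat>(w["W2i"]);
  out.W1o = Rcpp::as<mat>(w["W1o"]); out.W2o = Rcpp::as<mat>(w["W2o"]);
  out.W1g = Rcpp::as<mat>(w["W1g"]); out.W2g = Rcpp::as<mat>(w["W2g"]);
  out.bf = Rcpp::as<vec>(w["bf"]); out.bi = Rcpp::as<vec>(w["bi"]);
  out.bo = Rcpp::as<vec>(w["bo"]); out.bg = Rcpp::as<vec>(w["bg"]);
  out.Wy = Rcpp::as<rowvec>(w["Wy"]);
  out.by = Rcpp::as<double>(w["by"]);
  return out;
}

Rcpp::List to_list(const Weights& w) {
  return Rcpp::List::create(
      Rcpp::Named("W1f") = w.W1f, Rcpp::Named("W2f") = w.W2f,
      Rcpp::Named("bf") = w.bf,
      Rcpp::Named("W1i") = w.W1i, Rcpp::Named("W2i") = w.W2i,
      Rcpp::Named("bi") = w.bi,
      Rcpp::Named("W1o") = w.W1o, Rcpp::Named("W2o") = w.W2o,
      Rcpp::Named("bo") = w.bo,
      Rcpp::Named("W1g") = w.W1g, Rcpp::Named("W2g") = w.W2g,
      Rcpp::Named("bg") = w.bg,
      Rcpp::Named("Wy") = w.Wy, Rcpp::Named("by") = w.by);
}

inline vec sigmoid(const vec& z) { return 1.0 / (1.0 + exp(-z)); }

struct Cache {
  mat f, i, o, g, s, h, tanh_s;
  vec yhat;
};

// forward pass over one sequence; X is T x D
void forward(const Weights& w, const mat& X, Cache& c) {
  const uword T = X.n_rows, H = w.bf.n_elem;
  c.f.set_size(H, T); c.i.set_size(H, T); c.o.set_size(H, T);
  c.g.set_size(H, T); c.s.set_size(H, T); c.h.set_size(H, T);
  c.tanh_s.set_size(H, T); c.yhat.set_size(T);
  vec h_prev(H, fill::zeros), s_prev(H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    vec x = X.row(t).t();
    vec f = sigmoid(w.W1f * x + w.W2f * h_prev + w.bf);
    vec i = sigmoid(w.W1i * x + w.W2i * h_prev + w.bi);
    vec o = sigmoid(w.W1o * x + w.W2o * h_prev + w.bo);
    vec g = tanh(w.W1g * x + w.W2g * h_prev + w.bg);
    vec s = g % i + s_prev % f;
    vec ts = tanh(s);
    vec h = ts % o;
    c.f.col(t) = f; c.i.col(t) = i; c.o.col(t) = o; c.g.col(t) = g;
    c.s.col(t) = s; c.tanh_s.col(t) = ts; c.h.col(t) = h;
    c.yhat(t) = dot(w.Wy, h) + w.by;
    h_prev = h; s_prev = s;
  }
}

struct Grads {
  mat W1f, W2f, W1i, W2i, W1o, W2o, W1g, W2g;
  vec bf, bi, bo, bg;
  rowvec Wy;
  double by;
  void zeros_like(const Weights& w) {
    W1f.zeros(size(w.W1f)); W2f.zeros(size(w.W2f));
    W1i.zeros(size(w.W1i)); W2i.zeros(size(w.W2i));
    W1o.zeros(size(w.W1o)); W2o.zeros(size(w.W2o));
    W1g.zeros(size(w.W1g)); W2g.zeros(size(w.W2g));
    bf.zeros(size(w.bf)); bi.zeros(size(w.bi));
    bo.zeros(size(w.bo)); bg.zeros(size(w.bg));
    Wy.zeros(size(w.Wy)); by = 0.0;
  }
};

// backward pass (BPTT) for one sequence; returns the window loss
double backward(const Weights& w, const mat& X, const vec& y,
                const Cache& c, Grads& gr) {
  const uword T = X.n_rows, H = w.bf.n_elem;
  gr.zeros_like(w);
  vec dh_next(H, fill::zeros), ds_next(H, fill::zeros);
  vec err = c.yhat - y;
  double loss = dot(err, err) / T;
  for (uword t = T; t-- > 0;) {
    double dy = 2.0 * err(t) / T;
    gr.Wy += dy * c.h.col(t).t();
    gr.by += dy;
    vec dh = w.Wy.t() * dy + dh_next;
    vec ds = dh % c.o.col(t) % (1.0 - square(c.tanh_s.col(t))) + ds_next;
    vec s_prev = (t == 0) ? vec(H, fill::zeros) : vec(c.s.col(t - 1));
    vec h_prev = (t == 0) ? vec(H, fill::zeros) : vec(c.h.col(t - 1));
    vec do_ = dh % c.tanh_s.col(t);
    vec dg = ds % c.i.col(t);
    vec di = ds % c.g.col(t);
    vec df = ds % s_prev;
    // pre-activation gradients
    vec daf = df % c.f.col(t) % (1.0 - c.f.col(t));
    vec dai = di % c.i.col(t) % (1.0 - c.i.col(t));
    vec dao = do_ % c.o.col(t) % (1.0 - c.o.col(t));
    vec dag = dg % (1.0 - square(c.g.col(t)));
    rowvec x = X.row(t);
    gr.W1f += daf * x; gr.W2f += daf * h_prev.t(); gr.bf += daf;
    gr.W1i += dai * x; gr.W2i += dai * h_prev.t(); gr.bi += dai;
    gr.W1o += dao * x; gr.W2o += dao * h_prev.t(); gr.bo += dao;
    gr.W1g += dag * x; gr.W2g += dag * h_prev.t(); gr.bg += dag;
    dh_next = w.W2f.t() * daf + w.W2i.t() * dai + w.W2o.t() * dao +
              w.W2g.t() * dag;
    ds_next = ds % c.f.col(t);
  }
  return loss;
}

struct Adam {
  Grads m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8, lr = 1e-3;
  long t = 0;
  void init(const Weights& w, double lr_) {
    m.zeros_like(w); v.zeros_like(w); lr = lr_;
  }
  void upd(mat& W, mat& mM, mat& vM, const mat& g, double c1, double c2) {
    mM = b1 * mM + (1 - b1) * g;
    vM = b2 * vM + (1 - b2) * square(g);
    W -= lr * (mM / c1) / (sqrt(vM / c2) + eps);
  }
  void upd(vec& W, vec& mM, vec& vM, const vec& g, double c1, double c2) {
    mM = b1 * mM + (1 - b1) * g;
    vM = b2 * vM + (1 - b2) * square(g);
    W -= lr * (mM / c1) / (sqrt(vM / c2) + eps);
  }
  void upd(rowvec& W, rowvec& mM, rowvec& vM, const rowvec& g,
           double c1, double c2) {
    mM = b1 * mM + (1 - b1) * g;
    vM = b2 * vM + (1 - b2) * square(g);
    W -= lr * (mM / c1) / (sqrt(vM / c2) + eps);
  }
  void step(Weights& w, const Grads& g) {
    ++t;
    double c1 = 1 - std::pow(b1, (double)t);
    double c2 = 1 - std::pow(b2, (double)t);
    upd(w.W1f, m.W1f, v.W1f, g.W1f, c1, c2);
    upd(w.W2f, m.W2f, v.W2f, g.W2f, c1, c2);
    upd(w.W1i, m.W1i, v.W1i, g.W1i, c1, c2);
    upd(w.W2i, m.W2i, v.W2i, g.W2i, c1, c2);
    upd(w.W1o, m.W1o, v.W1o, g.W1o, c1, c2);
    upd(w.W2o, m.W2o, v.W2o, g.W2o, c1, c2);
    upd(w.W1g, m.W1g, v.W1g, g.W1g, c1, c2);
    upd(w.W2g, m.W2g, v.W2g, g.W2g, c1, c2);
    upd(w.bf, m.bf, v.bf, g.bf, c1, c2);
    upd(w.bi, m.bi, v.bi, g.bi, c1, c2);
    upd(w.bo, m.bo, v.bo, g.bo, c1, c2);
    upd(w.bg, m.bg, v.bg, g.bg, c1, c2);
    upd(w.Wy, m.Wy, v.Wy, g.Wy, c1, c2);
    m.by = b1 * m.by + (1 - b1) * g.by;
    v.by = b2 * v.by + (1 - b2) * g.by * g.by;
    w.by -= lr * (m.by / c1) / (std::sqrt(v.by / c2) + eps);
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector lstm_forward_cpp(const Rcpp::List& weights,
                                     const arma::mat& X) {
  Weights w = from_list(weights);
  Cache c;
  forward(w, X, c);
  return Rcpp::wrap(c.yhat);
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const Rcpp::List& Xs, const Rcpp::List& ys,
                          const Rcpp::List& weights, int epochs,
                          double learning_rate) {
  Weights w = from_list(weights);
  Adam adam;
  adam.init(w, learning_rate);
  const int nwin = Xs.size();
  std::vector<mat> X(nwin);
  std::vector<vec> y(nwin);
  for (int j = 0; j < nwin; ++j) {
    X[j] = Rcpp::as<mat>(Xs[j]);
    y[j] = Rcpp::as<vec>(ys[j]);
  }
  Cache c;
  Grads g;
  std::vector<double> history;
  history.reserve(epochs);
  bool diverged = false;
  for (int e = 0; e < epochs && !diverged; ++e) {
    double total = 0.0;
    for (int j = 0; j < nwin; ++j) {
      forward(w, X[j], c);
      double loss = backward(w, X[j], y[j], c, g);
      if (!std::isfinite(loss)) { diverged = true; break; }
      adam.step(w, g);
      total += loss;
    }
    history.push_back(total / nwin);
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = to_list(w),
      Rcpp::Named("loss_history") = history,
      Rcpp::Named("diverged") = diverged);
}
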