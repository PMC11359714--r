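// Stacked bidirectional LSTM forward pass and backpropagation through time.
// Parameters per direction are a concatenated gate matrix G (4H x (H+I)),
// gate row order [forget; input; output; candidate], and bias b (4H).
// Sequences are cubes with layout (features, batch, time).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct DirCache {
  cube f, i, o, g, c, h;  // each H x B x T
};

// One direction of one LSTM layer over the whole batch.
// reverse = true processes time back-to-front; outputs/caches are stored at
// the true time index either way.
static void lstm_dir_forward(const mat& G, const vec& b, const cube& X,
                             bool reverse, DirCache& cc) {
  const uword I = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = G.n_rows / 4;
  if (G.n_cols != H + I) Rcpp::stop("gate matrix column mismatch");
  cc.f.set_size(H, B, T); cc.i.set_size(H, B, T); cc.o.set_size(H, B, T);
  cc.g.set_size(H, B, T); cc.c.set_size(H, B, T); cc.h.set_size(H, B, T);
  mat h_prev(H, B, fill::zeros), c_prev(H, B, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    uword t = reverse ? (T - 1 - s) : s;
    mat A = G * join_cols(h_prev, X.slice(t));
    A.each_col() += b;
    mat f = sigmoid(A.rows(0, H - 1));
    mat ig = sigmoid(A.rows(H, 2 * H - 1));
    mat o = sigmoid(A.rows(2 * H, 3 * H - 1));
    mat g = tanh(A.rows(3 * H, 4 * H - 1));
    mat c = f % c_prev + ig % g;
    mat h = o % tanh(c);
    cc.f.slice(t) = f; cc.i.slice(t) = ig; cc.o.slice(t) = o;
    cc.g.slice(t) = g; cc.c.slice(t) = c; cc.h.slice(t) = h;
    h_prev = h; c_prev = c;
  }
}

// BPTT for one direction. dH is the upstream gradient w.r.t. h at each true
// time index. Fills dG, db and adds input gradients into dX.
static void lstm_dir_backward(const mat& G, const cube& X, bool reverse,
                              const DirCache& cc, const cube& dH,
                              mat& dG, vec& db, cube& dX) {
  const uword I = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = G.n_rows / 4;
  dG.zeros(4 * H, H + I);
  db.zeros(4 * H);
  mat dh_rec(H, B, fill::zeros), dc_rec(H, B, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    // reverse of the processing order
    uword t = reverse ? s : (T - 1 - s);
    bool first_step = reverse ? (t == T - 1) : (t == 0);
    mat h_prev(H, B, fill::zeros), c_prev(H, B, fill::zeros);
    if (!first_step) {
      uword tp = reverse ? (t + 1) : (t - 1);
      h_prev = cc.h.slice(tp);
      c_prev = cc.c.slice(tp);
    }
    mat f = cc.f.slice(t), ig = cc.i.slice(t), o = cc.o.slice(t),
        g = cc.g.slice(t), c = cc.c.slice(t);
    mat tc = tanh(c);
    mat dh = dH.slice(t) + dh_rec;
    mat dc = dc_rec + dh % o % (1.0 - tc % tc);
    mat da_o = dh % tc % o % (1.0 - o);
    mat da_f = dc % c_prev % f % (1.0 - f);
    mat da_i = dc % g % ig % (1.0 - ig);
    mat da_g = dc % ig % (1.0 - g % g);
    mat dA = join_cols(join_cols(da_f, da_i), join_cols(da_o, da_g));
    dG += dA * join_cols(h_prev, X.slice(t)).t();
    db += sum(dA, 1);
    mat dcomb = G.t() * dA;
    dh_rec = dcomb.rows(0, H - 1);
    dX.slice(t) += dcomb.rows(H, H + I - 1);
    dc_rec = dc % f;
  }
}

static void get_dir(const Rcpp::List& p, mat& G, vec& b) {
  G = Rcpp::as<mat>(p["G"]);
  b = Rcpp::as<vec>(p["b"]);
}

// Full forward through both stacked bidirectional layers plus the linear
// per-timestep readout. Returns predictions (targets x B x T) and, when
// keep = true, all caches needed for BPTT.
struct NetCache {
  DirCache l1f, l1b, l2f, l2b;
  cube Z1, Z2;
};

static cube net_forward(const Rcpp::List& params, const cube& X,
                        NetCache& nc) {
  mat G1f, G1b, G2f, G2b, Wr;
  vec b1f, b1b, b2f, b2b, br;
  get_dir(params["l1f"], G1f, b1f);
  get_dir(params["l1b"], G1b, b1b);
  get_dir(params["l2f"], G2f, b2f);
  get_dir(params["l2b"], G2b, b2b);
  Wr = Rcpp::as<mat>(params["Wr"]);
  br = Rcpp::as<vec>(params["br"]);
  const uword B = X.n_cols, T = X.n_slices;
  const uword H1 = G1f.n_rows / 4, H2 = G2f.n_rows / 4;
  lstm_dir_forward(G1f, b1f, X, false, nc.l1f);
  lstm_dir_forward(G1b, b1b, X, true, nc.l1b);
  nc.Z1.set_size(2 * H1, B, T);
  for (uword t = 0; t < T; ++t)
    nc.Z1.slice(t) = join_cols(nc.l1f.h.slice(t), nc.l1b.h.slice(t));
  lstm_dir_forward(G2f, b2f, nc.Z1, false, nc.l2f);
  lstm_dir_forward(G2b, b2b, nc.Z1, true, nc.l2b);
  nc.Z2.set_size(2 * H2, B, T);
  for (uword t = 0; t < T; ++t)
    nc.Z2.slice(t) = join_cols(nc.l2f.h.slice(t), nc.l2b.h.slice(t));
  cube Y(Wr.n_rows, B, T);
  for (uword t = 0; t < T; ++t) {
    mat y = Wr * nc.Z2.slice(t);
    y.each_col() += br;
    Y.slice(t) = y;
  }
  return Y;
}

// [[Rcpp::export]]
arma::cube cpp_bilstm_forward(Rcpp::List params, arma::cube X) {
  NetCache nc;
  return net_forward(params, X, nc);
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_loss_grad(Rcpp::List params, arma::cube X,
                                arma::cube Y) {
  NetCache nc;
  cube Yhat = net_forward(params, X, nc);
  const uword B = X.n_cols, T = X.n_slices;
  const double n = double(Yhat.n_elem);
  cube R = Yhat - Y;
  double loss = accu(R % R) / n;

  mat Wr = Rcpp::as<mat>(params["Wr"]);
  const uword H1 = Rcpp::as<mat>(Rcpp::as<Rcpp::List>(params["l1f"])["G"]).n_rows / 4;
  const uword H2 = Rcpp::as<mat>(Rcpp::as<Rcpp::List>(params["l2f"])["G"]).n_rows / 4;

  mat dWr(Wr.n_rows, Wr.n_cols, fill::zeros);
  vec dbr(Wr.n_rows, fill::zeros);
  cube dZ2(2 * H2, B, T);
  for (uword t = 0; t < T; ++t) {
    mat dy = 2.0 * R.slice(t) / n;
    dWr += dy * nc.Z2.slice(t).t();
    dbr += sum(dy, 1);
    dZ2.slice(t) = Wr.t() * dy;
  }
  cube dH2f = dZ2.rows(0, H2 - 1);
  cube dH2b = dZ2.rows(H2, 2 * H2 - 1);

  mat G2f, G2b, G1f, G1b; vec btmp;
  get_dir(params["l2f"], G2f, btmp);
  get_dir(params["l2b"], G2b, btmp);
  get_dir(params["l1f"], G1f, btmp);
  get_dir(params["l1b"], G1b, btmp);

  cube dZ1(2 * H1, B, T, fill::zeros);
  mat dG2f, dG2b, dG1f, dG1b;
  vec db2f, db2b, db1f, db1b;
  lstm_dir_backward(G2f, nc.Z1, false, nc.l2f, dH2f, dG2f, db2f, dZ1);
  lstm_dir_backward(G2b, nc.Z1, true, nc.l2b, dH2b, dG2b, db2b, dZ1);

  cube dH1f = dZ1.rows(0, H1 - 1);
  cube dH1b = dZ1.rows(H1, 2 * H1 - 1);
  cube dX(X.n_rows, B, T, fill::zeros);
  lstm_dir_backward(G1f, X, false, nc.l1f, dH1f, dG1f, db1f, dX);
  lstm_dir_backward(G1b, X, true, nc.l1b, dH1b, dG1b, db1b, dX);

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("l1f") = Rcpp::List::create(Rcpp::Named("G") = dG1f,
                                              Rcpp::Named("b") = db1f),
      Rcpp::Named("l1b") = Rcpp::List::create(Rcpp::Named("G") = dG1b,
                                              Rcpp::Named("b") = db1b),
      Rcpp::Named("l2f") = Rcpp::List::create(Rcpp::Named("G") = dG2f,
                                              Rcpp::Named("b") = db2f),
      Rcpp::Named("l2b") = Rcpp::List::create(Rcpp::Named("G") = dG2b,
                                              Rcpp::Named("b") = db2b),
      Rcpp::Named("Wr") = dWr,
      Rcpp::Named("br") = dbr));
}

// [[Rcpp::export]]
double cpp_bilstm_loss(Rcpp::List params, arma::cube X, arma::cube Y) {
  NetCache nc;
  cube Yhat = net_forward(params, X, nc);
  cube R = Yhat - Y;
  return accu(R % R) / double(Yhat.n_elem);
}

// Single-direction layer output, exposed for the layer-level operation.
// [[Rcpp::export]]
arma::cube cpp_lstm_dir(arma::mat G, arma::vec b, arma::cube X,
                        bool reverse) {
  DirCache cc;
  lstm_dir_forward(G, b, X, reverse, cc);
  return cc.h;
}

// Second-layer feature sequence (input to the readout), for closed-form
// refits of the linear readout.
// [[Rcpp::export]]
arma::cube cpp_bilstm_features(Rcpp::List params, arma::cube X) {
  NetCache nc;
  net_forward(params, X, nc);
  return nc.Z2;
}
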