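// Minimal LSTM machinery for the autoencoder anomaly detector and the
// sequence classifier: forward pass, backpropagation through time, and
// Adam / SGD-momentum / RMSprop updates. Gate semantics: sigmoid input,
// forget and output gates, tanh candidate and state activations. Weight
// layout stacks the four gates row-wise (rows [0,H) input, [H,2H) forget,
// [2H,3H) candidate, [3H,4H) output), so a hidden size H yields 4*H stacked
// input-weight rows.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct LstmParams {
  mat W;   // 4H x D
  mat U;   // 4H x H
  vec b;   // 4H
};

struct LstmCache {
  cube i, f, g, o, c, h;  // H x B x L
};

LstmParams init_lstm(int D, int H, std::mt19937_64 &rng) {
  std::uniform_real_distribution<double> uw(-1.0 / std::sqrt((double)D),
                                            1.0 / std::sqrt((double)D));
  std::uniform_real_distribution<double> uu(-1.0 / std::sqrt((double)H),
                                            1.0 / std::sqrt((double)H));
  LstmParams p;
  p.W.set_size(4 * H, D);
  p.U.set_size(4 * H, H);
  p.b.zeros(4 * H);
  for (uword k = 0; k < p.W.n_elem; ++k) p.W(k) = uw(rng);
  for (uword k = 0; k < p.U.n_elem; ++k) p.U(k) = uu(rng);
  // forget-gate bias starts at 1 (standard stabilization)
  p.b.subvec(H, 2 * H - 1).fill(1.0);
  return p;
}

inline mat sigmoid(const mat &x) { return 1.0 / (1.0 + exp(-x)); }

// forward over a D x B x L input cube; returns caches (H x B x L)
LstmCache lstm_forward(const cube &X, const LstmParams &p, int H) {
  const int B = X.n_cols, L = X.n_slices;
  LstmCache cc;
  cc.i.set_size(H, B, L); cc.f.set_size(H, B, L); cc.g.set_size(H, B, L);
  cc.o.set_size(H, B, L); cc.c.set_size(H, B, L); cc.h.set_size(H, B, L);
  mat h_prev(H, B, fill::zeros), c_prev(H, B, fill::zeros);
  for (int t = 0; t < L; ++t) {
    mat z = p.W * X.slice(t) + p.U * h_prev;
    z.each_col() += p.b;
    mat i_t = sigmoid(z.rows(0, H - 1));
    mat f_t = sigmoid(z.rows(H, 2 * H - 1));
    mat g_t = tanh(z.rows(2 * H, 3 * H - 1));
    mat o_t = sigmoid(z.rows(3 * H, 4 * H - 1));
    mat c_t = f_t % c_prev + i_t % g_t;
    mat h_t = o_t % tanh(c_t);
    cc.i.slice(t) = i_t; cc.f.slice(t) = f_t; cc.g.slice(t) = g_t;
    cc.o.slice(t) = o_t; cc.c.slice(t) = c_t; cc.h.slice(t) = h_t;
    h_prev = h_t; c_prev = c_t;
  }
  return cc;
}

struct LstmGrads {
  mat dW, dU;
  vec db;
  cube dX;  // D x B x L
};

// dh_out: upstream gradient on h_t per step (H x B x L)
LstmGrads lstm_backward(const cube &X, const LstmParams &p,
                        const LstmCache &cc, const cube &dh_out, int H) {
  const int D = X.n_rows, B = X.n_cols, L = X.n_slices;
  LstmGrads gr;
  gr.dW.zeros(4 * H, D); gr.dU.zeros(4 * H, H); gr.db.zeros(4 * H);
  gr.dX.set_size(D, B, L);
  mat dh_rec(H, B, fill::zeros), dc(H, B, fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    mat dh = dh_out.slice(t) + dh_rec;
    const mat &i_t = cc.i.slice(t), &f_t = cc.f.slice(t);
    const mat &g_t = cc.g.slice(t), &o_t = cc.o.slice(t);
    mat tc = tanh(cc.c.slice(t));
    mat do_ = dh % tc;
    dc += dh % o_t % (1.0 - tc % tc);
    mat c_prev = (t > 0) ? cc.c.slice(t - 1) : mat(H, B, fill::zeros);
    mat h_prev = (t > 0) ? cc.h.slice(t - 1) : mat(H, B, fill::zeros);
    mat di = dc % g_t, dg = dc % i_t, df = dc % c_prev;
    mat dz(4 * H, B);
    dz.rows(0, H - 1)         = di % i_t % (1.0 - i_t);
    dz.rows(H, 2 * H - 1)     = df % f_t % (1.0 - f_t);
    dz.rows(2 * H, 3 * H - 1) = dg % (1.0 - g_t % g_t);
    dz.rows(3 * H, 4 * H - 1) = do_ % o_t % (1.0 - o_t);
    gr.dW += dz * X.slice(t).t();
    gr.dU += dz * h_prev.t();
    gr.db += sum(dz, 1);
    gr.dX.slice(t) = p.W.t() * dz;
    dh_rec = p.U.t() * dz;
    dc = dc % f_t;
  }
  return gr;
}

// ---- optimizer state -------------------------------------------------------

struct OptState {
  std::vector<mat> m1, m2;
  int t = 0;
};

enum OptKind { ADAM, SGDM, RMSPROP };

// global gradient-norm clipping (standard LSTM stabilization)
void clip_grads(std::vector<mat *> &grads, double max_norm) {
  double total = 0.0;
  for (auto *g : grads) total += accu(*g % *g);
  total = std::sqrt(total);
  if (total > max_norm) {
    double s = max_norm / total;
    for (auto *g : grads) *g *= s;
  }
}

void opt_step(std::vector<mat *> params, std::vector<mat *> grads,
              OptState &st, OptKind kind, double lr) {
  clip_grads(grads, 1.0);
  if (st.m1.empty()) {
    for (auto *p : params) {
      st.m1.push_back(mat(p->n_rows, p->n_cols, fill::zeros));
      st.m2.push_back(mat(p->n_rows, p->n_cols, fill::zeros));
    }
  }
  st.t += 1;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  for (size_t k = 0; k < params.size(); ++k) {
    mat &g = *grads[k];
    switch (kind) {
      case ADAM: {
        st.m1[k] = b1 * st.m1[k] + (1 - b1) * g;
        st.m2[k] = b2 * st.m2[k] + (1 - b2) * (g % g);
        mat mhat = st.m1[k] / (1 - std::pow(b1, st.t));
        mat vhat = st.m2[k] / (1 - std::pow(b2, st.t));
        *params[k] -= lr * mhat / (sqrt(vhat) + eps);
        break;
      }
      case SGDM:
        st.m1[k] = b1 * st.m1[k] + g;
        *params[k] -= lr * st.m1[k];
        break;
      case RMSPROP:
        st.m2[k] = 0.9 * st.m2[k] + 0.1 * (g % g);
        *params[k] -= lr * g / (sqrt(st.m2[k]) + eps);
        break;
    }
  }
}

OptKind opt_kind(const std::string &name) {
  if (name == "adam") return ADAM;
  if (name == "sgdm") return SGDM;
  if (name == "rmsprop") return RMSPROP;
  Rcpp::stop("unknown optimizer '%s'", name.c_str());
}

LstmParams params_from_list(const Rcpp::List &l) {
  LstmParams p;
  p.W = Rcpp::as<mat>(l["W"]);
  p.U = Rcpp::as<mat>(l["U"]);
  p.b = Rcpp::as<vec>(l["b"]);
  return p;
}

Rcpp::List params_to_list(const LstmParams &p) {
  return Rcpp::List::create(Rcpp::Named("W") = p.W, Rcpp::Named("U") = p.U,
                            Rcpp::Named("b") = p.b);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_lstm_init")]]
Rcpp::List cpp_lstm_init(int input_dim, int hidden, int seed) {
  std::mt19937_64 rng(seed);
  return params_to_list(init_lstm(input_dim, hidden, rng));
}

// [[Rcpp::export(name = ".cpp_ae_init")]]
Rcpp::List cpp_ae_init(int hidden, int seed) {
  std::mt19937_64 rng(seed);
  LstmParams enc = init_lstm(1, hidden, rng);
  LstmParams dec = init_lstm(hidden, hidden, rng);
  std::uniform_real_distribution<double> uo(-1.0 / std::sqrt((double)hidden),
                                            1.0 / std::sqrt((double)hidden));
  mat Wo(1, hidden);
  for (uword k = 0; k < Wo.n_elem; ++k) Wo(k) = uo(rng);
  vec bo(1, fill::zeros);
  return Rcpp::List::create(Rcpp::Named("enc") = params_to_list(enc),
                            Rcpp::Named("dec") = params_to_list(dec),
                            Rcpp::Named("Wo") = Wo, Rcpp::Named("bo") = bo);
}

static cube chunks_to_cube(const mat &X) {
  // X: L x B chunk matrix -> 1 x B x L input cube
  cube C(1, X.n_cols, X.n_rows);
  for (uword t = 0; t < X.n_rows; ++t) C.slice(t) = X.row(t);
  return C;
}

// forward pass of the autoencoder on chunk matrix X (L x B); returns L x B
// reconstruction. The decoder emits the sequence in reverse order (the
// standard LSTM-autoencoder target reversal, which gives the decoder's
// first step a local dependency on the encoder's last input); callers
// receive the reconstruction flipped back into input order.
static mat ae_forward(const mat &X, const LstmParams &enc,
                      const LstmParams &dec, const mat &Wo, const vec &bo,
                      int H, const mat *drop_mask, LstmCache *enc_cc,
                      LstmCache *dec_cc, cube *dec_in) {
  const int L = X.n_rows, B = X.n_cols;
  cube Xin = chunks_to_cube(X);
  LstmCache ec = lstm_forward(Xin, enc, H);
  mat z = ec.h.slice(L - 1);
  if (drop_mask) z = z % (*drop_mask);
  cube Xd(H, B, L);
  for (int t = 0; t < L; ++t) Xd.slice(t) = z;  // repeat vector
  LstmCache dc = lstm_forward(Xd, dec, H);
  mat Y(L, B);
  for (int t = 0; t < L; ++t) {
    mat y = Wo * dc.h.slice(t);
    y.each_col() += bo;
    Y.row(t) = y;
  }
  if (enc_cc) *enc_cc = ec;
  if (dec_cc) *dec_cc = dc;
  if (dec_in) *dec_in = Xd;
  return Y;
}

// [[Rcpp::export(name = ".cpp_ae_predict")]]
arma::mat cpp_ae_predict(Rcpp::List weights, const arma::mat &X) {
  LstmParams enc = params_from_list(weights["enc"]);
  LstmParams dec = params_from_list(weights["dec"]);
  mat Wo = Rcpp::as<mat>(weights["Wo"]);
  vec bo = Rcpp::as<vec>(weights["bo"]);
  int H = enc.U.n_cols;
  mat Y = ae_forward(X, enc, dec, Wo, bo, H, nullptr, nullptr, nullptr,
                     nullptr);
  return flipud(Y);  // decoder emits in reverse order
}

// [[Rcpp::export(name = ".cpp_ae_train")]]
Rcpp::List cpp_ae_train(Rcpp::List weights, const arma::mat &X, int epochs,
                        int batch_size, double lr, double dropout,
                        std::string loss, std::string optimizer, int seed) {
  LstmParams enc = params_from_list(weights["enc"]);
  LstmParams dec = params_from_list(weights["dec"]);
  mat Wo = Rcpp::as<mat>(weights["Wo"]);
  vec bo = Rcpp::as<vec>(weights["bo"]);
  const int H = enc.U.n_cols;
  const int L = X.n_rows, N = X.n_cols;
  const bool mae = (loss == "mae");
  OptKind kind = opt_kind(optimizer);
  std::mt19937_64 rng(seed + 1000003LL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  OptState st;
  std::vector<double> history;
  history.reserve(epochs);
  std::vector<int> order(N);
  for (int k = 0; k < N; ++k) order[k] = k;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    // step decay: halve the rate at 1/2 and 3/4 of the epoch budget
    double lr_ep = lr;
    if (ep >= 3 * epochs / 4) lr_ep = lr * 0.25;
    else if (ep >= epochs / 2) lr_ep = lr * 0.5;
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < N; start += batch_size) {
      int end = std::min(start + batch_size, N);
      int B = end - start;
      mat Xb(L, B);
      for (int k = 0; k < B; ++k) Xb.col(k) = X.col(order[start + k]);
      mat mask(H, B, fill::ones);
      if (dropout > 0) {
        for (uword k = 0; k < mask.n_elem; ++k)
          mask(k) = (unif(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      }
      LstmCache ec, dc;
      cube Xd;
      mat Y = ae_forward(Xb, enc, dec, Wo, bo, H, &mask, &ec, &dc, &Xd);
      mat E = Y - flipud(Xb);  // reversed-target reconstruction
      double batch_loss;
      mat dY;
      if (mae) {
        batch_loss = accu(abs(E)) / E.n_elem;
        dY = sign(E) / (double)E.n_elem;
      } else {
        batch_loss = 0.5 * accu(E % E) / E.n_elem;
        dY = E / (double)E.n_elem;
      }
      if (!std::isfinite(batch_loss))
        Rcpp::stop("autoencoder training diverged (non-finite loss) at epoch %d",
                   ep + 1);
      ep_loss += batch_loss;
      n_batches += 1;
      // backward: output layer
      mat dWo(1, H, fill::zeros);
      vec dbo(1, fill::zeros);
      cube dh_dec(H, B, L, fill::zeros);
      for (int t = 0; t < L; ++t) {
        mat dy = dY.row(t);                     // 1 x B
        dWo += dy * dc.h.slice(t).t();
        dbo += sum(dy, 1);
        dh_dec.slice(t) = Wo.t() * dy;
      }
      LstmGrads gd = lstm_backward(Xd, dec, dc, dh_dec, H);
      // gradient into the repeated latent: sum over decoder steps
      mat dz(H, B, fill::zeros);
      for (int t = 0; t < L; ++t) dz += gd.dX.slice(t);
      dz = dz % mask;
      cube dh_enc(H, B, L, fill::zeros);
      dh_enc.slice(L - 1) = dz;
      cube Xin = chunks_to_cube(Xb);
      LstmGrads ge = lstm_backward(Xin, enc, ec, dh_enc, H);
      mat dbe(ge.db), dbd(gd.db);  // vec->mat for uniform optimizer handling
      mat be_m(enc.b), bd_m(dec.b), bo_m(bo);
      std::vector<mat *> params = {&enc.W, &enc.U, &be_m, &dec.W, &dec.U,
                                   &bd_m, &Wo, &bo_m};
      mat dbo_m(dbo);
      std::vector<mat *> grads = {&ge.dW, &ge.dU, &dbe, &gd.dW, &gd.dU,
                                  &dbd, &dWo, &dbo_m};
      opt_step(params, grads, st, kind, lr_ep);
      enc.b = be_m.col(0); dec.b = bd_m.col(0); bo = bo_m.col(0);
    }
    history.push_back(ep_loss / std::max(n_batches, 1));
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = Rcpp::List::create(
          Rcpp::Named("enc") = params_to_list(enc),
          Rcpp::Named("dec") = params_to_list(dec),
          Rcpp::Named("Wo") = Wo, Rcpp::Named("bo") = bo),
      Rcpp::Named("history") = history);
}

// ---- sequence classifier ---------------------------------------------------

// [[Rcpp::export(name = ".cpp_clf_init")]]
Rcpp::List cpp_clf_init(int input_dim, int hidden, int n_classes, int seed) {
  std::mt19937_64 rng(seed + 7LL);
  LstmParams lstm = init_lstm(input_dim, hidden, rng);
  std::uniform_real_distribution<double> uf(-1.0 / std::sqrt((double)hidden),
                                            1.0 / std::sqrt((double)hidden));
  mat Wf(n_classes, hidden);
  for (uword k = 0; k < Wf.n_elem; ++k) Wf(k) = uf(rng);
  vec bf(n_classes, fill::zeros);
  return Rcpp::List::create(Rcpp::Named("lstm") = params_to_list(lstm),
                            Rcpp::Named("Wf") = Wf, Rcpp::Named("bf") = bf);
}

static mat softmax_cols(mat z) {
  rowvec mx = max(z, 0);
  z.each_row() -= mx;
  mat e = exp(z);
  rowvec s = sum(e, 0);
  e.each_row() /= s;
  return e;
}

// [[Rcpp::export(name = ".cpp_clf_predict")]]
arma::mat cpp_clf_predict(Rcpp::List weights, const arma::cube &X) {
  LstmParams p = params_from_list(weights["lstm"]);
  mat Wf = Rcpp::as<mat>(weights["Wf"]);
  vec bf = Rcpp::as<vec>(weights["bf"]);
  const int H = p.U.n_cols, L = X.n_cols, B = X.n_slices;
  // X arrives as D x L x B; rearrange to D x B x L
  cube Xin(X.n_rows, B, L);
  for (int t = 0; t < L; ++t)
    for (int k = 0; k < B; ++k) Xin.slice(t).col(k) = X.slice(k).col(t);
  LstmCache cc = lstm_forward(Xin, p, H);
  mat logits = Wf * cc.h.slice(L - 1);
  logits.each_col() += bf;
  return softmax_cols(logits);  // C x B
}

// [[Rcpp::export(name = ".cpp_clf_train")]]
Rcpp::List cpp_clf_train(Rcpp::List weights, const arma::cube &X,
                         const arma::ivec &y, int epochs, int batch_size,
                         double lr, std::string optimizer, int seed) {
  LstmParams p = params_from_list(weights["lstm"]);
  mat Wf = Rcpp::as<mat>(weights["Wf"]);
  vec bf = Rcpp::as<vec>(weights["bf"]);
  const int H = p.U.n_cols;
  const int D = X.n_rows, L = X.n_cols, N = X.n_slices;
  const int C = Wf.n_rows;
  OptKind kind = opt_kind(optimizer);
  std::mt19937_64 rng(seed + 29LL);
  OptState st;
  std::vector<double> loss_hist, acc_hist;
  std::vector<int> order(N);
  for (int k = 0; k < N; ++k) order[k] = k;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    int n_batches = 0, n_correct = 0;
    for (int start = 0; start < N; start += batch_size) {
      int end = std::min(start + batch_size, N);
      int B = end - start;
      cube Xb(D, B, L);
      ivec yb(B);
      for (int k = 0; k < B; ++k) {
        int idx = order[start + k];
        yb(k) = y(idx);
        for (int t = 0; t < L; ++t) Xb.slice(t).col(k) = X.slice(idx).col(t);
      }
      LstmCache cc = lstm_forward(Xb, p, H);
      mat hL = cc.h.slice(L - 1);
      mat logits = Wf * hL;
      logits.each_col() += bf;
      mat probs = softmax_cols(logits);
      double batch_loss = 0.0;
      for (int k = 0; k < B; ++k) {
        batch_loss -= std::log(std::max(probs(yb(k), k), 1e-300));
        uword arg;
        probs.col(k).max(arg);
        if ((int)arg == yb(k)) n_correct += 1;
      }
      batch_loss /= B;
      if (!std::isfinite(batch_loss))
        Rcpp::stop("classifier training diverged (non-finite loss) at epoch %d",
                   ep + 1);
      ep_loss += batch_loss;
      n_batches += 1;
      mat dlog = probs;
      for (int k = 0; k < B; ++k) dlog(yb(k), k) -= 1.0;
      dlog /= (double)B;
      mat dWf = dlog * hL.t();
      vec dbf = sum(dlog, 1);
      cube dh(H, B, L, fill::zeros);
      dh.slice(L - 1) = Wf.t() * dlog;
      LstmGrads gr = lstm_backward(Xb, p, cc, dh, H);
      mat db_m(gr.db), b_m(p.b), bf_m(bf), dbf_m(dbf);
      std::vector<mat *> params = {&p.W, &p.U, &b_m, &Wf, &bf_m};
      std::vector<mat *> grads = {&gr.dW, &gr.dU, &db_m, &dWf, &dbf_m};
      opt_step(params, grads, st, kind, lr);
      p.b = b_m.col(0); bf = bf_m.col(0);
    }
    loss_hist.push_back(ep_loss / std::max(n_batches, 1));
    acc_hist.push_back((double)n_correct / N);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = Rcpp::List::create(
          Rcpp::Named("lstm") = params_to_list(p),
          Rcpp::Named("Wf") = Wf, Rcpp::Named("bf") = bf),
      Rcpp::Named("loss") = loss_hist, Rcpp::Named("accuracy") = acc_hist);
}

// [[Rcpp::export(name = ".cpp_ae_grad_debug")]]
Rcpp::List cpp_ae_grad_debug(Rcpp::List weights, const arma::mat &X,
                             std::string loss) {
  LstmParams enc = params_from_list(weights["enc"]);
  LstmParams dec = params_from_list(weights["dec"]);
  mat Wo = Rcpp::as<mat>(weights["Wo"]);
  vec bo = Rcpp::as<vec>(weights["bo"]);
  const int H = enc.U.n_cols;
  const int L = X.n_rows, B = X.n_cols;
  LstmCache ec, dc;
  cube Xd;
  mat Y = ae_forward(X, enc, dec, Wo, bo, H, nullptr, &ec, &dc, &Xd);
  mat E = Y - flipud(X);
  double lval;
  mat dY;
  if (loss == "mae") {
    lval = accu(abs(E)) / E.n_elem;
    dY = sign(E) / (double)E.n_elem;
  } else {
    lval = 0.5 * accu(E % E) / E.n_elem;
    dY = E / (double)E.n_elem;
  }
  mat dWo(1, H, fill::zeros);
  vec dbo(1, fill::zeros);
  cube dh_dec(H, B, L, fill::zeros);
  for (int t = 0; t < L; ++t) {
    mat dy = dY.row(t);
    dWo += dy * dc.h.slice(t).t();
    dbo += sum(dy, 1);
    dh_dec.slice(t) = Wo.t() * dy;
  }
  LstmGrads gd = lstm_backward(Xd, dec, dc, dh_dec, H);
  mat dz(H, B, fill::zeros);
  for (int t = 0; t < L; ++t) dz += gd.dX.slice(t);
  cube dh_enc(H, B, L, fill::zeros);
  dh_enc.slice(L - 1) = dz;
  cube Xin = chunks_to_cube(X);
  LstmGrads ge = lstm_backward(Xin, enc, ec, dh_enc, H);
  return Rcpp::List::create(
      Rcpp::Named("loss") = lval,
      Rcpp::Named("d_enc_W") = ge.dW, Rcpp::Named("d_enc_U") = ge.dU,
      Rcpp::Named("d_dec_W") = gd.dW, Rcpp::Named("d_dec_U") = gd.dU,
      Rcpp::Named("d_Wo") = dWo);
}
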