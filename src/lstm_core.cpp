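// Batched LSTM forward / backward / SGD-momentum training.
// Gate row order within the stacked weight matrices: input, forget,
// cell-candidate, output (H rows each). Sequence-to-one regression: the
// fully connected layer reads the top layer's hidden state at the last
// time step. Loss is the mean squared error over the mini-batch.
//
// Layers are processed sequentially over the whole time axis, so the
// input-weight products and all weight-gradient accumulations run as one
// GEMM over the flattened (time x batch) axis; only the recurrent products
// (Wh * h, Wh^T * dz) are stepwise.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Layer {
  mat Wx, Wh;
  vec b;
  int H;
};

// per-layer activations over the whole sequence (H x B x N cubes)
struct LayerState {
  cube i, f, g, o, tc, c, h;
};

static std::vector<Layer> layers_from_list(const Rcpp::List& layers) {
  std::vector<Layer> out;
  for (int l = 0; l < layers.size(); ++l) {
    Rcpp::List ly = layers[l];
    Layer L;
    L.Wx = Rcpp::as<mat>(ly["Wx"]);
    L.Wh = Rcpp::as<mat>(ly["Wh"]);
    L.b = Rcpp::as<vec>(ly["b"]);
    L.H = L.Wh.n_cols;
    out.push_back(L);
  }
  return out;
}

// flat view of a cube: d x (B*N), slice t occupying columns [t*B, (t+1)*B)
static mat flat_view(cube& c) {
  return mat(c.memptr(), c.n_rows, c.n_cols * c.n_slices, false, true);
}

// forward through all layers; returns predictions, fills states
static vec forward_all(const std::vector<Layer>& layers, const vec& fc_w,
                       double fc_b, cube& X, std::vector<LayerState>& st) {
  const int N = X.n_slices, B = X.n_cols, L = layers.size();
  st.resize(L);
  cube* input = &X;  // d_in x B x N
  for (int l = 0; l < L; ++l) {
    const Layer& ly = layers[l];
    const int H = ly.H;
    LayerState& s = st[l];
    s.i.set_size(H, B, N); s.f.set_size(H, B, N); s.g.set_size(H, B, N);
    s.o.set_size(H, B, N); s.tc.set_size(H, B, N); s.c.set_size(H, B, N);
    s.h.set_size(H, B, N);
    mat Xf = flat_view(*input);
    mat P = ly.Wx * Xf;          // 4H x (B*N), all time steps at once
    P.each_col() += ly.b;
    mat h_prev = zeros<mat>(H, B), c_prev = zeros<mat>(H, B);
    for (int t = 0; t < N; ++t) {
      mat z = P.cols(t * B, (t + 1) * B - 1) + ly.Wh * h_prev;
      s.i.slice(t) = 1.0 / (1.0 + exp(-z.rows(0, H - 1)));
      s.f.slice(t) = 1.0 / (1.0 + exp(-z.rows(H, 2 * H - 1)));
      s.g.slice(t) = tanh(z.rows(2 * H, 3 * H - 1));
      s.o.slice(t) = 1.0 / (1.0 + exp(-z.rows(3 * H, 4 * H - 1)));
      s.c.slice(t) = s.f.slice(t) % c_prev + s.i.slice(t) % s.g.slice(t);
      s.tc.slice(t) = tanh(s.c.slice(t));
      s.h.slice(t) = s.o.slice(t) % s.tc.slice(t);
      h_prev = s.h.slice(t);
      c_prev = s.c.slice(t);
    }
    input = &s.h;
  }
  return (fc_w.t() * st[L - 1].h.slice(N - 1)).t() + fc_b;
}

struct Grads {
  std::vector<mat> dWx, dWh;
  std::vector<vec> db;
  vec dfc_w;
  double dfc_b;
};

static double loss_and_grads(const std::vector<Layer>& layers,
                             const vec& fc_w, double fc_b, cube& X,
                             const vec& targets, Grads& G,
                             double* sum_sq = nullptr) {
  const int N = X.n_slices, B = X.n_cols, L = layers.size();
  std::vector<LayerState> st;
  vec pred = forward_all(layers, fc_w, fc_b, X, st);
  vec resid = pred - targets;
  double loss = accu(square(resid)) / B;
  if (sum_sq) *sum_sq = accu(square(resid));
  vec dy = 2.0 * resid / B;

  G.dWx.assign(L, mat());
  G.dWh.assign(L, mat());
  G.db.assign(L, vec());
  G.dfc_w = st[L - 1].h.slice(N - 1) * dy;
  G.dfc_b = accu(dy);

  // dH: incoming dL/dh for the current layer, all time steps
  cube dH;
  for (int l = L - 1; l >= 0; --l) {
    const Layer& ly = layers[l];
    const int H = ly.H;
    LayerState& s = st[l];
    if (l == L - 1) {
      dH = zeros<cube>(H, B, N);
      dH.slice(N - 1) = fc_w * dy.t();
    }
    cube dZ(4 * H, B, N);
    mat dh_rec = zeros<mat>(H, B), dc_rec = zeros<mat>(H, B);
    for (int t = N - 1; t >= 0; --t) {
      mat dh = dH.slice(t) + dh_rec;
      mat dc = dc_rec +
        dh % s.o.slice(t) % (1.0 - square(s.tc.slice(t)));
      mat c_prev = (t == 0) ? zeros<mat>(H, B) : s.c.slice(t - 1);
      mat& dz = dZ.slice(t);
      dz.rows(0, H - 1) =
        dc % s.g.slice(t) % s.i.slice(t) % (1.0 - s.i.slice(t));
      dz.rows(H, 2 * H - 1) =
        dc % c_prev % s.f.slice(t) % (1.0 - s.f.slice(t));
      dz.rows(2 * H, 3 * H - 1) =
        dc % s.i.slice(t) % (1.0 - square(s.g.slice(t)));
      dz.rows(3 * H, 4 * H - 1) =
        dh % s.tc.slice(t) % s.o.slice(t) % (1.0 - s.o.slice(t));
      dh_rec = ly.Wh.t() * dz;
      dc_rec = dc % s.f.slice(t);
    }
    mat Zf = flat_view(dZ);                      // 4H x (B*N)
    cube& inp = (l == 0) ? X : st[l - 1].h;
    G.dWx[l] = Zf * flat_view(inp).t();          // one GEMM over all steps
    // shifted hidden states: h_prev(t) = h(t-1), zero at t = 0
    mat Hprev(H, B * N, fill::zeros);
    if (N > 1) {
      Hprev.cols(B, B * N - 1) =
        mat(s.h.memptr(), H, B * (N - 1), false, true);
    }
    G.dWh[l] = Zf * Hprev.t();
    G.db[l] = sum(Zf, 1);
    if (l > 0) {                                 // pass down: dX = Wx^T dZ
      mat dXf = ly.Wx.t() * Zf;
      dH = cube(dXf.memptr(), layers[l - 1].H, B, N);
    }
  }
  return loss;
}

// [[Rcpp::export(name = ".lstm_forward_cpp")]]
arma::vec lstm_forward_cpp(Rcpp::List layers, arma::vec fc_w, double fc_b,
                           arma::cube X) {
  std::vector<Layer> ls = layers_from_list(layers);
  std::vector<LayerState> st;
  return forward_all(ls, fc_w, fc_b, X, st);
}

// [[Rcpp::export(name = ".lstm_loss_grad_cpp")]]
Rcpp::List lstm_loss_grad_cpp(Rcpp::List layers, arma::vec fc_w, double fc_b,
                              arma::cube X, arma::vec targets) {
  std::vector<Layer> ls = layers_from_list(layers);
  Grads G;
  double loss = loss_and_grads(ls, fc_w, fc_b, X, targets, G);
  Rcpp::List gl(ls.size());
  for (size_t l = 0; l < ls.size(); ++l) {
    gl[l] = Rcpp::List::create(Rcpp::Named("Wx") = G.dWx[l],
                               Rcpp::Named("Wh") = G.dWh[l],
                               Rcpp::Named("b") = G.db[l]);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("layers") = gl,
                            Rcpp::Named("fc_w") = G.dfc_w,
                            Rcpp::Named("fc_b") = G.dfc_b);
}

// perms: B_all x max_epochs matrix of 1-based shuffled indices (one column
// per epoch), drawn on the R side so determinism follows R's RNG.
// [[Rcpp::export(name = ".lstm_train_cpp")]]
Rcpp::List lstm_train_cpp(Rcpp::List layers, arma::vec fc_w, double fc_b,
                          arma::cube X, arma::vec targets,
                          arma::imat perms, double lr, double l2,
                          double momentum, int batch_size) {
  std::vector<Layer> ls = layers_from_list(layers);
  const int L = ls.size();
  const int B_all = X.n_cols;
  const int max_epochs = perms.n_cols;
  std::vector<mat> vWx(L), vWh(L);
  std::vector<vec> vb(L);
  for (int l = 0; l < L; ++l) {
    vWx[l] = zeros<mat>(ls[l].Wx.n_rows, ls[l].Wx.n_cols);
    vWh[l] = zeros<mat>(ls[l].Wh.n_rows, ls[l].Wh.n_cols);
    vb[l] = zeros<vec>(ls[l].b.n_elem);
  }
  vec vfc_w = zeros<vec>(fc_w.n_elem);
  double vfc_b = 0.0;
  vec curve(max_epochs);
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double sq_err = 0.0;
    for (int start = 0; start < B_all; start += batch_size) {
      int stop = std::min(start + batch_size, B_all) - 1;
      int B = stop - start + 1;
      cube Xb(X.n_rows, B, X.n_slices);
      vec tb(B);
      for (int j = 0; j < B; ++j) {
        int idx = perms(start + j, epoch) - 1;
        Xb.tube(span::all, span(j)) = X.tube(span::all, span(idx));
        tb(j) = targets(idx);
      }
      Grads G;
      double batch_sq = 0.0;
      loss_and_grads(ls, fc_w, fc_b, Xb, tb, G, &batch_sq);
      sq_err += batch_sq;
      for (int l = 0; l < L; ++l) {
        vWx[l] = momentum * vWx[l] - lr * (G.dWx[l] + l2 * ls[l].Wx);
        ls[l].Wx += vWx[l];
        vWh[l] = momentum * vWh[l] - lr * (G.dWh[l] + l2 * ls[l].Wh);
        ls[l].Wh += vWh[l];
        vb[l] = momentum * vb[l] - lr * G.db[l];
        ls[l].b += vb[l];
      }
      vfc_w = momentum * vfc_w - lr * (G.dfc_w + l2 * fc_w);
      fc_w += vfc_w;
      vfc_b = momentum * vfc_b - lr * G.dfc_b;
      fc_b += vfc_b;
    }
    curve(epoch) = std::sqrt(sq_err / B_all);
    if (!std::isfinite(curve(epoch))) {
      Rcpp::stop("LSTM training diverged (non-finite loss) at learn rate %g "
                 "in epoch %d", lr, epoch + 1);
    }
  }
  Rcpp::List out_layers(L);
  for (int l = 0; l < L; ++l) {
    out_layers[l] = Rcpp::List::create(Rcpp::Named("Wx") = ls[l].Wx,
                                       Rcpp::Named("Wh") = ls[l].Wh,
                                       Rcpp::Named("b") = ls[l].b,
                                       Rcpp::Named("H") = ls[l].H);
  }
  return Rcpp::List::create(Rcpp::Named("layers") = out_layers,
                            Rcpp::Named("fc_w") = fc_w,
                            Rcpp::Named("fc_b") = fc_b,
                            Rcpp::Named("curve") = curve);
}
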