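#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Network = time-distributed dense input layer (ReLU), a GRU whose final
// hidden state feeds a dense head (ReLU hidden layers), and a single
// sigmoid output unit. The GRU follows
//   z_t = sigma(W_z [h_{t-1}, x_t] + b_z)
//   r_t = sigma(W_r [h_{t-1}, x_t] + b_r)
//   c_t = tanh (W_c [r_t * h_{t-1}, x_t] + b_c)
//   h_t = (1 - z_t) * h_{t-1} + z_t * c_t
// Parameters arrive from R as a flat list in fixed order:
//   Wi, bi, Wz, bz, Wr, br, Wc, bc, W1, b1, ..., Wk, bk
// where the last head layer has one output unit.

struct Net {
  arma::mat Wi;
  arma::vec bi;
  arma::mat Wz, Wr, Wc;
  arma::vec bz, br, bc;
  std::vector<arma::mat> Wh;
  std::vector<arma::vec> bh;
};

static Net unpack(const List& p) {
  Net n;
  n.Wi = as<arma::mat>(p[0]);
  n.bi = as<arma::vec>(p[1]);
  n.Wz = as<arma::mat>(p[2]);
  n.bz = as<arma::vec>(p[3]);
  n.Wr = as<arma::mat>(p[4]);
  n.br = as<arma::vec>(p[5]);
  n.Wc = as<arma::mat>(p[6]);
  n.bc = as<arma::vec>(p[7]);
  for (int i = 8; i < p.size(); i += 2) {
    n.Wh.push_back(as<arma::mat>(p[i]));
    n.bh.push_back(as<arma::vec>(p[i + 1]));
  }
  return n;
}

static List pack(const Net& n, const List& tmpl) {
  List out = clone(tmpl);
  out[0] = n.Wi; out[1] = n.bi;
  out[2] = n.Wz; out[3] = n.bz;
  out[4] = n.Wr; out[5] = n.br;
  out[6] = n.Wc; out[7] = n.bc;
  for (size_t i = 0; i < n.Wh.size(); ++i) {
    out[8 + 2 * i] = n.Wh[i];
    out[9 + 2 * i] = n.bh[i];
  }
  return out;
}

static Net zeros_like(const Net& n) {
  Net z;
  z.Wi = arma::zeros(arma::size(n.Wi)); z.bi = arma::zeros(arma::size(n.bi));
  z.Wz = arma::zeros(arma::size(n.Wz)); z.bz = arma::zeros(arma::size(n.bz));
  z.Wr = arma::zeros(arma::size(n.Wr)); z.br = arma::zeros(arma::size(n.br));
  z.Wc = arma::zeros(arma::size(n.Wc)); z.bc = arma::zeros(arma::size(n.bc));
  for (size_t i = 0; i < n.Wh.size(); ++i) {
    z.Wh.push_back(arma::zeros(arma::size(n.Wh[i])));
    z.bh.push_back(arma::zeros(arma::size(n.bh[i])));
  }
  return z;
}

static inline arma::vec sigm(const arma::vec& a) { return 1.0 / (1.0 + arma::exp(-a)); }

struct Cache {
  arma::mat U, Z, R, C, Hs;          // T x (D2 or H)
  arma::mat Au;                      // input-layer pre-activations
  std::vector<arma::vec> hv;         // head activations, hv[0] = h_T
  std::vector<arma::vec> ha;         // head pre-activations
  double yhat;
};

static double forward_one(const Net& net, const arma::mat& Xs, Cache* cc) {
  const int T = Xs.n_rows;
  const int D2 = net.Wi.n_rows, H = net.Wz.n_rows;
  arma::vec h(H, arma::fill::zeros);
  if (cc) {
    cc->U.set_size(T, D2); cc->Au.set_size(T, D2);
    cc->Z.set_size(T, H); cc->R.set_size(T, H);
    cc->C.set_size(T, H); cc->Hs.set_size(T, H);
  }
  for (int t = 0; t < T; ++t) {
    arma::vec xt = Xs.row(t).t();
    arma::vec au = net.Wi * xt + net.bi;
    arma::vec u = arma::clamp(au, 0.0, arma::datum::inf);
    arma::vec v = arma::join_cols(h, u);
    arma::vec z = sigm(net.Wz * v + net.bz);
    arma::vec r = sigm(net.Wr * v + net.br);
    arma::vec vc = arma::join_cols(r % h, u);
    arma::vec c = arma::tanh(net.Wc * vc + net.bc);
    arma::vec hn = (1.0 - z) % h + z % c;
    if (cc) {
      cc->Au.row(t) = au.t(); cc->U.row(t) = u.t();
      cc->Z.row(t) = z.t(); cc->R.row(t) = r.t();
      cc->C.row(t) = c.t(); cc->Hs.row(t) = hn.t();
    }
    h = hn;
  }
  arma::vec v = h;
  if (cc) { cc->hv.clear(); cc->ha.clear(); cc->hv.push_back(v); }
  const int nl = (int)net.Wh.size();
  for (int l = 0; l < nl; ++l) {
    arma::vec a = net.Wh[l] * v + net.bh[l];
    if (l < nl - 1) v = arma::clamp(a, 0.0, arma::datum::inf);
    else v = sigm(a);
    if (cc) { cc->ha.push_back(a); cc->hv.push_back(v); }
  }
  double yhat = v(0);
  if (cc) cc->yhat = yhat;
  return yhat;
}

static const double PCLIP = 1e-7;

// Adds the gradient for one sample to `gr`; returns its loss.
static double backward_one(const Net& net, const arma::mat& Xs, double y,
                           int loss_type, Net& gr) {
  Cache cc;
  double p = forward_one(net, Xs, &cc);
  double loss, dlast;  // dlast = dL/d(pre-activation of the output unit)
  if (loss_type == 0) {
    double pc = std::min(std::max(p, PCLIP), 1.0 - PCLIP);
    loss = -(y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));
    dlast = p - y;  // sigmoid + BCE
  } else {
    loss = (p - y) * (p - y);
    dlast = 2.0 * (p - y) * p * (1.0 - p);
  }

  const int nl = (int)net.Wh.size();
  arma::vec delta(1);
  delta(0) = dlast;
  for (int l = nl - 1; l >= 0; --l) {
    gr.Wh[l] += delta * cc.hv[l].t();
    gr.bh[l] += delta;
    arma::vec dv = net.Wh[l].t() * delta;
    if (l > 0) delta = dv % arma::conv_to<arma::vec>::from(cc.ha[l - 1] > 0.0);
    else delta = dv;  // holds dh_T
  }
  arma::vec dh = delta;

  const int T = Xs.n_rows, H = net.Wz.n_rows, D2 = net.Wi.n_rows;
  for (int t = T - 1; t >= 0; --t) {
    arma::vec hprev = (t > 0) ? cc.Hs.row(t - 1).t()
                              : arma::vec(H, arma::fill::zeros);
    arma::vec z = cc.Z.row(t).t(), r = cc.R.row(t).t(), c = cc.C.row(t).t();
    arma::vec u = cc.U.row(t).t();

    arma::vec dz = dh % (c - hprev);
    arma::vec dc = dh % z;
    arma::vec dhprev = dh % (1.0 - z);

    arma::vec dac = dc % (1.0 - c % c);
    arma::vec vc = arma::join_cols(r % hprev, u);
    gr.Wc += dac * vc.t();
    gr.bc += dac;
    arma::vec dvc = net.Wc.t() * dac;
    arma::vec drh = dvc.head(H);
    arma::vec du = dvc.tail(D2);
    arma::vec dr = drh % hprev;
    dhprev += drh % r;

    arma::vec daz = dz % z % (1.0 - z);
    arma::vec dar = dr % r % (1.0 - r);
    arma::vec v = arma::join_cols(hprev, u);
    gr.Wz += daz * v.t();
    gr.bz += daz;
    gr.Wr += dar * v.t();
    gr.br += dar;
    dhprev += net.Wz.cols(0, H - 1).t() * daz + net.Wr.cols(0, H - 1).t() * dar;
    du += net.Wz.cols(H, H + D2 - 1).t() * daz +
          net.Wr.cols(H, H + D2 - 1).t() * dar;

    arma::vec dau = du % arma::conv_to<arma::vec>::from(cc.Au.row(t).t() > 0.0);
    gr.Wi += dau * Xs.row(t);
    gr.bi += dau;

    dh = dhprev;
  }
  return loss;
}

// [[Rcpp::export]]
arma::vec cpp_gru_predict(List params, const arma::cube& X) {
  Net net = unpack(params);
  arma::vec out(X.n_slices);
  for (arma::uword s = 0; s < X.n_slices; ++s)
    out(s) = forward_one(net, X.slice(s), nullptr);
  return out;
}

// [[Rcpp::export]]
List cpp_gru_loss_grad(List params, const arma::cube& X, const arma::vec& y,
                       int loss_type) {
  Net net = unpack(params);
  Net gr = zeros_like(net);
  double loss = 0.0;
  const int n = X.n_slices;
  for (int s = 0; s < n; ++s)
    loss += backward_one(net, X.slice(s), y(s), loss_type, gr);
  loss /= n;
  gr.Wi /= n; gr.bi /= n; gr.Wz /= n; gr.bz /= n;
  gr.Wr /= n; gr.br /= n; gr.Wc /= n; gr.bc /= n;
  for (size_t i = 0; i < gr.Wh.size(); ++i) { gr.Wh[i] /= n; gr.bh[i] /= n; }
  return List::create(_["loss"] = loss, _["grads"] = pack(gr, params));
}

// Exposes the raw GRU recursion on a sequence of already-transformed
// inputs U (T x input dim); returns the T x H matrix of hidden states.
// [[Rcpp::export]]
arma::mat cpp_gru_hidden(const arma::mat& Wz, const arma::vec& bz,
                         const arma::mat& Wr, const arma::vec& br,
                         const arma::mat& Wc, const arma::vec& bc,
                         const arma::mat& U) {
  const int T = U.n_rows, H = Wz.n_rows;
  arma::mat Hs(T, H);
  arma::vec h(H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::vec u = U.row(t).t();
    arma::vec v = arma::join_cols(h, u);
    arma::vec z = sigm(Wz * v + bz);
    arma::vec r = sigm(Wr * v + br);
    arma::vec vc = arma::join_cols(r % h, u);
    arma::vec c = arma::tanh(Wc * vc + bc);
    h = (1.0 - z) % h + z % c;
    Hs.row(t) = h.t();
  }
  return Hs;
}

struct Adam {
  Net m, v;
  long t = 0;
  Adam(const Net& n) : m(zeros_like(n)), v(zeros_like(n)) {}
};

static void adam_update_mat(arma::mat& w, const arma::mat& g, arma::mat& m,
                            arma::mat& v, double lr, double b1, double b2,
                            double wd, double eps, double bc1, double bc2) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps) + lr * wd * w;
}

static void adam_update_vec(arma::vec& w, const arma::vec& g, arma::vec& m,
                            arma::vec& v, double lr, double b1, double b2,
                            double wd, double eps, double bc1, double bc2) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps) + lr * wd * w;
}

static void eval_set(const Net& net, const arma::cube& X, const arma::vec& y,
                     int loss_type, double* loss_out, double* metric_out) {
  const int n = X.n_slices;
  if (n == 0) { *loss_out = NA_REAL; *metric_out = NA_REAL; return; }
  double loss = 0.0, metric = 0.0;
  for (int s = 0; s < n; ++s) {
    double p = forward_one(net, X.slice(s), nullptr);
    if (loss_type == 0) {
      double pc = std::min(std::max(p, PCLIP), 1.0 - PCLIP);
      loss += -(y(s) * std::log(pc) + (1.0 - y(s)) * std::log(1.0 - pc));
      metric += ((p > 0.5) == (y(s) > 0.5)) ? 1.0 : 0.0;
    } else {
      double e = (p - y(s)) * (p - y(s));
      loss += e;
      metric += e;
    }
  }
  *loss_out = loss / n;
  *metric_out = (loss_type == 0) ? metric / n : std::sqrt(metric / n);
}

// Full training loop: mini-batch ADAM with decoupled weight decay.
// `perms` holds one 0-based sample order per epoch (n_train x n_epochs),
// generated from R's RNG so the whole run is reproducible from one seed.
// [[Rcpp::export]]
List cpp_gru_train(List params, const arma::cube& Xtr, const arma::vec& ytr,
                   const arma::cube& Xval, const arma::vec& yval,
                   const arma::imat& perms, int batch, double lr, double beta1,
                   double beta2, double wd, double eps, int loss_type) {
  Net net = unpack(params);
  Adam ad(net);
  const int n = Xtr.n_slices, n_epochs = perms.n_cols;
  arma::mat history(n_epochs, 4);
  for (int ep = 0; ep < n_epochs; ++ep) {
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch) {
      int end = std::min(start + batch, n);
      Net gr = zeros_like(net);
      double bl = 0.0;
      for (int b = start; b < end; ++b) {
        int s = perms(b, ep);
        bl += backward_one(net, Xtr.slice(s), ytr(s), loss_type, gr);
      }
      int bs = end - start;
      bl /= bs;
      gr.Wi /= bs; gr.bi /= bs; gr.Wz /= bs; gr.bz /= bs;
      gr.Wr /= bs; gr.br /= bs; gr.Wc /= bs; gr.bc /= bs;
      for (size_t i = 0; i < gr.Wh.size(); ++i) { gr.Wh[i] /= bs; gr.bh[i] /= bs; }
      if (!std::isfinite(bl)) stop("non-finite training loss");
      ad.t += 1;
      double bc1 = 1.0 - std::pow(beta1, (double)ad.t);
      double bc2 = 1.0 - std::pow(beta2, (double)ad.t);
      adam_update_mat(net.Wi, gr.Wi, ad.m.Wi, ad.v.Wi, lr, beta1, beta2, wd, eps, bc1, bc2);
      adam_update_vec(net.bi, gr.bi, ad.m.bi, ad.v.bi, lr, beta1, beta2, wd, eps, bc1, bc2);
      adam_update_mat(net.Wz, gr.Wz, ad.m.Wz, ad.v.Wz, lr, beta1, beta2, wd, eps, bc1, bc2);
      adam_update_vec(net.bz, gr.bz, ad.m.bz, ad.v.bz, lr, beta1, beta2, wd, eps, bc1, bc2);
      adam_update_mat(net.Wr, gr.Wr, ad.m.Wr, ad.v.Wr, lr, beta1, beta2, wd, eps, bc1, bc2);
      adam_update_vec(net.br, gr.br, ad.m.br, ad.v.br, lr, beta1, beta2, wd, eps, bc1, bc2);
      adam_update_mat(net.Wc, gr.Wc, ad.m.Wc, ad.v.Wc, lr, beta1, beta2, wd, eps, bc1, bc2);
      adam_update_vec(net.bc, gr.bc, ad.m.bc, ad.v.bc, lr, beta1, beta2, wd, eps, bc1, bc2);
      for (size_t i = 0; i < net.Wh.size(); ++i) {
        adam_update_mat(net.Wh[i], gr.Wh[i], ad.m.Wh[i], ad.v.Wh[i], lr, beta1, beta2, wd, eps, bc1, bc2);
        adam_update_vec(net.bh[i], gr.bh[i], ad.m.bh[i], ad.v.bh[i], lr, beta1, beta2, wd, eps, bc1, bc2);
      }
      ep_loss += bl;
      ++n_batches;
    }
    double trl, trm, vl, vm;
    eval_set(net, Xtr, ytr, loss_type, &trl, &trm);
    eval_set(net, Xval, yval, loss_type, &vl, &vm);
    history(ep, 0) = trl; history(ep, 1) = trm;
    history(ep, 2) = vl; history(ep, 3) = vm;
    (void)ep_loss; (void)n_batches;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = pack(net, params), _["history"] = history);
}
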