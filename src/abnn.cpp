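// Core numerics for the MC-dropout neural-network chain.
//
// Layer convention: layerWidths k_1..k_L with k_L = 1; every layer has a
// weight matrix (fan_in x k_l) and a bias vector, and the activation is
// applied at every layer.  Dropout sites: one Bernoulli mask on the input
// dimension (retention p1, masks rows of W_1) and one per hidden-layer
// output (retention p2, masks rows of W_{l+1}).  Inverted scaling: masked
// weights are multiplied by z/p at train and predict time, so each
// per-iteration model is the thinned model actually used for prediction.
//
// All randomness is drawn from R's RNG (unif_rand) so that set.seed() at
// the R level makes every run bit-reproducible.

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline mat act_apply(const mat& z, int act) {
  if (act == 0) return z;                      // linear
  if (act == 1) return arma::tanh(z);          // tanh = 2/(1+e^{-2x}) - 1
  return arma::clamp(z, 0.0, arma::datum::inf); // relu
}

// derivative given pre-activation z and activation h = sigma(z)
static inline mat act_deriv(const mat& z, const mat& h, int act) {
  if (act == 0) return arma::ones<mat>(z.n_rows, z.n_cols);
  if (act == 1) return 1.0 - arma::square(h);
  return arma::conv_to<mat>::from(z > 0.0);
}

struct Net {
  std::vector<mat> W;
  std::vector<vec> b;
  int act;
};

static Net net_from_lists(List W_, List b_, int act) {
  Net net;
  net.act = act;
  for (int l = 0; l < W_.size(); ++l) {
    net.W.push_back(as<mat>(W_[l]));
    net.b.push_back(as<vec>(b_[l]));
  }
  return net;
}

// masks[0] has length fan-in of layer 1 (input site, retention p1);
// masks[l] (l >= 1) has length k_l (output of hidden layer l, retention p2).
// An empty vector means "no mask at this site".
static std::vector<vec> masks_from_list(List masks_, int L) {
  std::vector<vec> masks(L);
  if (masks_.size() == 0) return masks;
  for (int l = 0; l < L && l < masks_.size(); ++l) {
    RObject m = masks_[l];
    if (!m.isNULL()) masks[l] = as<vec>(m);
  }
  return masks;
}

// effective (thinned, 1/p-scaled) weights for one layer
static mat effective_W(const mat& W, const vec& mask, double retain) {
  if (mask.n_elem == 0) return W;
  mat We = W;
  We.each_col() %= (mask / retain);
  return We;
}

// Xt is the TRANSPOSED input (fan_in x n); keeping the design matrix in
// this orientation makes mini-batch extraction a contiguous column gather
// and feeds BLAS a transpose flag instead of a physical copy.
static void forward_pass(const Net& net, const std::vector<vec>& masks,
                         double p1, double p2, const mat& Xt,
                         std::vector<mat>& Z, std::vector<mat>& H) {
  int L = net.W.size();
  Z.resize(L);
  H.resize(L);
  for (int l = 0; l < L; ++l) {
    double retain = (l == 0) ? p1 : p2;
    mat We = effective_W(net.W[l], masks[l], retain);
    Z[l] = (l == 0) ? mat(Xt.t() * We) : mat(H[l - 1] * We);
    Z[l].each_row() += net.b[l].t();
    H[l] = act_apply(Z[l], net.act);
  }
}

static vec predict_net(const Net& net, const std::vector<vec>& masks,
                       double p1, double p2, const mat& Xt) {
  std::vector<mat> Z, H;
  forward_pass(net, masks, p1, p2, Xt, Z, H);
  return H.back().col(0);
}

// Gradient of the squared-error data loss (1/(2m)) * sum (y - yhat)^2 over
// the rows of X.  Penalties are not included (decoupled decay is applied in
// the update step); `coupled` adds the l2 gradients 2*lambda*theta for the
// plain-GD ridge path.
static void backprop_net(const Net& net, const std::vector<vec>& masks,
                         double p1, double p2, const mat& Xt, const vec& y,
                         std::vector<mat>& gW, std::vector<vec>& gb,
                         bool coupled, double lam1, double lam2, double lam3) {
  int L = net.W.size();
  std::vector<mat> Z, H;
  forward_pass(net, masks, p1, p2, Xt, Z, H);
  double m = (double)Xt.n_cols;
  gW.resize(L);
  gb.resize(L);
  mat dH = (H[L - 1] - mat(y)) / m;  // dL/dH_L, n x 1
  for (int l = L - 1; l >= 0; --l) {
    mat dZ = dH % act_deriv(Z[l], H[l], net.act);
    mat gWe = (l == 0) ? mat(Xt * dZ) : mat(H[l - 1].t() * dZ);
    gb[l] = arma::sum(dZ, 0).t();
    if (l > 0) {
      double retain = p2;
      mat We = effective_W(net.W[l], masks[l], retain);
      dH = dZ * We.t();
    }
    // chain rule through W_eff = diag(mask/p) W: same row scaling
    if (masks[l].n_elem > 0) {
      double retain = (l == 0) ? p1 : p2;
      gWe.each_col() %= (masks[l] / retain);
    }
    if (coupled) {
      double lam = (l == 0) ? lam1 : lam2;
      gWe += 2.0 * lam * net.W[l];
      gb[l] += 2.0 * lam3 * net.b[l];
    }
    gW[l] = gWe;
  }
}

// [[Rcpp::export]]
List cpp_forward(List W_, List b_, int act, arma::mat X, List masks_,
                 double p1, double p2) {
  Net net = net_from_lists(W_, b_, act);
  std::vector<vec> masks = masks_from_list(masks_, net.W.size());
  std::vector<mat> Z, H;
  mat Xt = X.t();
  forward_pass(net, masks, p1, p2, Xt, Z, H);
  List Zl(Z.size()), Hl(H.size());
  for (size_t l = 0; l < Z.size(); ++l) {
    Zl[l] = Z[l];
    Hl[l] = H[l];
  }
  return List::create(_["pred"] = H.back().col(0), _["preact"] = Zl,
                      _["activations"] = Hl);
}

// [[Rcpp::export]]
List cpp_backprop(List W_, List b_, int act, arma::mat X, arma::vec y,
                  List masks_, double p1, double p2, bool coupled,
                  double lam1, double lam2, double lam3) {
  Net net = net_from_lists(W_, b_, act);
  std::vector<vec> masks = masks_from_list(masks_, net.W.size());
  std::vector<mat> gW;
  std::vector<vec> gb;
  mat Xt = X.t();
  backprop_net(net, masks, p1, p2, Xt, y, gW, gb, coupled, lam1, lam2, lam3);
  List gWl(gW.size()), gbl(gb.size());
  for (size_t l = 0; l < gW.size(); ++l) {
    gWl[l] = gW[l];
    gbl[l] = gb[l];
  }
  return List::create(_["W"] = gWl, _["b"] = gbl);
}


// ---- one-hot fast path -----------------------------------------------------
// For one-hot designs the dense n x 3p indicator matrix is redundant: row i
// has exactly one 1 per marker triple, at column code(j, i).  Storing the
// p x n matrix of those column indices lets layer 1 be computed by table
// lookup (one weight read per marker) instead of a dense product, which is
// what makes the desk-scale chain lengths cheap.  Deeper layers are tiny
// and stay on the generic path.

static void forward_codes(const Net& net, const std::vector<vec>& masks,
                          double p1, double p2, const arma::umat& Cb,
                          std::vector<mat>& Z, std::vector<mat>& H) {
  int L = net.W.size();
  Z.resize(L);
  H.resize(L);
  int nb = Cb.n_cols, p = Cb.n_rows;
  mat We0 = effective_W(net.W[0], masks[0], p1);
  int k = We0.n_cols;
  mat Z0(nb, k);
  for (int i = 0; i < nb; ++i) {
    const arma::uword* c = Cb.colptr(i);
    for (int kk = 0; kk < k; ++kk) {
      const double* w = We0.colptr(kk);
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += w[c[j]];
      Z0(i, kk) = s;
    }
  }
  Z0.each_row() += net.b[0].t();
  Z[0] = Z0;
  H[0] = act_apply(Z0, net.act);
  for (int l = 1; l < L; ++l) {
    mat We = effective_W(net.W[l], masks[l], p2);
    Z[l] = H[l - 1] * We;
    Z[l].each_row() += net.b[l].t();
    H[l] = act_apply(Z[l], net.act);
  }
}

static vec predict_codes(const Net& net, const arma::umat& Cb) {
  std::vector<vec> nomask(net.W.size());
  std::vector<mat> Z, H;
  forward_codes(net, nomask, 1.0, 1.0, Cb, Z, H);
  return H.back().col(0);
}

static void backprop_codes(const Net& net, const std::vector<vec>& masks,
                           double p1, double p2, const arma::umat& Cb,
                           const vec& y, std::vector<mat>& gW,
                           std::vector<vec>& gb, bool coupled, double lam1,
                           double lam2, double lam3) {
  int L = net.W.size();
  std::vector<mat> Z, H;
  forward_codes(net, masks, p1, p2, Cb, Z, H);
  double m = (double)Cb.n_cols;
  gW.resize(L);
  gb.resize(L);
  mat dH = (H[L - 1] - mat(y)) / m;
  for (int l = L - 1; l >= 1; --l) {
    mat dZ = dH % act_deriv(Z[l], H[l], net.act);
    gW[l] = H[l - 1].t() * dZ;
    gb[l] = arma::sum(dZ, 0).t();
    mat We = effective_W(net.W[l], masks[l], p2);
    dH = dZ * We.t();
    if (masks[l].n_elem > 0) gW[l].each_col() %= (masks[l] / p2);
    if (coupled) {
      gW[l] += 2.0 * lam2 * net.W[l];
      gb[l] += 2.0 * lam3 * net.b[l];
    }
  }
  mat dZ = dH % act_deriv(Z[0], H[0], net.act);
  int nb = Cb.n_cols, p = Cb.n_rows, k = net.W[0].n_cols;
  mat gWe(net.W[0].n_rows, k, arma::fill::zeros);
  for (int i = 0; i < nb; ++i) {
    const arma::uword* c = Cb.colptr(i);
    for (int kk = 0; kk < k; ++kk) {
      double* g = gWe.colptr(kk);
      double d = dZ(i, kk);
      for (int j = 0; j < p; ++j) g[c[j]] += d;
    }
  }
  gb[0] = arma::sum(dZ, 0).t();
  if (masks[0].n_elem > 0) gWe.each_col() %= (masks[0] / p1);
  if (coupled) {
    gWe += 2.0 * lam1 * net.W[0];
    gb[0] += 2.0 * lam3 * net.b[0];
  }
  gW[0] = gWe;
}

struct AdamState {
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  long t = 0;
};

// One ADAM step with decoupled weight decay (factor 1 - eta*lambda/batch on
// each parameter group).  lam1: input weights, lam2: deeper weights,
// lam3: biases.
static void adam_step(Net& net, AdamState& st, const std::vector<mat>& gW,
                      const std::vector<vec>& gb, double eta, double beta1,
                      double beta2, double eps, double lam1, double lam2,
                      double lam3, double batch) {
  st.t += 1;
  double c1 = 1.0 - std::pow(beta1, (double)st.t);
  double c2 = 1.0 - std::pow(beta2, (double)st.t);
  int L = net.W.size();
  for (int l = 0; l < L; ++l) {
    double lamW = (l == 0) ? lam1 : lam2;
    double decayW = 1.0 - eta * lamW / batch;
    double decayB = 1.0 - eta * lam3 / batch;
    st.mW[l] = beta1 * st.mW[l] + (1.0 - beta1) * gW[l];
    st.vW[l] = beta2 * st.vW[l] + (1.0 - beta2) * arma::square(gW[l]);
    st.mb[l] = beta1 * st.mb[l] + (1.0 - beta1) * gb[l];
    st.vb[l] = beta2 * st.vb[l] + (1.0 - beta2) * arma::square(gb[l]);
    net.W[l] = decayW * net.W[l] -
               eta * (st.mW[l] / c1) / (arma::sqrt(st.vW[l] / c2) + eps);
    net.b[l] = decayB * net.b[l] -
               eta * (st.mb[l] / c1) / (arma::sqrt(st.vb[l] / c2) + eps);
  }
}

// [[Rcpp::export]]
List cpp_adam_step(List W_, List b_, List mW_, List vW_, List mb_, List vb_,
                   int t, List gW_, List gb_, double eta, double beta1,
                   double beta2, double eps, double lam1, double lam2,
                   double lam3, double batch) {
  Net net = net_from_lists(W_, b_, 0);
  int L = net.W.size();
  AdamState st;
  st.t = t;
  std::vector<mat> gW;
  std::vector<vec> gb;
  for (int l = 0; l < L; ++l) {
    st.mW.push_back(as<mat>(mW_[l]));
    st.vW.push_back(as<mat>(vW_[l]));
    st.mb.push_back(as<vec>(mb_[l]));
    st.vb.push_back(as<vec>(vb_[l]));
    gW.push_back(as<mat>(gW_[l]));
    gb.push_back(as<vec>(gb_[l]));
  }
  double maxlam = std::max(lam1, std::max(lam2, lam3));
  if (eta * maxlam / batch >= 1.0)
    stop("weight-decay factor 1 - eta*lambda/batch is not positive");
  adam_step(net, st, gW, gb, eta, beta1, beta2, eps, lam1, lam2, lam3, batch);
  List Wl(L), bl(L), mWl(L), vWl(L), mbl(L), vbl(L);
  for (int l = 0; l < L; ++l) {
    Wl[l] = net.W[l];
    bl[l] = net.b[l];
    mWl[l] = st.mW[l];
    vWl[l] = st.vW[l];
    mbl[l] = st.mb[l];
    vbl[l] = st.vb[l];
  }
  return List::create(_["W"] = Wl, _["b"] = bl, _["mW"] = mWl, _["vW"] = vWl,
                      _["mb"] = mbl, _["vb"] = vbl, _["t"] = (int)st.t);
}

static vec sample_bernoulli(int n, double p) {
  vec z(n);
  if (p >= 1.0) {
    z.ones();
    return z;
  }
  for (int i = 0; i < n; ++i) z[i] = (unif_rand() < p) ? 1.0 : 0.0;
  return z;
}

// Fisher-Yates shuffle of 0..n-1 driven by R's RNG
static arma::uvec shuffled_indices(int n) {
  arma::uvec idx = arma::regspace<arma::uvec>(0, n - 1);
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

// The MC-dropout chain.  Per iteration t: sample fresh masks, run one
// optimization pass over the training data (mini-batched) continuing from
// the current parameters, then record the thinned model omega^t = z .* W / p,
// its test predictions, MSE_t and MAE_t.  Posterior first/second moments of
// omega are accumulated over iterations t > burnin with 1/(T - burnin)
// normalization.
//
// optimizer: 0 = full-batch plain GD, 1 = SGD (batch 1), 2 = mini-batch ADAM.
// steps_per_iter <= 0 means one full pass over the training data.
// [[Rcpp::export]]
List cpp_run_chain(arma::mat X, arma::vec y, arma::mat Xtest, arma::vec ytest,
                   List W0, List b0, int act, double p1, double p2,
                   bool joint_triples, double lam1, double lam2, double lam3,
                   double eta, double beta1, double beta2, double eps,
                   int batch, int T, int burnin, int optimizer,
                   bool coupled, bool keep_snapshots, int steps_per_iter,
                   arma::umat codes_train, arma::umat codes_test,
                   List adam0) {
  Net net = net_from_lists(W0, b0, act);
  int L = net.W.size();
  bool fast = codes_train.n_elem > 0;
  int n = fast ? codes_train.n_cols : X.n_rows;
  int ntest = fast ? codes_test.n_cols : Xtest.n_rows;
  int d0 = fast ? net.W[0].n_rows : X.n_cols;
  mat Xt = fast ? mat() : mat(X.t());
  mat Xtest_t = fast ? mat() : mat(Xtest.t());
  if (optimizer == 0) batch = n;
  if (optimizer == 1) batch = 1;
  if (batch > n) batch = n;
  double maxlam = std::max(lam1, std::max(lam2, lam3));
  if (optimizer == 2 && eta * maxlam / batch >= 1.0)
    stop("weight-decay factor 1 - eta*lambda/batch is not positive");

  AdamState st;
  if (adam0.size() > 0) {
    List mW_ = adam0["mW"], vW_ = adam0["vW"], mb_ = adam0["mb"],
         vb_ = adam0["vb"];
    st.t = as<int>(adam0["t"]);
    for (int l = 0; l < L; ++l) {
      st.mW.push_back(as<mat>(mW_[l]));
      st.vW.push_back(as<mat>(vW_[l]));
      st.mb.push_back(as<vec>(mb_[l]));
      st.vb.push_back(as<vec>(vb_[l]));
    }
  } else {
    for (int l = 0; l < L; ++l) {
      st.mW.push_back(arma::zeros<mat>(net.W[l].n_rows, net.W[l].n_cols));
      st.vW.push_back(arma::zeros<mat>(net.W[l].n_rows, net.W[l].n_cols));
      st.mb.push_back(arma::zeros<vec>(net.b[l].n_elem));
      st.vb.push_back(arma::zeros<vec>(net.b[l].n_elem));
    }
  }

  vec mse(T, arma::fill::value(NA_REAL));
  vec mae(T, arma::fill::value(NA_REAL));
  mat preds;
  if (ntest > 0) preds.set_size(T, ntest);
  preds.fill(NA_REAL);

  // accumulators for omega moments over retained iterations
  std::vector<mat> sW(L), sW2(L);
  std::vector<vec> sb(L), sb2(L);
  for (int l = 0; l < L; ++l) {
    sW[l] = arma::zeros<mat>(net.W[l].n_rows, net.W[l].n_cols);
    sW2[l] = sW[l];
    sb[l] = arma::zeros<vec>(net.b[l].n_elem);
    sb2[l] = sb[l];
  }
  vec predSum;
  if (ntest > 0) predSum = arma::zeros<vec>(ntest);
  int retained = 0;
  List snapshots(keep_snapshots ? T : 0);

  bool use_dropout = (p1 < 1.0) || (p2 < 1.0);
  std::vector<vec> masks(L);  // empty = no mask
  bool diverged = false;
  int completed = 0;

  for (int t = 0; t < T; ++t) {
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
    if (use_dropout) {
      if (p1 < 1.0) {
        if (joint_triples) {
          vec ztrip = sample_bernoulli(d0 / 3, p1);
          vec z(d0);
          for (int j = 0; j < d0 / 3; ++j)
            for (int r = 0; r < 3; ++r) z[3 * j + r] = ztrip[j];
          masks[0] = z;
        } else {
          masks[0] = sample_bernoulli(d0, p1);
        }
      }
      for (int l = 1; l < L; ++l)
        if (p2 < 1.0) masks[l] = sample_bernoulli(net.W[l].n_rows, p2);
    }

    // one optimization pass
    int nsteps = (steps_per_iter > 0)
                     ? steps_per_iter
                     : (optimizer == 0 ? 1 : (n + batch - 1) / batch);
    arma::uvec idx;
    if (optimizer != 0) idx = shuffled_indices(n);
    int pos = 0;
    for (int s = 0; s < nsteps; ++s) {
      mat Xbt;
      arma::umat Cb;
      vec yb;
      int bsize;
      if (optimizer == 0) {
        if (fast) Cb = codes_train; else Xbt = Xt;
        yb = y;
        bsize = n;
      } else {
        if (pos >= n) {
          idx = shuffled_indices(n);
          pos = 0;
        }
        int hi = std::min(pos + batch, n);
        arma::uvec rows = idx.subvec(pos, hi - 1);
        if (fast) Cb = codes_train.cols(rows); else Xbt = Xt.cols(rows);
        yb = y.elem(rows);
        pos = hi;
        bsize = (int)rows.n_elem;
      }
      std::vector<mat> gW;
      std::vector<vec> gb;
      if (fast) {
        backprop_codes(net, masks, p1, p2, Cb, yb, gW, gb, coupled, lam1,
                       lam2, lam3);
      } else {
        backprop_net(net, masks, p1, p2, Xbt, yb, gW, gb, coupled, lam1,
                     lam2, lam3);
      }
      if (optimizer == 2) {
        adam_step(net, st, gW, gb, eta, beta1, beta2, eps, lam1, lam2, lam3,
                  (double)bsize);
      } else {
        for (int l = 0; l < L; ++l) {
          net.W[l] -= eta * gW[l];
          net.b[l] -= eta * gb[l];
        }
      }
    }

    // thinned model omega^t and its test performance
    bool finite = true;
    for (int l = 0; l < L; ++l)
      if (!net.W[l].is_finite() || !net.b[l].is_finite()) finite = false;
    if (!finite) {
      diverged = true;
      break;
    }
    std::vector<mat> omegaW(L);
    for (int l = 0; l < L; ++l) {
      double retain = (l == 0) ? p1 : p2;
      omegaW[l] = effective_W(net.W[l], masks[l], retain);
    }
    if (ntest > 0) {
      Net thin;
      thin.act = act;
      thin.W = omegaW;
      thin.b = net.b;
      std::vector<vec> nomask(L);
      vec yhat = fast ? predict_codes(thin, codes_test)
                      : predict_net(thin, nomask, 1.0, 1.0, Xtest_t);
      if (!yhat.is_finite()) {
        diverged = true;
        break;
      }
      preds.row(t) = yhat.t();
      mse[t] = arma::mean(arma::square(yhat - ytest));
      mae[t] = arma::mean(arma::abs(yhat - ytest));
    }
    if (t >= burnin) {
      retained += 1;
      for (int l = 0; l < L; ++l) {
        sW[l] += omegaW[l];
        sW2[l] += arma::square(omegaW[l]);
        sb[l] += net.b[l];
        sb2[l] += arma::square(net.b[l]);
      }
      if (ntest > 0) predSum += preds.row(t).t();
    }
    if (keep_snapshots) {
      List sw(L), sbL(L);
      for (int l = 0; l < L; ++l) {
        sw[l] = omegaW[l];
        sbL[l] = net.b[l];
      }
      snapshots[t] = List::create(_["W"] = sw, _["b"] = sbL);
    }
    completed = t + 1;
  }

  List meanW(L), varW(L), meanB(L), varB(L), finW(L), finB(L);
  for (int l = 0; l < L; ++l) {
    if (retained > 0) {
      mat mW = sW[l] / retained;
      mat vW = sW2[l] / retained - arma::square(mW);
      vW.clamp(0.0, arma::datum::inf);
      vec mB = sb[l] / retained;
      vec vB = sb2[l] / retained - arma::square(mB);
      vB.clamp(0.0, arma::datum::inf);
      meanW[l] = mW;
      varW[l] = vW;
      meanB[l] = mB;
      varB[l] = vB;
    } else {
      meanW[l] = R_NilValue;
      varW[l] = R_NilValue;
      meanB[l] = R_NilValue;
      varB[l] = R_NilValue;
    }
    finW[l] = net.W[l];
    finB[l] = net.b[l];
  }
  vec predMean;
  if (ntest > 0 && retained > 0) predMean = predSum / retained;
  List mWl(L), vWl(L), mbl(L), vbl(L);
  for (int l = 0; l < L; ++l) {
    mWl[l] = st.mW[l];
    vWl[l] = st.vW[l];
    mbl[l] = st.mb[l];
    vbl[l] = st.vb[l];
  }
  List adamOut = List::create(_["mW"] = mWl, _["vW"] = vWl, _["mb"] = mbl,
                              _["vb"] = vbl, _["t"] = (int)st.t);

  return List::create(
      _["mse"] = mse, _["mae"] = mae, _["predictions"] = preds,
      _["predMean"] = predMean, _["meanW"] = meanW, _["varW"] = varW,
      _["meanB"] = meanB, _["varB"] = varB, _["finalW"] = finW,
      _["finalB"] = finB, _["retained"] = retained, _["completed"] = completed,
      _["diverged"] = diverged, _["snapshots"] = snapshots,
      _["adam"] = adamOut);
}
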