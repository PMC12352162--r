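// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Small 1-D CNN for binary classification of multichannel time-series
// tensors: three Conv1D blocks (kernel 3, "same" padding, ReLU, then batch
// normalization), global average pooling over time, and a single sigmoid
// output unit, trained with Adam on binary cross-entropy.  Layout:
//   X      : cube, channels x time x trials (float32)
//   W[l]   : n_filters x (3 * n_in) with row-block ordering
//            [offset 0 | offset 1 | offset 2], each block n_in wide
// All arithmetic is single precision; a fixed permutation table drives the
// mini-batch order so training is bit-reproducible for a given seed.

struct BNState {
  fvec gamma, beta, run_mean, run_var;
};

// im2col for kernel 3 / same padding: output (3*Cin) x (T*B), column b*T+t.
static fmat im2col3(const fcube& A) {
  const uword C = A.n_rows, T = A.n_cols, B = A.n_slices;
  fmat M(3 * C, T * B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    const fmat& S = A.slice(b);
    for (uword k = 0; k < 3; ++k) {
      // offset k - 1: output column t reads input column t + k - 1
      const sword off = (sword)k - 1;
      uword t0 = (off < 0) ? 1 : 0;
      uword t1 = (off > 0) ? T - 1 : T;
      if (t1 <= t0) continue;
      M.submat(k * C, b * T + t0, k * C + C - 1, b * T + t1 - 1) =
          S.cols(t0 + off, t1 - 1 + off);
    }
  }
  return M;
}

// scatter-add inverse of im2col3
static fcube col2im3(const fmat& dM, uword C, uword T, uword B) {
  fcube dA(C, T, B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    fmat& S = dA.slice(b);
    for (uword k = 0; k < 3; ++k) {
      const sword off = (sword)k - 1;
      uword t0 = (off < 0) ? 1 : 0;
      uword t1 = (off > 0) ? T - 1 : T;
      if (t1 <= t0) continue;
      S.cols(t0 + off, t1 - 1 + off) +=
          dM.submat(k * C, b * T + t0, k * C + C - 1, b * T + t1 - 1);
    }
  }
  return dA;
}

struct LayerCache {
  fmat M;     // im2col input
  fmat Z;     // pre-activation
  fmat xhat;  // normalized activations
  fvec mu, invstd;
};

static const float BN_EPS = 1e-3f;
static const float BN_MOMENTUM = 0.99f;

// forward one conv block; train=true uses batch statistics and fills cache
static fmat conv_block_fwd(const fcube& A, const fmat& W, const fvec& b,
                           BNState& bn, bool train, LayerCache* cache,
                           float momentum = BN_MOMENTUM) {
  const uword T = A.n_cols, B = A.n_slices;
  fmat M = im2col3(A);
  fmat Z = W * M;
  Z.each_col() += b;
  fmat R = clamp(Z, 0.0f, std::numeric_limits<float>::max());
  if (train) {
    fvec mu = mean(R, 1);
    R.each_col() -= mu;
    fvec var = mean(square(R), 1);  // biased, as in keras
    fvec invstd = 1.0f / sqrt(var + BN_EPS);
    R.each_col() %= invstd;  // R is now xhat
    fmat out = R;
    out.each_col() %= bn.gamma;
    out.each_col() += bn.beta;
    bn.run_mean = momentum * bn.run_mean + (1.0f - momentum) * mu;
    bn.run_var = momentum * bn.run_var + (1.0f - momentum) * var;
    if (cache) {
      cache->M = std::move(M);
      cache->Z = std::move(Z);
      cache->xhat = std::move(R);
      cache->mu = std::move(mu);
      cache->invstd = std::move(invstd);
    }
    return out;
  }
  fvec invstd = 1.0f / sqrt(bn.run_var + BN_EPS);
  R.each_col() -= bn.run_mean;
  R.each_col() %= invstd;
  R.each_col() %= bn.gamma;
  R.each_col() += bn.beta;
  return R;
}

// reshape (C x T*B) back into a cube view
static fcube mat_to_cube(const fmat& M, uword T, uword B) {
  fcube A(M.n_rows, T, B);
  for (uword b = 0; b < B; ++b)
    A.slice(b) = M.cols(b * T, b * T + T - 1);
  return A;
}

struct AdamState {
  std::vector<fmat> m, v;
  long step = 0;
};

static void adam_update(fmat& P, const fmat& G, fmat& m, fmat& v, long t,
                        float lr, float b1, float b2, float eps) {
  m = b1 * m + (1.0f - b1) * G;
  v = b2 * v + (1.0f - b2) * square(G);
  float c1 = 1.0f - std::pow(b1, (float)t);
  float c2 = 1.0f - std::pow(b2, (float)t);
  P -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

struct Net {
  std::vector<fmat> W;  // conv weights, 3 layers
  std::vector<fvec> b;
  std::vector<BNState> bn;
  frowvec Wd;  // dense 1 x 64
  float bd;
};

static Net net_from_list(const Rcpp::List& w) {
  Net net;
  for (int l = 0; l < 3; ++l) {
    std::string i = std::to_string(l + 1);
    net.W.push_back(Rcpp::as<fmat>(w["W" + i]));
    net.b.push_back(Rcpp::as<fvec>(w["b" + i]));
    BNState s;
    s.gamma = Rcpp::as<fvec>(w["gamma" + i]);
    s.beta = Rcpp::as<fvec>(w["beta" + i]);
    s.run_mean = Rcpp::as<fvec>(w["run_mean" + i]);
    s.run_var = Rcpp::as<fvec>(w["run_var" + i]);
    net.bn.push_back(s);
  }
  net.Wd = Rcpp::as<frowvec>(w["Wd"]);
  net.bd = Rcpp::as<float>(w["bd"]);
  return net;
}

static Rcpp::List net_to_list(const Net& net) {
  Rcpp::List out;
  for (int l = 0; l < 3; ++l) {
    std::string i = std::to_string(l + 1);
    out["W" + i] = net.W[l];
    out["b" + i] = net.b[l];
    out["gamma" + i] = net.bn[l].gamma;
    out["beta" + i] = net.bn[l].beta;
    out["run_mean" + i] = net.bn[l].run_mean;
    out["run_var" + i] = net.bn[l].run_var;
  }
  out["Wd"] = net.Wd;
  out["bd"] = net.bd;
  return out;
}

static fvec forward_infer(const Net& net, const fcube& X) {
  const uword T = X.n_cols, B = X.n_slices;
  fcube A = X;
  for (int l = 0; l < 3; ++l) {
    fmat out = conv_block_fwd(A, net.W[l], net.b[l],
                              const_cast<BNState&>(net.bn[l]), false, nullptr);
    A = mat_to_cube(out, T, B);
  }
  // global average pooling over time -> C x B
  fmat G(A.n_rows, B);
  for (uword s = 0; s < B; ++s) G.col(s) = mean(A.slice(s), 1);
  fvec logits = (net.Wd * G).t() + net.bd;
  return 1.0f / (1.0f + exp(-logits));
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(const arma::fcube& X, const Rcpp::List& weights) {
  Net net = net_from_list(weights);
  return conv_to<vec>::from(forward_infer(net, X));
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::fcube& X, const arma::vec& y,
                         const Rcpp::List& weights,
                         const Rcpp::IntegerMatrix& perm, int batch_size,
                         double lr, double beta1, double beta2,
                         double eps_adam) {
  Net net = net_from_list(weights);
  const uword T = X.n_cols, N = X.n_slices;
  const int epochs = perm.nrow();
  const float flr = (float)lr, fb1 = (float)beta1, fb2 = (float)beta2,
              feps = (float)eps_adam;

  // Adam slots: W1,b1,g1,be1, W2,b2,g2,be2, W3,b3,g3,be3, Wd, bd
  AdamState ad;
  auto add_slot = [&](uword r, uword c) {
    ad.m.emplace_back(r, c, fill::zeros);
    ad.v.emplace_back(r, c, fill::zeros);
  };
  for (int l = 0; l < 3; ++l) {
    add_slot(net.W[l].n_rows, net.W[l].n_cols);
    add_slot(net.b[l].n_elem, 1);
    add_slot(net.bn[l].gamma.n_elem, 1);
    add_slot(net.bn[l].beta.n_elem, 1);
  }
  add_slot(1, net.Wd.n_elem);
  add_slot(1, 1);

  for (int ep = 0; ep < epochs; ++ep) {
    for (uword start = 0; start < N; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, N) - 1;
      uword B = stop - start + 1;
      fcube Xb(X.n_rows, T, B);
      fvec yb(B);
      for (uword j = 0; j < B; ++j) {
        int idx = perm(ep, start + j) - 1;  // 1-based from R
        Xb.slice(j) = X.slice(idx);
        yb(j) = (float)y(idx);
      }
      // ---- forward ----
      std::vector<LayerCache> cache(3);
      std::vector<uword> cin(3);
      fcube A = Xb;
      for (int l = 0; l < 3; ++l) {
        cin[l] = A.n_rows;
        fmat out =
            conv_block_fwd(A, net.W[l], net.b[l], net.bn[l], true, &cache[l]);
        A = mat_to_cube(out, T, B);
      }
      fmat G(A.n_rows, B);
      for (uword s = 0; s < B; ++s) G.col(s) = mean(A.slice(s), 1);
      fvec logits = (net.Wd * G).t() + net.bd;
      fvec p = 1.0f / (1.0f + exp(-logits));

      // ---- backward ----
      fvec dlogit = (p - yb) / (float)B;  // BCE + sigmoid
      fmat dWd = (G * dlogit).t();        // 1 x C
      float dbd = accu(dlogit);
      fmat dG = net.Wd.t() * dlogit.t();  // C x B

      // through GAP: each time step gets dG / T
      fmat dtop(A.n_rows, T * B);
      for (uword s = 0; s < B; ++s)
        dtop.cols(s * T, s * T + T - 1).each_col() = dG.col(s) / (float)T;

      std::vector<fmat> gW(3), gb(3), gg(3), gbe(3);
      fmat dcur = std::move(dtop);
      for (int l = 2; l >= 0; --l) {
        LayerCache& C = cache[l];
        const float Nn = (float)(T * B);
        // batch-norm backward; note mean(dy*gamma) = gamma * mean(dy),
        // so the gamma-scaled intermediate matrix is never materialized:
        // dZ = gamma*invstd*(dy - dbeta/N - xhat*dgamma/N), masked by ReLU
        fvec dgamma = sum(dcur % C.xhat, 1);
        fvec dbeta = sum(dcur, 1);
        const uword nr = dcur.n_rows, ncol = dcur.n_cols;
        for (uword j = 0; j < ncol; ++j) {
          float* d = dcur.colptr(j);
          const float* xh = C.xhat.colptr(j);
          const float* zz = C.Z.colptr(j);
          for (uword c = 0; c < nr; ++c) {
            if (zz[c] <= 0.0f) { d[c] = 0.0f; continue; }
            float g = net.bn[l].gamma(c) * C.invstd(c);
            d[c] = g * (d[c] - dbeta(c) / Nn - xh[c] * dgamma(c) / Nn);
          }
        }
        // dcur is now dZ
        gW[l] = dcur * C.M.t();
        gb[l] = sum(dcur, 1);
        gg[l] = dgamma;
        gbe[l] = dbeta;
        if (l > 0) {
          fmat dM = net.W[l].t() * dcur;
          fcube dA = col2im3(dM, cin[l], T, B);
          // flatten back to matrix layout C x (T*B)
          fmat flat(cin[l], T * B);
          for (uword s = 0; s < B; ++s)
            flat.cols(s * T, s * T + T - 1) = dA.slice(s);
          dcur = std::move(flat);
        }
      }

      // ---- Adam ----
      ad.step++;
      int s = 0;
      for (int l = 0; l < 3; ++l) {
        adam_update(net.W[l], gW[l], ad.m[s], ad.v[s], ad.step, flr, fb1, fb2,
                    feps);
        s++;
        fmat gbm = gb[l];
        fmat bm = net.b[l];
        adam_update(bm, gbm, ad.m[s], ad.v[s], ad.step, flr, fb1, fb2, feps);
        net.b[l] = bm.col(0);
        s++;
        fmat ggm = gg[l], gmat = net.bn[l].gamma;
        adam_update(gmat, ggm, ad.m[s], ad.v[s], ad.step, flr, fb1, fb2, feps);
        net.bn[l].gamma = gmat.col(0);
        s++;
        fmat gbem = gbe[l], bem = net.bn[l].beta;
        adam_update(bem, gbem, ad.m[s], ad.v[s], ad.step, flr, fb1, fb2, feps);
        net.bn[l].beta = bem.col(0);
        s++;
      }
      fmat Wdm = net.Wd;
      adam_update(Wdm, dWd, ad.m[s], ad.v[s], ad.step, flr, fb1, fb2, feps);
      net.Wd = Wdm.row(0);
      s++;
      fmat bdm(1, 1);
      bdm(0, 0) = net.bd;
      fmat gbd(1, 1);
      gbd(0, 0) = dbd;
      adam_update(bdm, gbd, ad.m[s], ad.v[s], ad.step, flr, fb1, fb2, feps);
      net.bd = bdm(0, 0);
    }
  }
  // Recalibrate batch-norm inference statistics with one pass over the
  // full training set (momentum 0): with few gradient steps the momentum-
  // averaged running statistics are still close to their initialization,
  // which would distort inference-mode normalization.
  {
    fcube A = X;
    for (int l = 0; l < 3; ++l) {
      fmat out = conv_block_fwd(A, net.W[l], net.b[l], net.bn[l], true,
                                nullptr, 0.0f);
      A = mat_to_cube(out, T, N);
    }
  }
  return net_to_list(net);
}
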