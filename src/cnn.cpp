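// Core numerics for the 1-D convolutional genome-wide prediction network:
// strided cross-correlation with equal zero padding, max pooling with argmax
// bookkeeping, the dense linear output, and the exact backward pass of
// mse + lambda * ||W||_1 with respect to every trainable parameter.
//
// Layout conventions (shared with the R level):
//  * X is n x p, one row per individual, one column per SNP.
//  * K is kernel_width x q (single input channel), bias_c is length q.
//  * conv output C is stored as an (n*out_len) x q matrix whose row index is
//    i + t*n for individual i (0-based) at output position t.
//  * flattened features F are n x (Lp*q) with column t*q + l (position-major,
//    filter fastest) matching the weight-index mapping used for QTL
//    localization (flat index ~ SNP index * factor).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvGeom {
  int out_len;
  int pad_left;
  int pad_total;
};

ConvGeom conv_geometry(int L, int stride, int kw) {
  ConvGeom g;
  g.out_len = (L + stride - 1) / stride;  // ceil(L / stride)
  int tot = (g.out_len - 1) * stride + kw - L;
  g.pad_total = tot > 0 ? tot : 0;
  g.pad_left = g.pad_total / 2;  // extra zero (odd totals) goes on the right
  return g;
}

// Patch matrix P: (n*out_len) x kw with P(i + t*n, k) = Xpad(i, t*stride + k)
mat build_patches(const mat& X, int stride, int kw, const ConvGeom& g) {
  const int n = X.n_rows, L = X.n_cols;
  mat P(static_cast<uword>(n) * g.out_len, kw, fill::zeros);
  for (int t = 0; t < g.out_len; ++t) {
    for (int k = 0; k < kw; ++k) {
      int src = t * stride + k - g.pad_left;  // column in the unpadded X
      if (src >= 0 && src < L) {
        P.col(k).subvec(static_cast<uword>(t) * n,
                        static_cast<uword>(t) * n + n - 1) = X.col(src);
      }
    }
  }
  return P;
}

// Max pooling of C ((n*out_len) x q) into flattened features F (n x Lp*q),
// recording for each pooled cell the row of C that achieved the maximum.
// Ties broken by the first (lowest) position.
void pool_flatten(const mat& C, int n, int out_len, int pool,
                  mat& F, umat& amx) {
  const int q = C.n_cols;
  const int Lp = out_len / pool;
  F.set_size(n, static_cast<uword>(Lp) * q);
  amx.set_size(n, static_cast<uword>(Lp) * q);
  for (int l = 0; l < q; ++l) {
    const double* cl = C.colptr(l);
    for (int w = 0; w < Lp; ++w) {
      const uword col = static_cast<uword>(w) * q + l;
      double* fcol = F.colptr(col);
      uword* acol = amx.colptr(col);
      const int t0 = w * pool;
      for (int i = 0; i < n; ++i) {
        double best = cl[static_cast<uword>(t0) * n + i];
        uword arg = static_cast<uword>(t0) * n + i;
        for (int j = 1; j < pool; ++j) {
          const uword r = static_cast<uword>(t0 + j) * n + i;
          if (cl[r] > best) { best = cl[r]; arg = r; }
        }
        fcol[i] = best;
        acol[i] = arg;
      }
    }
  }
}

}  // namespace

// Strided 1-D cross-correlation with equal zero padding.
// Returns a cube n x out_len x q.
// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::mat& X, const arma::mat& K,
                          const arma::vec& bias_c, int stride) {
  const int n = X.n_rows, L = X.n_cols, kw = K.n_rows, q = K.n_cols;
  ConvGeom g = conv_geometry(L, stride, kw);
  mat P = build_patches(X, stride, kw, g);
  mat C = P * K;
  C.each_row() += bias_c.t();
  cube out(n, g.out_len, q);
  for (int l = 0; l < q; ++l) {
    out.slice(l) = reshape(C.col(l), n, g.out_len);
  }
  return out;
}

// Max pooling over non-overlapping windows along the position axis of an
// n x L x q cube; the trailing remainder (L mod pool) is dropped.
// [[Rcpp::export]]
Rcpp::List maxpool_fwd_cpp(const arma::cube& G, int pool) {
  const int n = G.n_rows, L = G.n_cols, q = G.n_slices;
  const int Lp = L / pool;
  cube out(n, Lp, q);
  arma::ucube arg(n, Lp, q);  // 1-based position along L
  for (int l = 0; l < q; ++l) {
    for (int w = 0; w < Lp; ++w) {
      for (int i = 0; i < n; ++i) {
        double best = G(i, w * pool, l);
        int bt = w * pool;
        for (int j = 1; j < pool; ++j) {
          if (G(i, w * pool + j, l) > best) {
            best = G(i, w * pool + j, l);
            bt = w * pool + j;
          }
        }
        out(i, w, l) = best;
        arg(i, w, l) = bt + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("pooled") = out,
                            Rcpp::Named("argmax") = arg);
}

// Full forward pass to predictions: conv -> max pool -> flatten -> dense.
// [[Rcpp::export]]
arma::vec cnn_predict_cpp(const arma::mat& X, const arma::mat& K,
                          const arma::vec& bias_c, const arma::vec& W,
                          double b, int stride, int pool) {
  const int n = X.n_rows, L = X.n_cols, kw = K.n_rows;
  ConvGeom g = conv_geometry(L, stride, kw);
  mat P = build_patches(X, stride, kw, g);
  mat C = P * K;
  C.each_row() += bias_c.t();
  mat F;
  umat amx;
  pool_flatten(C, n, g.out_len, pool, F, amx);
  return F * W + b;
}

// Fused mini-batch ADAM training loop. Per epoch: visit the training rows
// in the order given by the corresponding column-set of `perms` (epochs
// rows, n_train columns, 1-based; computed in R under the seeded-shuffle
// contract), take one ADAM step per batch on the gradient of
// mse + lambda*||W||_1, then score the validation rows (plain MSE, no
// penalty) and checkpoint the parameters whenever the validation MSE
// improves. The validation patch matrix is built once and reused.
// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::mat& Xtr, const arma::vec& ytr,
                         const arma::mat& Xval, const arma::vec& yval,
                         arma::mat K, arma::vec bias_c, arma::vec W, double b,
                         int stride, int pool, double lambda,
                         double lr, double beta1, double beta2, double eps,
                         const arma::imat& perms, int batch_size) {
  const int n_train = Xtr.n_rows, L = Xtr.n_cols;
  const int kw = K.n_rows, q = K.n_cols;
  const int n_val = Xval.n_rows;
  const int epochs = perms.n_rows;
  ConvGeom g = conv_geometry(L, stride, kw);
  const int out_len = g.out_len;
  const int Lp = out_len / pool;
  const int n_batches = (n_train + batch_size - 1) / batch_size;

  mat Pval = build_patches(Xval, stride, kw, g);

  // ADAM moment accumulators.
  mat mK(kw, q, fill::zeros), vK(kw, q, fill::zeros);
  vec mbc(q, fill::zeros), vbc(q, fill::zeros);
  vec mW(W.n_elem, fill::zeros), vW(W.n_elem, fill::zeros);
  double mb = 0, vb = 0;
  long tstep = 0;

  mat K_best = K;
  vec bc_best = bias_c, W_best = W;
  double b_best = b;
  int best_epoch = -1;
  double best_val = datum::inf;
  mat trace(epochs, 2);

  auto adam_upd = [&](double& theta, double& m, double& v, double grad,
                      double c1, double c2) {
    m = beta1 * m + (1 - beta1) * grad;
    v = beta2 * v + (1 - beta2) * grad * grad;
    theta -= lr * (m / c1) / (std::sqrt(v / c2) + eps);
  };

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0;
    for (int bi = 0; bi < n_batches; ++bi) {
      const int start = bi * batch_size;
      const int nb = std::min(batch_size, n_train - start);
      // Patch matrix for this batch, gathered straight from Xtr rows.
      mat P(static_cast<uword>(nb) * out_len, kw, fill::zeros);
      for (int t = 0; t < out_len; ++t) {
        for (int k = 0; k < kw; ++k) {
          const int src = t * stride + k - g.pad_left;
          if (src < 0 || src >= L) continue;
          const double* xcol = Xtr.colptr(src);
          double* pdst = P.colptr(k) + static_cast<uword>(t) * nb;
          for (int i = 0; i < nb; ++i) {
            pdst[i] = xcol[perms(ep, start + i) - 1];
          }
        }
      }
      mat C = P * K;
      C.each_row() += bias_c.t();
      mat F;
      umat amx;
      pool_flatten(C, nb, out_len, pool, F, amx);
      vec pred = F * W + b;
      vec yb(nb);
      for (int i = 0; i < nb; ++i) yb[i] = ytr[perms(ep, start + i) - 1];
      vec resid = pred - yb;
      ep_loss += dot(resid, resid) + (lambda * norm(W, 1)) * nb;

      vec dpred = (2.0 / nb) * resid;
      vec dW = F.t() * dpred + lambda * sign(W);
      double db = accu(dpred);
      mat dC(C.n_rows, q, fill::zeros);
      for (int l = 0; l < q; ++l) {
        double* dcl = dC.colptr(l);
        for (int w = 0; w < Lp; ++w) {
          const uword col = static_cast<uword>(w) * q + l;
          const uword* acol = amx.colptr(col);
          const double wcol = W[col];
          for (int i = 0; i < nb; ++i) dcl[acol[i]] += dpred[i] * wcol;
        }
      }
      mat dK = P.t() * dC;
      vec dbias = sum(dC, 0).t();

      if (!dK.is_finite() || !dW.is_finite() || !dbias.is_finite() ||
          !std::isfinite(db)) {
        Rcpp::stop("non-finite gradient at epoch %d, batch %d",
                   ep + 1, bi + 1);
      }
      ++tstep;
      const double c1 = 1 - std::pow(beta1, (double)tstep);
      const double c2 = 1 - std::pow(beta2, (double)tstep);
      for (uword i = 0; i < K.n_elem; ++i) adam_upd(K[i], mK[i], vK[i], dK[i], c1, c2);
      for (uword i = 0; i < bias_c.n_elem; ++i) adam_upd(bias_c[i], mbc[i], vbc[i], dbias[i], c1, c2);
      for (uword i = 0; i < W.n_elem; ++i) adam_upd(W[i], mW[i], vW[i], dW[i], c1, c2);
      adam_upd(b, mb, vb, db, c1, c2);
    }
    // Validation pass with the freshly updated parameters.
    mat Cv = Pval * K;
    Cv.each_row() += bias_c.t();
    mat Fv;
    umat amxv;
    pool_flatten(Cv, n_val, out_len, pool, Fv, amxv);
    vec pv = Fv * W + b;
    double val_mse = accu(square(pv - yval)) / n_val;
    trace(ep, 0) = ep_loss / n_train;
    trace(ep, 1) = val_mse;
    if (val_mse < best_val) {
      best_val = val_mse;
      best_epoch = ep + 1;
      K_best = K;
      bc_best = bias_c;
      W_best = W;
      b_best = b;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("K") = K, Rcpp::Named("bias_c") = bias_c,
      Rcpp::Named("W") = W, Rcpp::Named("b") = b,
      Rcpp::Named("K_best") = K_best, Rcpp::Named("bias_c_best") = bc_best,
      Rcpp::Named("W_best") = W_best, Rcpp::Named("b_best") = b_best,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val") = best_val, Rcpp::Named("trace") = trace);
}

// Forward + backward for one mini-batch. Returns the loss decomposition,
// predictions, and exact (sub)gradients of mse + lambda*||W||_1 for K,
// bias_c, W and b. The L1 subgradient uses sign(0) = 0.
// [[Rcpp::export]]
Rcpp::List cnn_batch_grad_cpp(const arma::mat& X, const arma::vec& y,
                              const arma::mat& K, const arma::vec& bias_c,
                              const arma::vec& W, double b,
                              int stride, int pool, double lambda) {
  const int n = X.n_rows, L = X.n_cols, kw = K.n_rows, q = K.n_cols;
  ConvGeom g = conv_geometry(L, stride, kw);
  mat P = build_patches(X, stride, kw, g);
  mat C = P * K;
  C.each_row() += bias_c.t();
  mat F;
  umat amx;
  pool_flatten(C, n, g.out_len, pool, F, amx);
  vec pred = F * W + b;

  vec resid = pred - y;
  double mse = dot(resid, resid) / n;
  double pen = lambda * norm(W, 1);

  vec dpred = (2.0 / n) * resid;
  vec dW = F.t() * dpred + lambda * sign(W);
  double db = accu(dpred);

  // Route gradient through the pooling argmax back onto the conv output.
  mat dC(C.n_rows, q, fill::zeros);
  const int Lp = g.out_len / pool;
  mat dF = dpred * W.t();  // n x (Lp*q)
  for (int l = 0; l < q; ++l) {
    double* dcl = dC.colptr(l);
    for (int w = 0; w < Lp; ++w) {
      const uword col = static_cast<uword>(w) * q + l;
      const double* dfc = dF.colptr(col);
      const uword* acol = amx.colptr(col);
      for (int i = 0; i < n; ++i) dcl[acol[i]] += dfc[i];
    }
  }
  mat dK = P.t() * dC;
  vec dbias = sum(dC, 0).t();

  return Rcpp::List::create(
      Rcpp::Named("mse") = mse, Rcpp::Named("penalty") = pen,
      Rcpp::Named("total") = mse + pen, Rcpp::Named("pred") = pred,
      Rcpp::Named("dK") = dK, Rcpp::Named("dbias") = dbias,
      Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
}

// Cyclic coordinate descent for (1/2n)||y - X b||^2 + lambda ||b||_1 with
// residual updates; the convergence criterion is the largest absolute
// coordinate change in a full sweep.
// [[Rcpp::export]]
Rcpp::List cd_lasso_cpp(const arma::mat& X, const arma::vec& y, double lambda,
                        arma::vec beta, int max_sweeps, double tol) {
  const int n = X.n_rows, p = X.n_cols;
  vec v(p);
  for (int j = 0; j < p; ++j) v[j] = dot(X.col(j), X.col(j)) / n;
  vec r = y - X * beta;
  double max_change = 0;
  for (int sweep = 1; sweep <= max_sweeps; ++sweep) {
    max_change = 0;
    for (int j = 0; j < p; ++j) {
      if (v[j] < 1e-12) continue;
      const double bj = beta[j];
      const double z = dot(X.col(j), r) / n + v[j] * bj;
      double bnew = std::fabs(z) > lambda ?
          (z > 0 ? (z - lambda) : (z + lambda)) / v[j] : 0.0;
      if (bnew != bj) {
        r += X.col(j) * (bj - bnew);
        beta[j] = bnew;
        max_change = std::max(max_change, std::fabs(bnew - bj));
      }
    }
    if (max_change < tol) {
      return Rcpp::List::create(Rcpp::Named("beta") = beta,
                                Rcpp::Named("sweeps") = sweep,
                                Rcpp::Named("converged") = true,
                                Rcpp::Named("max_change") = max_change);
    }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("sweeps") = max_sweeps,
                            Rcpp::Named("converged") = false,
                            Rcpp::Named("max_change") = max_change);
}
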