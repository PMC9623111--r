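// 1D-CNN core: valid-padding cross-correlation, pooling, global average
// pooling, dense head, and a mini-batch RMSProp / MAE training loop.
// Everything here is deterministic given the parameter values passed in;
// all random initialization happens on the R side with R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for 1-D valid cross-correlation: A is (in_ch x W), result is
// (in_ch*k x L) with L = W - k + 1; row (i*k + t) holds A(i, p + t).
static mat im2col1d(const mat& A, const int k) {
  const int inc = A.n_rows;
  const int W = A.n_cols;
  const int L = W - k + 1;
  mat C(inc * k, L);
  for (int i = 0; i < inc; ++i)
    for (int t = 0; t < k; ++t)
      C.row(i * k + t) = A.row(i).cols(t, t + L - 1);
  return C;
}

// adjoint of im2col1d: scatter-add dC back onto the input layout
static mat col2im1d(const mat& dC, const int k, const int inc, const int W) {
  const int L = W - k + 1;
  mat dA(inc, W, fill::zeros);
  for (int i = 0; i < inc; ++i)
    for (int t = 0; t < k; ++t)
      dA.row(i).cols(t, t + L - 1) += dC.row(i * k + t);
  return dA;
}

// [[Rcpp::export]]
arma::mat cpp_conv1d(const arma::mat& x, const arma::mat& w,
                     const arma::vec& b, const int k) {
  if ((int)x.n_cols < k)
    Rcpp::stop("input width %d is shorter than the kernel length %d",
               (int)x.n_cols, k);
  if ((int)w.n_cols != (int)x.n_rows * k)
    Rcpp::stop("weight matrix has %d columns but %d (in_channels * kernel) expected",
               (int)w.n_cols, (int)x.n_rows * k);
  mat out = w * im2col1d(x, k);
  out.each_col() += b;
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_pool1d(const arma::mat& x, const int size, const int stride,
                     const bool maxpool) {
  const int W = x.n_cols;
  if (W < size)
    Rcpp::stop("input width %d is shorter than the pool size %d", W, size);
  const int L = (W - size) / stride + 1;
  mat out(x.n_rows, L);
  for (int p = 0; p < L; ++p) {
    const mat win = x.cols(p * stride, p * stride + size - 1);
    if (maxpool)
      out.col(p) = arma::max(win, 1);
    else
      out.col(p) = arma::mean(win, 1);
  }
  return out;
}

struct NetParams {
  std::vector<mat> cw;  // per conv layer: (n_filters x in_ch*k)
  std::vector<vec> cb;  // per conv layer bias
  vec dw;               // dense weights (n_filters)
  double db;            // dense bias
};

static NetParams unpack_params(const Rcpp::List& params) {
  NetParams np;
  Rcpp::List cw = params["conv_w"], cb = params["conv_b"];
  for (int l = 0; l < cw.size(); ++l) {
    np.cw.push_back(Rcpp::as<mat>(cw[l]));
    np.cb.push_back(Rcpp::as<vec>(cb[l]));
  }
  np.dw = Rcpp::as<vec>(params["dense_w"]);
  np.db = Rcpp::as<double>(params["dense_b"]);
  return np;
}

static Rcpp::List pack_params(const NetParams& np) {
  Rcpp::List cw(np.cw.size()), cb(np.cb.size());
  for (size_t l = 0; l < np.cw.size(); ++l) {
    cw[l] = np.cw[l];
    cb[l] = np.cb[l];
  }
  return Rcpp::List::create(Rcpp::Named("conv_w") = cw,
                            Rcpp::Named("conv_b") = cb,
                            Rcpp::Named("dense_w") = np.dw,
                            Rcpp::Named("dense_b") = np.db);
}

// forward for one standardized spectrum (single input channel), optionally
// caching the intermediates needed for backpropagation
struct FwdCache {
  std::vector<mat> C;   // im2col input of each conv layer
  std::vector<mat> Z;   // pre-activation of each conv layer
  mat conv_out;         // post-ReLU output of the last conv layer
  umat amax;            // argmax positions of the max pool
  vec gap;              // global-average-pooled features
  int pooled_len;
};

static double net_forward(const NetParams& np, const rowvec& x, const int k,
                          const int pool_size, const int pool_stride,
                          const bool pool_max, FwdCache* cache) {
  mat A = x;  // 1 x W
  const int nL = (int)np.cw.size();
  for (int l = 0; l < nL; ++l) {
    mat C = im2col1d(A, k);
    mat Z = np.cw[l] * C;
    Z.each_col() += np.cb[l];
    A = Z;
    A.elem(find(Z < 0)).zeros();  // ReLU
    if (cache) {
      cache->C.push_back(std::move(C));
      cache->Z.push_back(std::move(Z));
    }
  }
  const int W5 = A.n_cols;
  const int nf = A.n_rows;
  const int P = (W5 - pool_size) / pool_stride + 1;
  mat pooled(nf, P);
  umat amax(nf, P);
  for (int p = 0; p < P; ++p) {
    const int o = p * pool_stride;
    if (pool_max) {
      for (int ch = 0; ch < nf; ++ch) {
        uword idx;
        pooled(ch, p) = A.row(ch).cols(o, o + pool_size - 1).max(idx);
        amax(ch, p) = o + idx;
      }
    } else {
      pooled.col(p) = arma::mean(A.cols(o, o + pool_size - 1), 1);
    }
  }
  vec gap = arma::mean(pooled, 1);
  if (cache) {
    cache->conv_out = std::move(A);
    cache->amax = std::move(amax);
    cache->gap = gap;
    cache->pooled_len = P;
  }
  return dot(np.dw, gap) + np.db;
}

// [[Rcpp::export]]
arma::vec cpp_cnn_forward(const arma::mat& X, const Rcpp::List& params,
                          const int k, const int pool_size,
                          const int pool_stride, const bool pool_max) {
  const NetParams np = unpack_params(params);
  vec out(X.n_rows);
  for (uword s = 0; s < X.n_rows; ++s)
    out(s) = net_forward(np, X.row(s), k, pool_size, pool_stride, pool_max,
                         nullptr);
  return out;
}

static inline void rmsprop_step(mat& p, const mat& g, mat& acc,
                                const double lr, const double rho,
                                const double eps) {
  acc = rho * acc + (1.0 - rho) * square(g);
  p -= lr * g / sqrt(acc + eps);
}

static inline void rmsprop_step(vec& p, const vec& g, vec& acc,
                                const double lr, const double rho,
                                const double eps) {
  acc = rho * acc + (1.0 - rho) * square(g);
  p -= lr * g / sqrt(acc + eps);
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(const arma::mat& X, const arma::vec& y,
                         const Rcpp::List& params, const int k,
                         const int pool_size, const int pool_stride,
                         const bool pool_max, const double lr,
                         const double rho, const double eps,
                         const double lr_decay, const int epochs,
                         const int batch_size) {
  NetParams np = unpack_params(params);
  const int nL = (int)np.cw.size();
  const int n = X.n_rows;
  const int nf = np.dw.n_elem;

  // RMSProp accumulators, one per parameter block
  std::vector<mat> acw;
  std::vector<vec> acb;
  for (int l = 0; l < nL; ++l) {
    acw.push_back(mat(np.cw[l].n_rows, np.cw[l].n_cols, fill::zeros));
    acb.push_back(vec(np.cb[l].n_elem, fill::zeros));
  }
  vec adw(nf, fill::zeros);
  double adb = 0.0;

  vec history(epochs);
  std::vector<mat> gcw(nL);
  std::vector<vec> gcb(nL);

  for (int e = 0; e < epochs; ++e) {
    const double lre = lr / (1.0 + lr_decay * e);
    double abs_sum = 0.0;
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      const int b1 = std::min(n, b0 + batch_size);
      const int B = b1 - b0;
      for (int l = 0; l < nL; ++l) {
        gcw[l] = mat(np.cw[l].n_rows, np.cw[l].n_cols, fill::zeros);
        gcb[l] = vec(np.cb[l].n_elem, fill::zeros);
      }
      vec gdw(nf, fill::zeros);
      double gdb = 0.0;

      for (int s = b0; s < b1; ++s) {
        FwdCache cc;
        const double pred = net_forward(np, X.row(s), k, pool_size,
                                        pool_stride, pool_max, &cc);
        const double err = pred - y(s);
        abs_sum += std::abs(err);
        // d(MAE)/d(pred), averaged over the batch
        const double dpred =
            (err > 0 ? 1.0 : (err < 0 ? -1.0 : 0.0)) / (double)B;
        gdw += dpred * cc.gap;
        gdb += dpred;

        // back through GAP
        const vec dgap = dpred * np.dw;
        const int P = cc.pooled_len;
        const int W5 = cc.conv_out.n_cols;
        mat dA(nf, W5, fill::zeros);
        if (pool_max) {
          for (int ch = 0; ch < nf; ++ch) {
            const double g = dgap(ch) / (double)P;
            for (int p = 0; p < P; ++p) dA(ch, cc.amax(ch, p)) += g;
          }
        } else {
          for (int ch = 0; ch < nf; ++ch) {
            const double g = dgap(ch) / (double)P / (double)pool_size;
            for (int p = 0; p < P; ++p) {
              const int o = p * pool_stride;
              dA.row(ch).cols(o, o + pool_size - 1) += g;
            }
          }
        }
        // back through the conv stack
        for (int l = nL - 1; l >= 0; --l) {
          mat dZ = dA;
          dZ.elem(find(cc.Z[l] <= 0)).zeros();
          gcw[l] += dZ * cc.C[l].t();
          gcb[l] += sum(dZ, 1);
          if (l > 0) {
            const mat dC = np.cw[l].t() * dZ;
            const int in_ch = np.cw[l - 1].n_rows;
            const int Win = cc.Z[l].n_cols + k - 1;
            dA = col2im1d(dC, k, in_ch, Win);
          }
        }
      }
      if (!std::isfinite(abs_sum))
        Rcpp::stop("training aborted: non-finite loss at epoch %d", e + 1);
      for (int l = 0; l < nL; ++l) {
        rmsprop_step(np.cw[l], gcw[l], acw[l], lre, rho, eps);
        rmsprop_step(np.cb[l], gcb[l], acb[l], lre, rho, eps);
      }
      rmsprop_step(np.dw, gdw, adw, lre, rho, eps);
      adb = rho * adb + (1.0 - rho) * gdb * gdb;
      np.db -= lre * gdb / std::sqrt(adb + eps);
    }
    history(e) = abs_sum / (double)n;
    if (e % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = pack_params(np),
                            Rcpp::Named("history") = history);
}
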