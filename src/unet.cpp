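// 1D U-Net denoiser: forward pass, backpropagation and Adam training.
//
// No deep-learning runtime is linked. A 'same'-padded 1-D convolution with
// kernel width k is computed as k accumulated GEMM calls on shifted column
// ranges of the activation matrix (single-precision BLAS), which avoids
// materializing an im2col buffer entirely. Activations for a batch are
// stored channels-by-positions as an (C x B*L) matrix with the B samples
// laid out contiguously; the per-sample column ranges of each tap keep
// windows from bleeding across sample boundaries (zero padding).
//
// Architecture (n_levels = depth, base = channels at level 1, pool = 2):
//   encoder level i: [conv k, ReLU] x2 -> skip -> maxpool/2
//   bottleneck:      [conv k, ReLU] x2
//   decoder level i: linear upsample x2 -> concat skip -> [conv k, ReLU] x2
//   head:            conv k=1, linear
// All randomness (init, split, shuffling) lives on the R side; this unit is
// deterministic given its inputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

extern "C" {
void sgemm_(const char* transa, const char* transb, const int* m,
            const int* n, const int* k, const float* alpha, const float* a,
            const int* lda, const float* b, const int* ldb, const float* beta,
            float* c, const int* ldc);
}

namespace {

inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

struct LayerSpec {
  int in_ch, out_ch, kernel;
  bool relu;
};

// Layer sequence for a given depth/base width.
std::vector<LayerSpec> make_layout(int n_levels, int base, int kernel) {
  std::vector<LayerSpec> L;
  int c_in = 1;
  for (int i = 0; i < n_levels; ++i) {
    int c = base << i;
    L.push_back({c_in, c, kernel, true});
    L.push_back({c, c, kernel, true});
    c_in = c;
  }
  int cb = base << n_levels;
  L.push_back({c_in, cb, kernel, true});
  L.push_back({cb, cb, kernel, true});
  c_in = cb;
  for (int i = n_levels - 1; i >= 0; --i) {
    int c = base << i;
    L.push_back({c_in + c, c, kernel, true});
    L.push_back({c, c, kernel, true});
    c_in = c;
  }
  L.push_back({c_in, 1, 1, false}); // linear projection head
  return L;
}

void maxpool2(const fmat& A, int B, int L, fmat& out, Mat<unsigned char>& sel) {
  const int C = A.n_rows, M = L / 2;
  out.set_size(C, B * M);
  sel.set_size(C, B * M);
  for (int t = 0; t < B * M; ++t) {
    const float* a = A.colptr(2 * t);
    const float* b = A.colptr(2 * t + 1);
    float* o = out.colptr(t);
    unsigned char* s = sel.colptr(t);
    for (int c = 0; c < C; ++c) {
      if (a[c] >= b[c]) { o[c] = a[c]; s[c] = 0; }
      else              { o[c] = b[c]; s[c] = 1; }
    }
  }
}

void maxpool2_back(const fmat& dOut, const Mat<unsigned char>& sel,
                   int B, int L, fmat& dA) {
  const int C = dOut.n_rows, M = L / 2;
  dA.zeros(C, B * L);
  for (int t = 0; t < B * M; ++t) {
    const float* d = dOut.colptr(t);
    const unsigned char* s = sel.colptr(t);
    for (int c = 0; c < C; ++c) dA.at(c, 2 * t + s[c]) = d[c];
  }
}

// Linear interpolation upsample x2 within each sample:
// y[2i] = x[i]; y[2i+1] = (x[i] + x[i+1]) / 2 (last: y[2M-1] = x[M-1]).
void upsample2(const fmat& A, int B, int M, fmat& out) {
  const int C = A.n_rows;
  out.set_size(C, B * 2 * M);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < M; ++i) {
      const float* x0 = A.colptr(b * M + i);
      const float* x1 = A.colptr(b * M + (i < M - 1 ? i + 1 : i));
      float* y0 = out.colptr(b * 2 * M + 2 * i);
      float* y1 = y0 + C;
      for (int c = 0; c < C; ++c) {
        y0[c] = x0[c];
        y1[c] = 0.5f * (x0[c] + x1[c]);
      }
    }
  }
}

void upsample2_back(const fmat& dOut, int B, int M, fmat& dA) {
  const int C = dOut.n_rows;
  dA.zeros(C, B * M);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < M; ++i) {
      const float* d0 = dOut.colptr(b * 2 * M + 2 * i);
      const float* d1 = d0 + C;
      float* x0 = dA.colptr(b * M + i);
      float* x1 = dA.colptr(b * M + (i < M - 1 ? i + 1 : i));
      for (int c = 0; c < C; ++c) {
        x0[c] += d0[c] + 0.5f * d1[c];
        x1[c] += 0.5f * d1[c];
      }
    }
  }
}

struct UNet {
  int n_levels, base, kernel;
  std::vector<LayerSpec> layout;
  std::vector<fmat> W;
  std::vector<fvec> b;

  // caches (valid after a forward pass)
  std::vector<fmat> conv_in;   // input activation of each conv
  std::vector<fmat> conv_pre;  // pre-activation output of each conv
  std::vector<fmat> skips;
  std::vector<Mat<unsigned char>> pool_sel;
  std::vector<int> conv_L;     // positions-per-sample at each conv
  int cur_B = 0;

  UNet(int nl, int bc, int k) : n_levels(nl), base(bc), kernel(k),
                                layout(make_layout(nl, bc, k)) {}

  // Y[:, t] = b + sum_j W_j A[:, t + o_j] (zero outside the sample).
  fmat conv_fwd(int li, const fmat& A, int B, int L, bool cache) {
    const LayerSpec& sp = layout[li];
    const int Ci = sp.in_ch, Co = sp.out_ch, k = sp.kernel, half = k / 2;
    fmat Y(Co, B * L);
    Y.each_col() = b[li];
    for (int j = 0; j < k; ++j) {
      const int o = j - half;
      const int c0 = o < 0 ? -o : 0;
      const int c1 = o > 0 ? L - 1 - o : L - 1;
      if (c1 < c0) continue;
      const float* Wj = W[li].colptr(j * Ci);
      for (int s = 0; s < B; ++s) {
        sgemm('N', 'N', Co, c1 - c0 + 1, Ci, 1.0f, Wj, Co,
              A.colptr(s * L + c0 + o), Ci, 1.0f, Y.colptr(s * L + c0), Co);
      }
    }
    if (cache) {
      conv_in[li] = A;
      conv_pre[li] = Y;
      conv_L[li] = L;
    }
    if (sp.relu) Y.for_each([](float& v) { if (v < 0.f) v = 0.f; });
    return Y;
  }

  // dY is the gradient wrt the conv's *post-activation* output.
  fmat conv_bwd(int li, fmat dY, fmat& dW, fvec& db) {
    const LayerSpec& sp = layout[li];
    const int Ci = sp.in_ch, Co = sp.out_ch, k = sp.kernel, half = k / 2;
    const int B = cur_B, L = conv_L[li];
    if (sp.relu) {
      const fmat& Z = conv_pre[li];
      for (uword j = 0; j < dY.n_cols; ++j) {
        float* d = dY.colptr(j);
        const float* z = Z.colptr(j);
        for (uword c = 0; c < dY.n_rows; ++c) if (z[c] <= 0.f) d[c] = 0.f;
      }
    }
    db = sum(dY, 1);
    const fmat& A = conv_in[li];
    dW.zeros(Co, Ci * k);
    fmat dA(Ci, B * L, fill::zeros);
    for (int j = 0; j < k; ++j) {
      const int o = j - half;
      const int c0 = o < 0 ? -o : 0;
      const int c1 = o > 0 ? L - 1 - o : L - 1;
      if (c1 < c0) continue;
      float* dWj = dW.colptr(j * Ci);
      const float* Wj = W[li].colptr(j * Ci);
      for (int s = 0; s < B; ++s) {
        const int n = c1 - c0 + 1;
        // dW_j += dY[:, c0:c1] A[:, c0+o:c1+o]^T
        sgemm('N', 'T', Co, Ci, n, 1.0f, dY.colptr(s * L + c0), Co,
              A.colptr(s * L + c0 + o), Ci, 1.0f, dWj, Co);
        // dA[:, c0+o:c1+o] += W_j^T dY[:, c0:c1]
        sgemm('T', 'N', Ci, n, Co, 1.0f, Wj, Co,
              dY.colptr(s * L + c0), Co, 1.0f, dA.colptr(s * L + c0 + o), Ci);
      }
    }
    return dA;
  }

  fmat forward(const fmat& X, int B, int L0, bool cache) {
    cur_B = B;
    conv_in.assign(layout.size(), fmat());
    conv_pre.assign(layout.size(), fmat());
    conv_L.assign(layout.size(), 0);
    skips.assign(n_levels, fmat());
    pool_sel.assign(n_levels, Mat<unsigned char>());
    fmat A = X;
    int L = L0, li = 0;
    for (int i = 0; i < n_levels; ++i) {
      A = conv_fwd(li++, A, B, L, cache);
      A = conv_fwd(li++, A, B, L, cache);
      skips[i] = A;
      fmat P;
      Mat<unsigned char> sel;
      maxpool2(A, B, L, P, sel);
      if (cache) pool_sel[i] = sel;
      A = std::move(P);
      L /= 2;
    }
    A = conv_fwd(li++, A, B, L, cache);
    A = conv_fwd(li++, A, B, L, cache);
    for (int i = n_levels - 1; i >= 0; --i) {
      fmat U;
      upsample2(A, B, L, U);
      L *= 2;
      A = join_cols(U, skips[i]);
      A = conv_fwd(li++, A, B, L, cache);
      A = conv_fwd(li++, A, B, L, cache);
    }
    return conv_fwd(li++, A, B, L, cache); // linear head
  }

  void backward(const fmat& dOut, std::vector<fmat>& gW, std::vector<fvec>& gb) {
    gW.assign(layout.size(), fmat());
    gb.assign(layout.size(), fvec());
    int li = (int)layout.size() - 1;
    fmat d = conv_bwd(li, dOut, gW[li], gb[li]);
    --li;
    std::vector<fmat> dskip(n_levels);
    for (int i = 0; i < n_levels; ++i) {
      d = conv_bwd(li, d, gW[li], gb[li]); --li;
      d = conv_bwd(li, d, gW[li], gb[li]); --li;
      const int c_up = d.n_rows - skips[i].n_rows;
      fmat dU = d.rows(0, c_up - 1);
      dskip[i] = d.rows(c_up, d.n_rows - 1);
      fmat dA;
      upsample2_back(dU, cur_B, dU.n_cols / (2 * cur_B), dA);
      d = std::move(dA);
    }
    d = conv_bwd(li, d, gW[li], gb[li]); --li;
    d = conv_bwd(li, d, gW[li], gb[li]); --li;
    for (int i = n_levels - 1; i >= 0; --i) {
      const int L = conv_L[li]; // positions at this encoder level
      fmat dA;
      maxpool2_back(d, pool_sel[i], cur_B, L, dA);
      dA += dskip[i];
      d = conv_bwd(li, dA, gW[li], gb[li]); --li;
      d = conv_bwd(li, d, gW[li], gb[li]); --li;
    }
  }
};

void load_weights(UNet& net, const Rcpp::List& Wl, const Rcpp::List& bl) {
  const size_t n = net.layout.size();
  if ((size_t)Wl.size() != n || (size_t)bl.size() != n) {
    Rcpp::stop("weight list length does not match the architecture layout");
  }
  net.W.resize(n);
  net.b.resize(n);
  for (size_t i = 0; i < n; ++i) {
    Rcpp::NumericMatrix wm = Wl[i];
    Rcpp::NumericVector bv = bl[i];
    const LayerSpec& sp = net.layout[i];
    if (wm.nrow() != sp.out_ch || wm.ncol() != sp.in_ch * sp.kernel ||
        bv.size() != sp.out_ch) {
      Rcpp::stop("layer %d has the wrong weight shape", (int)i + 1);
    }
    net.W[i] = conv_to<fmat>::from(Rcpp::as<mat>(wm));
    net.b[i] = conv_to<fvec>::from(Rcpp::as<vec>(bv));
  }
}

// Batched inference over columns of X (L x n); returns (L x n).
fmat predict_all(UNet& net, const fmat& X, int batch) {
  const int L = X.n_rows, n = X.n_cols;
  fmat out(L, n);
  for (int s = 0; s < n; s += batch) {
    const int B = std::min(batch, n - s);
    fmat A0(1, B * L);
    for (int bi = 0; bi < B; ++bi) {
      std::memcpy(A0.colptr(bi * L), X.colptr(s + bi), L * sizeof(float));
    }
    fmat P = net.forward(A0, B, L, false);
    for (int bi = 0; bi < B; ++bi) {
      std::memcpy(out.colptr(s + bi), P.colptr(bi * L), L * sizeof(float));
    }
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_unet_train(const arma::mat& noisy, const arma::mat& clean,
                          Rcpp::List W0, Rcpp::List b0,
                          int n_levels, int base_channels, int kernel,
                          Rcpp::IntegerVector train_idx,
                          Rcpp::IntegerVector val_idx,
                          Rcpp::IntegerMatrix perms,
                          int batch, double lr, double beta1, double beta2,
                          double eps) {
  const int L = noisy.n_rows;
  const int epochs = perms.ncol();
  UNet net(n_levels, base_channels, kernel);
  load_weights(net, W0, b0);

  const fmat Xn = conv_to<fmat>::from(noisy);
  const fmat Xc = conv_to<fmat>::from(clean);

  const size_t nlay = net.layout.size();
  std::vector<fmat> mW(nlay), vW(nlay), gW;
  std::vector<fvec> mb(nlay), vb(nlay), gb;
  for (size_t i = 0; i < nlay; ++i) {
    mW[i].zeros(size(net.W[i])); vW[i].zeros(size(net.W[i]));
    mb[i].zeros(net.b[i].n_elem); vb[i].zeros(net.b[i].n_elem);
  }

  const int n_train = train_idx.size();
  arma::mat history(epochs, 4);
  double best_val = datum::inf;
  int best_epoch = 0;
  std::vector<fmat> bestW(net.W.begin(), net.W.end());
  std::vector<fvec> bestb(net.b.begin(), net.b.end());
  long step = 0;

  fmat A0, T0;
  for (int ep = 0; ep < epochs; ++ep) {
    double tr_se = 0, tr_ae = 0;
    long tr_n = 0;
    for (int s = 0; s < n_train; s += batch) {
      const int B = std::min(batch, n_train - s);
      A0.set_size(1, B * L);
      T0.set_size(1, B * L);
      for (int bi = 0; bi < B; ++bi) {
        const int col = perms(s + bi, ep) - 1; // 1-based from R
        std::memcpy(A0.colptr(bi * L), Xn.colptr(col), L * sizeof(float));
        std::memcpy(T0.colptr(bi * L), Xc.colptr(col), L * sizeof(float));
      }
      fmat P = net.forward(A0, B, L, true);
      fmat R = P - T0;
      tr_se += accu(square(R));
      tr_ae += accu(abs(R));
      tr_n += (long)B * L;
      fmat dOut = (2.0f / (float)(B * L)) * R;
      net.backward(dOut, gW, gb);
      ++step;
      const float b1c = 1.0f - std::pow((float)beta1, (float)step);
      const float b2c = 1.0f - std::pow((float)beta2, (float)step);
      for (size_t i = 0; i < nlay; ++i) {
        mW[i] = (float)beta1 * mW[i] + (1.0f - (float)beta1) * gW[i];
        vW[i] = (float)beta2 * vW[i] + (1.0f - (float)beta2) * square(gW[i]);
        net.W[i] -= (float)lr * (mW[i] / b1c) / (sqrt(vW[i] / b2c) + (float)eps);
        mb[i] = (float)beta1 * mb[i] + (1.0f - (float)beta1) * gb[i];
        vb[i] = (float)beta2 * vb[i] + (1.0f - (float)beta2) * square(gb[i]);
        net.b[i] -= (float)lr * (mb[i] / b1c) / (sqrt(vb[i] / b2c) + (float)eps);
      }
    }
    // validation
    double va_se = 0, va_ae = 0;
    long va_n = 0;
    {
      const int nv = val_idx.size();
      fmat Xv(L, nv);
      for (int i = 0; i < nv; ++i) Xv.col(i) = Xn.col(val_idx[i] - 1);
      fmat Pv = predict_all(net, Xv, 64);
      for (int i = 0; i < nv; ++i) {
        fvec r = Pv.col(i) - Xc.col(val_idx[i] - 1);
        va_se += accu(square(r));
        va_ae += accu(abs(r));
        va_n += L;
      }
    }
    history(ep, 0) = tr_se / tr_n;
    history(ep, 1) = tr_ae / tr_n;
    history(ep, 2) = va_se / va_n;
    history(ep, 3) = va_ae / va_n;
    if (history(ep, 2) < best_val) {
      best_val = history(ep, 2);
      best_epoch = ep + 1;
      bestW.assign(net.W.begin(), net.W.end());
      bestb.assign(net.b.begin(), net.b.end());
    }
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List Wout(nlay), bout(nlay);
  for (size_t i = 0; i < nlay; ++i) {
    Wout[i] = Rcpp::wrap(conv_to<mat>::from(bestW[i]));
    bout[i] = Rcpp::wrap(conv_to<vec>::from(bestb[i]));
  }
  return Rcpp::List::create(Rcpp::Named("W") = Wout,
                            Rcpp::Named("b") = bout,
                            Rcpp::Named("history") = history,
                            Rcpp::Named("best_epoch") = best_epoch,
                            Rcpp::Named("best_val_mse") = best_val);
}

// MSE loss and analytic parameter gradients for one batch; used by the
// finite-difference gradient tests.
// [[Rcpp::export]]
Rcpp::List cpp_unet_lossgrad(const arma::mat& noisy, const arma::mat& clean,
                             Rcpp::List W0, Rcpp::List b0,
                             int n_levels, int base_channels, int kernel) {
  const int L = noisy.n_rows, B = noisy.n_cols;
  UNet net(n_levels, base_channels, kernel);
  load_weights(net, W0, b0);
  fmat A0(1, B * L), T0(1, B * L);
  const fmat Xn = conv_to<fmat>::from(noisy);
  const fmat Xc = conv_to<fmat>::from(clean);
  for (int bi = 0; bi < B; ++bi) {
    std::memcpy(A0.colptr(bi * L), Xn.colptr(bi), L * sizeof(float));
    std::memcpy(T0.colptr(bi * L), Xc.colptr(bi), L * sizeof(float));
  }
  fmat P = net.forward(A0, B, L, true);
  fmat R = P - T0;
  const double loss = accu(square(R)) / (double)(B * L);
  std::vector<fmat> gW;
  std::vector<fvec> gb;
  fmat dOut = (2.0f / (float)(B * L)) * R;
  net.backward(dOut, gW, gb);
  Rcpp::List gWout(gW.size()), gbout(gb.size());
  for (size_t i = 0; i < gW.size(); ++i) {
    gWout[i] = Rcpp::wrap(conv_to<mat>::from(gW[i]));
    gbout[i] = Rcpp::wrap(conv_to<vec>::from(gb[i]));
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("gW") = gWout,
                            Rcpp::Named("gb") = gbout);
}

// [[Rcpp::export]]
arma::mat cpp_unet_predict(const arma::mat& X, Rcpp::List W, Rcpp::List b,
                           int n_levels, int base_channels, int kernel) {
  UNet net(n_levels, base_channels, kernel);
  load_weights(net, W, b);
  fmat out = predict_all(net, conv_to<fmat>::from(X), 64);
  return conv_to<mat>::from(out);
}
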