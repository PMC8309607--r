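// 1D fully convolutional denoiser: forward, backprop and SGD training.
//
// Performance-oriented layout (everything here runs on a single CPU):
//  - An activation batch is an arma::Mat of size (channels x B*S) where
//    S = N + 2*PAD and each spectrum occupies S contiguous columns with
//    PAD zero columns on each side. PAD is the largest one-sided "same"
//    padding among the multi-channel layers, so a convolution becomes a
//    handful of shifted GEMMs over the whole batch at once: the zero pad
//    columns between spectra absorb the kernel overhang and no im2col
//    matrix is ever materialized for the channel-heavy layers.
//  - Conv weights come from R as an array of dim (k, Cin, Cout) and are
//    flattened to a (Cout x k*Cin) matrix with column index t*Cin + ci.
//  - "Same" padding at stride 1: pad_left = floor((k-1)/2),
//    pad_right = ceil((k-1)/2) (left-light for even kernel widths).
//  - Single-channel layers (Cin == Cout == 1, e.g. the final
//    spectrum-wide kernel) use direct dot-product correlation loops.
//  - Batch norm: biased variance, eps = 1e-5, running-stat momentum 0.1;
//    training mode normalizes with batch statistics, inference with the
//    accumulated running statistics. The convolution bias of a unit that
//    is immediately batch-normalized is mathematically inert (absorbed by
//    the mean subtraction), so it is left out of the forward pass; its
//    gradient is the (identically ~zero) column sum of the normalized
//    gradient.
//
// The training path is instantiated in single precision (batch GEMMs
// dominate and sgemm is ~2x dgemm); inference and the gradient check used
// by the tests run in double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

// Winograd F(4,5) transforms (output tile 4, kernel 5, input tile 8) over
// the interpolation points {0, +-1, +-2, +-1/2, inf}; derived exactly from
// the Cook-Toom construction, so the schedule is algebraically identical to
// direct convolution. BT transforms input tiles, G kernels, AT accumulates
// the output tile; the backward pass reuses the same matrices transposed.
static const double WINO_BT[8][8] = {
  {1, 0, -5.25, 0, 5.25, 0, -1, 0},
  {0, -2.0/9, -2.0/9, 8.5/9, 8.5/9, -2.0/9, -2.0/9, 0},
  {0, 2.0/9, -2.0/9, -8.5/9, 8.5/9, 2.0/9, -2.0/9, 0},
  {0, 1.0/180, 0.5/180, -5.0/180, -2.5/180, 4.0/180, 2.0/180, 0},
  {0, -1.0/180, 0.5/180, 5.0/180, -2.5/180, -4.0/180, 2.0/180, 0},
  {0, 64.0/45, 128.0/45, -80.0/45, -160.0/45, 16.0/45, 32.0/45, 0},
  {0, -64.0/45, 128.0/45, 80.0/45, -160.0/45, -16.0/45, 32.0/45, 0},
  {0, -1, 0, 5.25, 0, -5.25, 0, 1},
};
static const double WINO_G[8][5] = {
  {1, 0, 0, 0, 0},
  {1, 1, 1, 1, 1},
  {1, -1, 1, -1, 1},
  {1, 2, 4, 8, 16},
  {1, -2, 4, -8, 16},
  {1, 0.5, 0.25, 0.125, 0.0625},
  {1, -0.5, 0.25, -0.125, 0.0625},
  {0, 0, 0, 0, 1},
};
static const double WINO_AT[4][8] = {
  {1, 1, 1, 1, 1, 1, 1, 0},
  {0, 1, -1, 2, -2, 0.5, -0.5, 0},
  {0, 1, 1, 4, 4, 0.25, 0.25, 0},
  {0, 1, -1, 8, -8, 0.125, -0.125, 1},
};

template <typename eT>
struct Layer {
  int k = 0, Cin = 0, Cout = 0, pl = 0, pr = 0;
  bool bn = false, onechan = false, tiny = false, wino = false;
  Mat<eT> W;                      // Cout x (k*Cin)
  Col<eT> b, gamma, beta, rmean, rvar;
  // momentum buffers
  Mat<eT> vW; Col<eT> vb, vgamma, vbeta;
  // per-batch caches
  Mat<eT> xh, a, dA, col;
  Col<eT> mu, istd;
  // Winograd-domain caches: Ux[p] (Cin x tiles), Zp[p] (Cout x tiles)
  std::array< Mat<eT>, 8 > Ux, Zp;
  // gradients
  Mat<eT> gW; Col<eT> gb, ggamma, gbeta;
};

template <typename eT>
struct Net {
  std::vector< Layer<eT> > L;
  int N = 0, PAD = 0, S = 0, Bmax = 0;
  Mat<eT> X0;                     // 1 x Bmax*S padded input buffer
};

template <typename eT>
static Mat<eT> alias_cols(const Mat<eT>& M, size_t c0, size_t ncols) {
  return Mat<eT>(const_cast<eT*>(M.memptr()) + M.n_rows * c0,
                 M.n_rows, ncols, false, true);
}

template <typename eT>
static void load_net(Net<eT>& net, const Rcpp::List& layers, int N, int Bmax) {
  net.N = N; net.Bmax = Bmax;
  net.L.resize(layers.size());
  int pad = 0;
  for (int li = 0; li < layers.size(); ++li) {
    Rcpp::List lay = layers[li];
    Rcpp::NumericVector Wr = lay["W"];
    Rcpp::IntegerVector d = Wr.attr("dim");
    Layer<eT>& l = net.L[li];
    l.k = d[0]; l.Cin = d[1]; l.Cout = d[2];
    l.pl = (l.k - 1) / 2; l.pr = l.k - 1 - l.pl;
    l.bn = Rcpp::as<bool>(lay["has_bn"]);
    l.onechan = (l.Cin == 1 && l.Cout == 1);
    l.tiny = (!l.onechan && (size_t)l.Cin * l.k <= 16);
    if (!l.onechan) pad = std::max(pad, l.pr);
    l.W.set_size(l.Cout, l.k * l.Cin);
    for (int o = 0; o < l.Cout; ++o)
      for (int ci = 0; ci < l.Cin; ++ci)
        for (int t = 0; t < l.k; ++t)
          l.W(o, t * l.Cin + ci) = (eT) Wr[t + l.k * ci + (size_t)l.k * l.Cin * o];
    l.b = conv_to< Col<eT> >::from(Rcpp::as<arma::vec>(lay["b"]));
    if (l.bn) {
      l.gamma = conv_to< Col<eT> >::from(Rcpp::as<arma::vec>(lay["gamma"]));
      l.beta  = conv_to< Col<eT> >::from(Rcpp::as<arma::vec>(lay["beta"]));
      l.rmean = conv_to< Col<eT> >::from(Rcpp::as<arma::vec>(lay["running_mean"]));
      l.rvar  = conv_to< Col<eT> >::from(Rcpp::as<arma::vec>(lay["running_var"]));
    }
  }
  net.PAD = pad;
  net.S = N + 2 * pad;
  const size_t BS = (size_t)Bmax * net.S;
  net.X0.zeros(1, BS);
  for (auto& l : net.L) {
    if (l.bn) l.xh.set_size(l.Cout, BS);
    l.a.zeros(l.Cout, BS);
    l.dA.zeros(l.Cout, BS);
    l.gW.set_size(l.Cout, (size_t)l.k * l.Cin);
    if (l.tiny) l.col.set_size((size_t)l.k * l.Cin, BS);
    l.wino = (!l.onechan && !l.tiny && l.k == 5 && N % 4 == 0 && pad >= 2);
    if (l.wino) {
      const size_t T = (size_t)Bmax * (N / 4);
      for (int p = 0; p < 8; ++p) {
        l.Ux[p].set_size(l.Cin, T);
        l.Zp[p].set_size(l.Cout, T);
      }
    }
  }
}

template <typename eT>
static Rcpp::List store_layers(const Net<eT>& net, const Rcpp::List& proto) {
  Rcpp::List out(net.L.size());
  for (size_t li = 0; li < net.L.size(); ++li) {
    const Layer<eT>& l = net.L[li];
    Rcpp::List lay = Rcpp::clone(Rcpp::as<Rcpp::List>(proto[li]));
    Rcpp::NumericVector Wr((size_t)l.k * l.Cin * l.Cout);
    Wr.attr("dim") = Rcpp::IntegerVector::create(l.k, l.Cin, l.Cout);
    for (int o = 0; o < l.Cout; ++o)
      for (int ci = 0; ci < l.Cin; ++ci)
        for (int t = 0; t < l.k; ++t)
          Wr[t + l.k * ci + (size_t)l.k * l.Cin * o] = (double) l.W(o, t * l.Cin + ci);
    lay["W"] = Wr;
    lay["b"] = Rcpp::wrap(conv_to<arma::vec>::from(l.b));
    if (l.bn) {
      lay["gamma"] = Rcpp::wrap(conv_to<arma::vec>::from(l.gamma));
      lay["beta"]  = Rcpp::wrap(conv_to<arma::vec>::from(l.beta));
      lay["running_mean"] = Rcpp::wrap(conv_to<arma::vec>::from(l.rmean));
      lay["running_var"]  = Rcpp::wrap(conv_to<arma::vec>::from(l.rvar));
    }
    out[li] = lay;
  }
  return out;
}

// Zero the PAD columns flanking each spectrum of a (channels x Bc*S) buffer.
template <typename eT>
static void zero_pads(Mat<eT>& M, int Bc, int S, int PAD) {
  if (PAD == 0) return;
  const int N = S - 2 * PAD;
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S;
    M.cols(off, off + PAD - 1).zeros();
    M.cols(off + PAD + N, off + S - 1).zeros();
  }
}

// --- convolution primitives -------------------------------------------------

// Multi-channel conv as shifted GEMMs: Z[:, j] += sum_t W_t X[:, j+t-pl].
template <typename eT>
static void conv_forward_offsets(const Layer<eT>& l, const Mat<eT>& X,
                                 Mat<eT>& Z, size_t cols_cur) {
  for (int t = 0; t < l.k; ++t) {
    const long s = t - l.pl;
    const long c0 = std::max(0L, -s);
    const long c1 = (long)cols_cur - 1 - std::max(0L, s);
    if (c0 > c1) continue;
    Mat<eT> Wt = l.W.cols((size_t)t * l.Cin, (size_t)(t + 1) * l.Cin - 1);
    Mat<eT> Xal = alias_cols(X, c0 + s, c1 - c0 + 1);
    Mat<eT> Zal = alias_cols(Z, c0, c1 - c0 + 1);
    Zal += Wt * Xal;
  }
}

// Small-fan-in conv (e.g. the 1-channel first layer): build the tiny im2col
// matrix once and run a single GEMM; the col matrix is reused for dW.
template <typename eT>
static void conv_forward_tiny(Layer<eT>& l, const Mat<eT>& X,
                              Mat<eT>& Z, size_t cols_cur) {
  const int kc = l.k * l.Cin;
  for (size_t j = 0; j < cols_cur; ++j) {
    eT* cj = l.col.colptr(j);
    for (int t = 0; t < l.k; ++t) {
      const long src = (long)j + t - l.pl;
      const eT* xj = (src < 0 || src >= (long)cols_cur) ? nullptr : X.colptr(src);
      for (int ci = 0; ci < l.Cin; ++ci)
        cj[t * l.Cin + ci] = xj ? xj[ci] : (eT)0;
    }
  }
  Mat<eT> colal(l.col.memptr(), kc, cols_cur, false, true);
  Mat<eT> Zal = alias_cols(Z, 0, cols_cur);
  Zal += l.W * colal;
}

template <typename eT>
static void conv_backward_offsets(Layer<eT>& l, const Mat<eT>& X,
                                  const Mat<eT>& D, Mat<eT>* dX,
                                  size_t cols_cur) {
  for (int t = 0; t < l.k; ++t) {
    const long s = t - l.pl;
    const long c0 = std::max(0L, -s);
    const long c1 = (long)cols_cur - 1 - std::max(0L, s);
    Mat<eT> gWt(l.gW.memptr() + (size_t)l.Cout * t * l.Cin, l.Cout, l.Cin,
                false, true);
    if (c0 > c1) { gWt.zeros(); continue; }
    Mat<eT> Xal = alias_cols(X, c0 + s, c1 - c0 + 1);
    Mat<eT> Dal = alias_cols(D, c0, c1 - c0 + 1);
    gWt = Dal * Xal.t();
    if (dX) {
      Mat<eT> Wt = l.W.cols((size_t)t * l.Cin, (size_t)(t + 1) * l.Cin - 1);
      Mat<eT> WtT = Wt.t();
      Mat<eT> dXal = alias_cols(*dX, c0 + s, c1 - c0 + 1);
      dXal += WtT * Dal;
    }
  }
}

template <typename eT>
static void conv_backward_tiny(Layer<eT>& l, const Mat<eT>& X,
                               const Mat<eT>& D, Mat<eT>* dX,
                               size_t cols_cur) {
  Mat<eT> colal(l.col.memptr(), l.k * l.Cin, cols_cur, false, true);
  Mat<eT> Dal = alias_cols(D, 0, cols_cur);
  l.gW = Dal * colal.t();
  if (dX) {
    // reuse the generic shifted-GEMM input gradient (no col2im needed)
    for (int t = 0; t < l.k; ++t) {
      const long s = t - l.pl;
      const long c0 = std::max(0L, -s);
      const long c1 = (long)cols_cur - 1 - std::max(0L, s);
      if (c0 > c1) continue;
      Mat<eT> Wt = l.W.cols((size_t)t * l.Cin, (size_t)(t + 1) * l.Cin - 1);
      Mat<eT> WtT = Wt.t();
      Mat<eT> Dsub = alias_cols(D, c0, c1 - c0 + 1);
      Mat<eT> dXal = alias_cols(*dX, c0 + s, c1 - c0 + 1);
      dXal += WtT * Dsub;
    }
  }
}

// Single-channel conv of arbitrary kernel width (the spectrum-wide final
// layer): per-spectrum padded dot products.
template <typename eT>
static void conv_forward_onechan(const Layer<eT>& l, const Mat<eT>& X,
                                 Mat<eT>& Z, int Bc, int S, int PAD, int N,
                                 bool add_bias, std::vector<eT>& scratch) {
  scratch.assign((size_t)N + l.k - 1, (eT)0);
  const eT* w = l.W.memptr();              // row vector of length k
  const eT b0 = add_bias ? l.b[0] : (eT)0;
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S + PAD;
    for (int i = 0; i < N; ++i) scratch[l.pl + i] = X(0, off + i);
    for (int i = 0; i < N; ++i) {
      eT acc = 0;
      const eT* xp = scratch.data() + i;
      for (int t = 0; t < l.k; ++t) acc += w[t] * xp[t];
      Z(0, off + i) = acc + b0;
    }
  }
}

template <typename eT>
static void conv_backward_onechan(Layer<eT>& l, const Mat<eT>& X,
                                  const Mat<eT>& D, Mat<eT>* dX,
                                  int Bc, int S, int PAD, int N,
                                  std::vector<eT>& scratch,
                                  std::vector<eT>& scratch2) {
  l.gW.zeros(1, l.k);
  eT* gw = l.gW.memptr();
  scratch.assign((size_t)N + l.k - 1, (eT)0);    // padded input
  scratch2.assign((size_t)N + l.k - 1, (eT)0);   // padded upstream gradient
  std::vector<eT> wrev(l.k);
  for (int t = 0; t < l.k; ++t) wrev[t] = l.W(0, l.k - 1 - t);
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S + PAD;
    for (int i = 0; i < N; ++i) scratch[l.pl + i] = X(0, off + i);
    // dW(q) = sum_i d(i) * xpad(i + q)
    for (int q = 0; q < l.k; ++q) {
      eT acc = 0;
      const eT* xp = scratch.data() + q;
      for (int i = 0; i < N; ++i) acc += D(0, off + i) * xp[i];
      gw[q] += acc;
    }
    if (dX) {
      // dx(p) = sum_q W(q) d(p + pl - q) = dot(Wrev, dpad + p)
      for (int i = 0; i < N; ++i) scratch2[l.pr + i] = D(0, off + i);
      for (int p = 0; p < N; ++p) {
        eT acc = 0;
        const eT* dp = scratch2.data() + p;
        for (int t = 0; t < l.k; ++t) acc += wrev[t] * dp[t];
        (*dX)(0, off + p) += acc;
      }
    }
  }
}

// --- Winograd F(4,5) path for width-5 multi-channel layers ------------------

// Forward: transform input tiles into the Winograd domain, run one GEMM per
// domain point over the channel dimensions, and accumulate output tiles.
// Writes (assigns) the interior columns of Z; pads are not touched.
template <typename eT>
static void wino_forward(Layer<eT>& l, const Mat<eT>& X, Mat<eT>& Z,
                         int Bc, int S, int PAD, int N, bool add_bias) {
  const int Tspec = N / 4;
  const size_t T = (size_t)Bc * Tspec;
  const int Cin = l.Cin, Cout = l.Cout;
  std::vector<eT> acc((size_t)8 * Cin);
  // input transform: Ux[p](:, tile) = sum_u BT[p][u] * x(:, win_start + u)
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S + PAD;
    for (int t = 0; t < Tspec; ++t) {
      const size_t tile = (size_t)b * Tspec + t;
      std::fill(acc.begin(), acc.end(), (eT)0);
      const size_t js = off + 4 * t - l.pl;
      for (int u = 0; u < 8; ++u) {
        const eT* xc = X.colptr(js + u);
        for (int p = 0; p < 8; ++p) {
          const eT c = (eT) WINO_BT[p][u];
          if (c == (eT)0) continue;
          eT* ap = acc.data() + (size_t)p * Cin;
          for (int ci = 0; ci < Cin; ++ci) ap[ci] += c * xc[ci];
        }
      }
      for (int p = 0; p < 8; ++p)
        std::memcpy(l.Ux[p].colptr(tile), acc.data() + (size_t)p * Cin,
                    sizeof(eT) * Cin);
    }
  }
  // kernel transform + domain GEMMs
  for (int p = 0; p < 8; ++p) {
    Mat<eT> Uw(Cout, Cin);
    for (int o = 0; o < Cout; ++o)
      for (int ci = 0; ci < Cin; ++ci) {
        eT s = 0;
        for (int q = 0; q < 5; ++q)
          s += (eT) WINO_G[p][q] * l.W(o, (size_t)q * Cin + ci);
        Uw(o, ci) = s;
      }
    Mat<eT> Uxal(l.Ux[p].memptr(), Cin, T, false, true);
    Mat<eT> Zal(l.Zp[p].memptr(), Cout, T, false, true);
    Zal = Uw * Uxal;
  }
  // output transform
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S + PAD;
    for (int t = 0; t < Tspec; ++t) {
      const size_t tile = (size_t)b * Tspec + t;
      const eT* zp[8];
      for (int p = 0; p < 8; ++p) zp[p] = l.Zp[p].colptr(tile);
      for (int i = 0; i < 4; ++i) {
        eT* dst = Z.colptr(off + 4 * t + i);
        if (add_bias) std::memcpy(dst, l.b.memptr(), sizeof(eT) * Cout);
        else std::memset(dst, 0, sizeof(eT) * Cout);
        for (int p = 0; p < 8; ++p) {
          const eT c = (eT) WINO_AT[i][p];
          if (c == (eT)0) continue;
          const eT* src = zp[p];
          for (int o = 0; o < Cout; ++o) dst[o] += c * src[o];
        }
      }
    }
  }
}

// Backward: transform the upstream gradient into the domain, one GEMM per
// point for the kernel gradient (vs the cached input transform) and one for
// the input gradient, then back-transform with overlap-add into dX.
template <typename eT>
static void wino_backward(Layer<eT>& l, const Mat<eT>& D, Mat<eT>* dX,
                          int Bc, int S, int PAD, int N) {
  const int Tspec = N / 4;
  const size_t T = (size_t)Bc * Tspec;
  const int Cin = l.Cin, Cout = l.Cout;
  // dZ[p](:, tile) = sum_i AT[i][p] * d(:, out_start + i); reuse Zp storage
  std::vector<eT> acc((size_t)8 * std::max(Cin, Cout));
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S + PAD;
    for (int t = 0; t < Tspec; ++t) {
      const size_t tile = (size_t)b * Tspec + t;
      std::fill(acc.begin(), acc.begin() + (size_t)8 * Cout, (eT)0);
      for (int i = 0; i < 4; ++i) {
        const eT* dc = D.colptr(off + 4 * t + i);
        for (int p = 0; p < 8; ++p) {
          const eT c = (eT) WINO_AT[i][p];
          if (c == (eT)0) continue;
          eT* ap = acc.data() + (size_t)p * Cout;
          for (int o = 0; o < Cout; ++o) ap[o] += c * dc[o];
        }
      }
      for (int p = 0; p < 8; ++p)
        std::memcpy(l.Zp[p].colptr(tile), acc.data() + (size_t)p * Cout,
                    sizeof(eT) * Cout);
    }
  }
  // kernel gradient: dUw[p] = dZ[p] * Ux[p]^T ; gW = G^T-combined
  l.gW.zeros(Cout, (size_t)5 * Cin);
  for (int p = 0; p < 8; ++p) {
    Mat<eT> dZal(l.Zp[p].memptr(), Cout, T, false, true);
    Mat<eT> Uxal(l.Ux[p].memptr(), Cin, T, false, true);
    Mat<eT> dUw = dZal * Uxal.t();
    for (int q = 0; q < 5; ++q) {
      const eT c = (eT) WINO_G[p][q];
      if (c == (eT)0) continue;
      Mat<eT> gWq(l.gW.memptr() + (size_t)Cout * q * Cin, Cout, Cin, false, true);
      gWq += c * dUw;
    }
  }
  if (!dX) return;
  // input gradient: dUx[p] = Uw[p]^T * dZ[p] (overwrites Ux), then
  // back-transform and overlap-add into dX (pre-zeroed by the caller)
  for (int p = 0; p < 8; ++p) {
    Mat<eT> Uw(Cout, Cin);
    for (int o = 0; o < Cout; ++o)
      for (int ci = 0; ci < Cin; ++ci) {
        eT s = 0;
        for (int q = 0; q < 5; ++q)
          s += (eT) WINO_G[p][q] * l.W(o, (size_t)q * Cin + ci);
        Uw(o, ci) = s;
      }
    Mat<eT> UwT = Uw.t();
    Mat<eT> dZal(l.Zp[p].memptr(), Cout, T, false, true);
    Mat<eT> dUxal(l.Ux[p].memptr(), Cin, T, false, true);
    dUxal = UwT * dZal;
  }
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S + PAD;
    for (int t = 0; t < Tspec; ++t) {
      const size_t tile = (size_t)b * Tspec + t;
      const eT* up[8];
      for (int p = 0; p < 8; ++p) up[p] = l.Ux[p].colptr(tile);
      const size_t js = off + 4 * t - l.pl;
      for (int u = 0; u < 8; ++u) {
        eT* dst = dX->colptr(js + u);
        for (int p = 0; p < 8; ++p) {
          const eT c = (eT) WINO_BT[p][u];
          if (c == (eT)0) continue;
          const eT* src = up[p];
          for (int ci = 0; ci < Cin; ++ci) dst[ci] += c * src[ci];
        }
      }
    }
  }
}

// --- batch norm + ReLU ------------------------------------------------------

template <typename eT>
static void bn_forward_train(Layer<eT>& l, int Bc, int S, int PAD, int N) {
  const int C = l.Cout;
  const double M = (double)Bc * N;
  std::vector<double> sum(C, 0.0), sumsq(C, 0.0);
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S + PAD;
    for (int i = 0; i < N; ++i) {
      const eT* z = l.xh.colptr(off + i);
      for (int c = 0; c < C; ++c) { sum[c] += z[c]; sumsq[c] += (double)z[c] * z[c]; }
    }
  }
  l.mu.set_size(C); l.istd.set_size(C);
  for (int c = 0; c < C; ++c) {
    const double m = sum[c] / M;
    const double v = sumsq[c] / M - m * m;
    l.mu[c] = (eT)m;
    l.istd[c] = (eT)(1.0 / std::sqrt(v + BN_EPS));
    l.rmean[c] = (eT)((1 - BN_MOMENTUM) * l.rmean[c] + BN_MOMENTUM * m);
    l.rvar[c]  = (eT)((1 - BN_MOMENTUM) * l.rvar[c]  + BN_MOMENTUM * v);
  }
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S + PAD;
    for (int i = 0; i < N; ++i) {
      eT* z = l.xh.colptr(off + i);
      eT* a = l.a.colptr(off + i);
      for (int c = 0; c < C; ++c) {
        const eT xh = (z[c] - l.mu[c]) * l.istd[c];
        z[c] = xh;
        const eT y = l.gamma[c] * xh + l.beta[c];
        a[c] = y > (eT)0 ? y : (eT)0;
      }
    }
  }
}

template <typename eT>
static void bn_forward_infer(Layer<eT>& l, int Bc, int S, int PAD, int N) {
  const int C = l.Cout;
  std::vector<eT> irstd(C);
  for (int c = 0; c < C; ++c)
    irstd[c] = (eT)(1.0 / std::sqrt((double)l.rvar[c] + BN_EPS));
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S + PAD;
    for (int i = 0; i < N; ++i) {
      const eT* z = l.xh.colptr(off + i);
      eT* a = l.a.colptr(off + i);
      for (int c = 0; c < C; ++c) {
        const eT y = l.gamma[c] * ((z[c] - l.rmean[c]) * irstd[c]) + l.beta[c];
        a[c] = y > (eT)0 ? y : (eT)0;
      }
    }
  }
}

// Transform the upstream gradient (in l.dA, wrt the post-ReLU output) into
// the gradient wrt the convolution output, in place; fills gbeta/ggamma/gb.
template <typename eT>
static void bn_backward(Layer<eT>& l, int Bc, int S, int PAD, int N) {
  const int C = l.Cout;
  const double M = (double)Bc * N;
  std::vector<double> sb(C, 0.0), sg(C, 0.0);
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S + PAD;
    for (int i = 0; i < N; ++i) {
      eT* d = l.dA.colptr(off + i);
      const eT* a = l.a.colptr(off + i);
      const eT* xh = l.xh.colptr(off + i);
      for (int c = 0; c < C; ++c) {
        if (a[c] <= (eT)0) d[c] = (eT)0;
        sb[c] += d[c]; sg[c] += (double)d[c] * xh[c];
      }
    }
  }
  l.gbeta.set_size(C); l.ggamma.set_size(C); l.gb.zeros(C);
  std::vector<eT> mb(C), mg(C), gi(C);
  std::vector<double> dzsum(C, 0.0);
  for (int c = 0; c < C; ++c) {
    l.gbeta[c] = (eT)sb[c];
    l.ggamma[c] = (eT)sg[c];
    mb[c] = (eT)(sb[c] / M);
    mg[c] = (eT)(sg[c] / M);
    gi[c] = l.gamma[c] * l.istd[c];
  }
  for (int b = 0; b < Bc; ++b) {
    const size_t off = (size_t)b * S + PAD;
    for (int i = 0; i < N; ++i) {
      eT* d = l.dA.colptr(off + i);
      const eT* xh = l.xh.colptr(off + i);
      for (int c = 0; c < C; ++c) {
        d[c] = gi[c] * (d[c] - mb[c] - xh[c] * mg[c]);
        dzsum[c] += d[c];
      }
    }
  }
  for (int c = 0; c < C; ++c) l.gb[c] = (eT)dzsum[c];
}

// --- network passes ---------------------------------------------------------

template <typename eT>
static const Mat<eT>& forward(Net<eT>& net, int Bc, bool training) {
  const int S = net.S, PAD = net.PAD, N = net.N;
  const size_t cols_cur = (size_t)Bc * S;
  std::vector<eT> scratch;
  const Mat<eT>* X = &net.X0;
  for (auto& l : net.L) {
    Mat<eT>& Z = l.bn ? l.xh : l.a;
    if (l.wino) {
      wino_forward(l, *X, Z, Bc, S, PAD, N, !l.bn);
    } else if (l.onechan) {
      conv_forward_onechan(l, *X, Z, Bc, S, PAD, N, !l.bn, scratch);
    } else {
      Mat<eT> Zal = alias_cols(Z, 0, cols_cur);
      if (l.bn) Zal.zeros();
      else for (size_t j = 0; j < cols_cur; ++j)
        std::memcpy(Z.colptr(j), l.b.memptr(), sizeof(eT) * l.Cout);
      if (l.tiny) conv_forward_tiny(l, *X, Z, cols_cur);
      else conv_forward_offsets(l, *X, Z, cols_cur);
    }
    if (l.bn) {
      if (training) bn_forward_train(l, Bc, S, PAD, N);
      else bn_forward_infer(l, Bc, S, PAD, N);
    } else if (!l.onechan) {
      zero_pads(l.a, Bc, S, PAD);
    }
    X = &l.a;
  }
  return net.L.back().a;
}

// Backprop from the gradient stored in the last layer's dA (interior
// columns; pads zero). Fills every layer's gW/gb/(ggamma/gbeta).
template <typename eT>
static void backward(Net<eT>& net, int Bc) {
  const int S = net.S, PAD = net.PAD, N = net.N;
  const size_t cols_cur = (size_t)Bc * S;
  std::vector<eT> scratch, scratch2;
  for (int li = (int)net.L.size() - 1; li >= 0; --li) {
    Layer<eT>& l = net.L[li];
    const Mat<eT>& X = (li > 0) ? net.L[li - 1].a : net.X0;
    if (l.bn) {
      bn_backward(l, Bc, S, PAD, N);
    } else {
      // linear output unit: bias gradient is the plain column sum
      std::vector<double> s(l.Cout, 0.0);
      for (int b = 0; b < Bc; ++b) {
        const size_t off = (size_t)b * S + PAD;
        for (int i = 0; i < N; ++i) {
          const eT* d = l.dA.colptr(off + i);
          for (int c = 0; c < l.Cout; ++c) s[c] += d[c];
        }
      }
      l.gb.set_size(l.Cout);
      for (int c = 0; c < l.Cout; ++c) l.gb[c] = (eT)s[c];
    }
    Mat<eT>* dX = nullptr;
    if (li > 0) {
      dX = &net.L[li - 1].dA;
      Mat<eT> dXal = alias_cols(*dX, 0, cols_cur);
      dXal.zeros();
    }
    if (l.wino)
      wino_backward(l, l.dA, dX, Bc, S, PAD, N);
    else if (l.onechan)
      conv_backward_onechan(l, X, l.dA, dX, Bc, S, PAD, N, scratch, scratch2);
    else if (l.tiny)
      conv_backward_tiny(l, X, l.dA, dX, cols_cur);
    else
      conv_backward_offsets(l, X, l.dA, dX, cols_cur);
    if (dX) zero_pads(*dX, Bc, S, PAD);
  }
}

// --- loss -------------------------------------------------------------------

// Peak-weighted squared-error loss over a batch held in padded layout.
// Returns the batch mean of  mean(e^2) + alpha * mean_window(e^2)  and, if
// dOut is non-null, writes gmul * d(per-spectrum loss)/d(prediction) into
// its interior columns (gmul = N for the summed-square objective, 1/B for
// the batch-mean objective).
template <typename eT>
static double batch_loss_grad(const Mat<eT>& P, const Mat<eT>& Y,
                              const int* pk, const int* nwin,
                              double alpha, int Bc, int S, int PAD, int N,
                              double gmul, Mat<eT>* dOut) {
  double total = 0.0;
  for (int s = 0; s < Bc; ++s) {
    const size_t off = (size_t)s * S + PAD;
    const int lo = pk[s] - 1 - nwin[s], hi = pk[s] - 1 + nwin[s];
    const double w_full = 1.0 / N;
    const double w_win = alpha / (2.0 * nwin[s] + 1.0);
    double ls = 0.0;
    for (int i = 0; i < N; ++i) {
      const double e = (double)P(0, off + i) - (double)Y(0, off + i);
      const double wi = w_full + ((i >= lo && i <= hi) ? w_win : 0.0);
      ls += wi * e * e;
      if (dOut) (*dOut)(0, off + i) = (eT)(2.0 * wi * e * gmul);
    }
    total += ls;
  }
  return total / Bc;
}

template <typename eT>
static double batch_mse(const Mat<eT>& P, const Mat<eT>& Y,
                        int Bc, int S, int PAD, int N) {
  double total = 0.0;
  for (int s = 0; s < Bc; ++s) {
    const size_t off = (size_t)s * S + PAD;
    double ls = 0.0;
    for (int i = 0; i < N; ++i) {
      const double e = (double)P(0, off + i) - (double)Y(0, off + i);
      ls += e * e;
    }
    total += ls / N;
  }
  return total / Bc;
}

// Deterministic shuffle (Fisher-Yates over a 64-bit LCG) so training order
// depends only on the seed, not on R's RNG or the C++ standard library.
struct Lcg64 {
  uint64_t s;
  explicit Lcg64(uint64_t seed) : s(seed * 2862933555777941757ULL + 3037000493ULL) {}
  uint64_t next() { s = s * 6364136223846793005ULL + 1442695040888963407ULL; return s >> 16; }
};
static void shuffle_idx(std::vector<int>& idx, Lcg64& rng) {
  for (size_t i = idx.size() - 1; i > 0; --i) {
    size_t j = (size_t)(rng.next() % (i + 1));
    std::swap(idx[i], idx[j]);
  }
}

// Copy selected spectra (columns of an N x n matrix) into the interior of a
// padded (1 x B*S) buffer.
template <typename eT>
static void gather(const Mat<eT>& Xsrc, const std::vector<int>& idx,
                   int from, int Bc, int S, int PAD, int N, Mat<eT>& out) {
  for (int s = 0; s < Bc; ++s)
    std::memcpy(out.memptr() + (size_t)s * S + PAD,
                Xsrc.colptr(idx[from + s]), sizeof(eT) * N);
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::List layers,
                         const arma::mat& Xtr, const arma::mat& Ytr,
                         const arma::ivec& pk_tr, const arma::ivec& n_tr,
                         const arma::mat& Xval, const arma::mat& Yval,
                         const arma::ivec& pk_val, const arma::ivec& n_val,
                         double alpha, double lr0, double momentum,
                         int batch_size, int n_epochs, int lr_half_epoch,
                         int seed, bool sum_objective) {
  typedef float eT;
  const int N = Xtr.n_rows;
  const int ntr = Xtr.n_cols, nval = Xval.n_cols;
  const int nbatch = (ntr + batch_size - 1) / batch_size;

  Net<eT> net;
  load_net(net, layers, N, batch_size);
  const int S = net.S, PAD = net.PAD;

  Mat<eT> Xt = conv_to< Mat<eT> >::from(Xtr);
  Mat<eT> Yt = conv_to< Mat<eT> >::from(Ytr);
  Mat<eT> Xv = conv_to< Mat<eT> >::from(Xval);
  Mat<eT> Yv = conv_to< Mat<eT> >::from(Yval);

  for (auto& l : net.L) {
    l.vW.zeros(l.W.n_rows, l.W.n_cols);
    l.vb.zeros(l.b.n_elem);
    if (l.bn) { l.vgamma.zeros(l.gamma.n_elem); l.vbeta.zeros(l.beta.n_elem); }
  }

  std::vector<int> idx(ntr), vidx(nval);
  for (int i = 0; i < ntr; ++i) idx[i] = i;
  for (int i = 0; i < nval; ++i) vidx[i] = i;
  Lcg64 rng((uint64_t)(uint32_t)seed);

  std::vector<double> train_loss;
  train_loss.reserve((size_t)n_epochs * nbatch);
  std::vector<double> val_loss(n_epochs), val_mse(n_epochs);
  Mat<eT> Yb(1, (size_t)batch_size * S, fill::zeros);
  std::vector<int> pkb(batch_size), nb(batch_size);

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    const double lr = (epoch <= lr_half_epoch) ? lr0 : lr0 / 2.0;
    shuffle_idx(idx, rng);
    for (int bi = 0; bi < nbatch; ++bi) {
      const int from = bi * batch_size;
      const int Bc = std::min(batch_size, ntr - from);
      gather(Xt, idx, from, Bc, S, PAD, N, net.X0);
      gather(Yt, idx, from, Bc, S, PAD, N, Yb);
      for (int s = 0; s < Bc; ++s) {
        pkb[s] = (int) pk_tr[idx[from + s]];
        nb[s]  = (int) n_tr[idx[from + s]];
      }
      const Mat<eT>& P = forward(net, Bc, true);
      Mat<eT>& dOut = net.L.back().dA;
      const double gmul = sum_objective ? (double)N : 1.0 / Bc;
      train_loss.push_back(batch_loss_grad(P, Yb, pkb.data(), nb.data(),
                                           alpha, Bc, S, PAD, N,
                                           gmul, &dOut));
      backward(net, Bc);
      for (auto& l : net.L) {
        l.vW = (eT)momentum * l.vW - (eT)lr * l.gW;  l.W += l.vW;
        l.vb = (eT)momentum * l.vb - (eT)lr * l.gb;  l.b += l.vb;
        if (l.bn) {
          l.vgamma = (eT)momentum * l.vgamma - (eT)lr * l.ggamma;  l.gamma += l.vgamma;
          l.vbeta  = (eT)momentum * l.vbeta  - (eT)lr * l.gbeta;   l.beta  += l.vbeta;
        }
      }
      Rcpp::checkUserInterrupt();
    }
    // end-of-epoch validation in inference mode
    double vl = 0.0, vm = 0.0;
    for (int from = 0; from < nval; from += batch_size) {
      const int Bc = std::min(batch_size, nval - from);
      gather(Xv, vidx, from, Bc, S, PAD, N, net.X0);
      gather(Yv, vidx, from, Bc, S, PAD, N, Yb);
      for (int s = 0; s < Bc; ++s) {
        pkb[s] = (int) pk_val[from + s];
        nb[s]  = (int) n_val[from + s];
      }
      const Mat<eT>& P = forward(net, Bc, false);
      vl += batch_loss_grad<eT>(P, Yb, pkb.data(), nb.data(), alpha, Bc, S,
                                PAD, N, 1.0, (Mat<eT>*)nullptr) * Bc;
      vm += batch_mse(P, Yb, Bc, S, PAD, N) * Bc;
    }
    val_loss[epoch - 1] = nval > 0 ? vl / nval : NA_REAL;
    val_mse[epoch - 1]  = nval > 0 ? vm / nval : NA_REAL;
  }

  return Rcpp::List::create(
    Rcpp::Named("layers") = store_layers(net, layers),
    Rcpp::Named("train_loss") = Rcpp::wrap(train_loss),
    Rcpp::Named("val_loss") = Rcpp::wrap(val_loss),
    Rcpp::Named("val_mse") = Rcpp::wrap(val_mse));
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(Rcpp::List layers, const arma::mat& X) {
  typedef double eT;
  const int N = X.n_rows, B = X.n_cols;
  const int chunk = std::min(B, 128);
  Net<eT> net;
  load_net(net, layers, N, chunk);
  const int S = net.S, PAD = net.PAD;
  arma::mat out(N, B);
  std::vector<int> idx(B);
  for (int i = 0; i < B; ++i) idx[i] = i;
  for (int from = 0; from < B; from += chunk) {
    const int Bc = std::min(chunk, B - from);
    gather(X, idx, from, Bc, S, PAD, N, net.X0);
    const Mat<eT>& P = forward(net, Bc, false);
    for (int s = 0; s < Bc; ++s)
      for (int i = 0; i < N; ++i)
        out(i, from + s) = P(0, (size_t)s * S + PAD + i);
  }
  return out;
}

// Double-precision loss + gradients for one batch with training-mode batch
// norm; used by the tests to check the backward pass against finite
// differences.
// [[Rcpp::export]]
Rcpp::List cpp_cnn_loss_grad(Rcpp::List layers,
                             const arma::mat& X, const arma::mat& Y,
                             const arma::ivec& pk, const arma::ivec& nwin,
                             double alpha, double grad_scale) {
  typedef double eT;
  const int N = X.n_rows, B = X.n_cols;
  Net<eT> net;
  load_net(net, layers, N, B);
  const int S = net.S, PAD = net.PAD;
  std::vector<int> idx(B), pkv(B), nv(B);
  for (int i = 0; i < B; ++i) idx[i] = i;
  for (int s = 0; s < B; ++s) { pkv[s] = (int) pk[s]; nv[s] = (int) nwin[s]; }
  gather(X, idx, 0, B, S, PAD, N, net.X0);
  Mat<eT> Yb(1, (size_t)B * S, fill::zeros);
  gather(Y, idx, 0, B, S, PAD, N, Yb);
  const Mat<eT>& P = forward(net, B, true);
  Mat<eT>& dOut = net.L.back().dA;
  double loss = batch_loss_grad(P, Yb, pkv.data(), nv.data(), alpha, B, S,
                                PAD, N, grad_scale / B, &dOut);
  backward(net, B);
  Rcpp::List grads(net.L.size());
  for (size_t li = 0; li < net.L.size(); ++li) {
    Layer<eT>& l = net.L[li];
    Rcpp::NumericVector gWr((size_t)l.k * l.Cin * l.Cout);
    gWr.attr("dim") = Rcpp::IntegerVector::create(l.k, l.Cin, l.Cout);
    for (int o = 0; o < l.Cout; ++o)
      for (int ci = 0; ci < l.Cin; ++ci)
        for (int t = 0; t < l.k; ++t)
          gWr[t + l.k * ci + (size_t)l.k * l.Cin * o] = l.gW(o, t * l.Cin + ci);
    Rcpp::List g = Rcpp::List::create(
      Rcpp::Named("W") = gWr,
      Rcpp::Named("b") = Rcpp::wrap(conv_to<arma::vec>::from(l.gb)));
    if (l.bn) {
      g["gamma"] = Rcpp::wrap(conv_to<arma::vec>::from(l.ggamma));
      g["beta"]  = Rcpp::wrap(conv_to<arma::vec>::from(l.gbeta));
    }
    grads[li] = g;
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}
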