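// Small convolutional network engine: 3x3 SAME convolutions + ReLU + 2x2
// max pooling blocks, flatten, inverted dropout, and a dense softmax head.
// im2col + BLAS GEMM keeps single-core training of desk-scale backbones
// inside the test-suite budget; no deep-learning framework is available in
// the target library. Dropout uses R's RNG so runs are seed-reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>

using namespace Rcpp;

// X rows are samples; each row holds C channels of a d x d image,
// channel-major, each channel in R column-major order.

struct ConvLayer {
  arma::fmat W;  // (C_in * 9) x C_out
  arma::fvec b;
};

static void im2col3(const arma::fmat& X, int n0, int n1, int C, int H,
                    arma::fmat& M) {
  // rows of M: (sample-local index) * H*W + output pixel (col-major);
  // cols: c * 9 + (ky * 3 + kx), zero padding of 1 on each side
  int HW = H * H;
  // stage each sample row contiguously: reading X row-wise is stride-N and
  // cache-hostile, and these loops dominate the batch cost otherwise
  arma::fvec buf(C * HW);
  for (int n = n0; n < n1; ++n) {
    for (int j = 0; j < C * HW; ++j) buf[j] = X(n, j);
    for (int c = 0; c < C; ++c) {
      for (int kx = 0; kx < 3; ++kx) {
        for (int ky = 0; ky < 3; ++ky) {
          int colM = c * 9 + ky * 3 + kx;
          float* dst = M.colptr(colM) + (n - n0) * HW;
          const float* srcb = buf.memptr() + c * HW;
          for (int x = 0; x < H; ++x) {
            int sx = x + kx - 1;
            if (sx < 0 || sx >= H) continue;
            int y0 = (ky == 0) ? 1 : 0;
            int y1 = (ky == 2) ? H - 1 : H;
            const float* s = srcb + sx * H + (y0 + ky - 1);
            float* t = dst + x * H + y0;
            for (int y = y0; y < y1; ++y) *t++ = *s++;
          }
        }
      }
    }
  }
}

static void col2im3(const arma::fmat& dM, int n0, int n1, int C, int H,
                    arma::fmat& dX) {
  int HW = H * H;
  arma::fvec buf(C * HW);
  for (int n = n0; n < n1; ++n) {
    buf.zeros();
    for (int c = 0; c < C; ++c) {
      for (int kx = 0; kx < 3; ++kx) {
        for (int ky = 0; ky < 3; ++ky) {
          int colM = c * 9 + ky * 3 + kx;
          const float* srcm = dM.colptr(colM) + (n - n0) * HW;
          float* dstb = buf.memptr() + c * HW;
          for (int x = 0; x < H; ++x) {
            int sx = x + kx - 1;
            if (sx < 0 || sx >= H) continue;
            int y0 = (ky == 0) ? 1 : 0;
            int y1 = (ky == 2) ? H - 1 : H;
            float* t = dstb + sx * H + (y0 + ky - 1);
            const float* s = srcm + x * H + y0;
            for (int y = y0; y < y1; ++y) *t++ += *s++;
          }
        }
      }
    }
    for (int j = 0; j < C * HW; ++j) dX(n, j) += buf[j];
  }
}

// 2x2 max pooling (stride 2); records argmax offsets for backward
static void pool2(const arma::fmat& A, int N, int K, int H, arma::fmat& P,
                  arma::umat& amax) {
  int Hp = H / 2, HW = H * H, HWp = Hp * Hp;
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < K; ++k) {
      for (int x = 0; x < Hp; ++x) {
        for (int y = 0; y < Hp; ++y) {
          float best = -1e30f; int bi = 0;
          for (int dx = 0; dx < 2; ++dx) {
            for (int dy = 0; dy < 2; ++dy) {
              int src = (2 * x + dx) * H + 2 * y + dy;
              float v = A(n * HW + src, k);
              if (v > best) { best = v; bi = src; }
            }
          }
          P(n * HWp + x * Hp + y, k) = best;
          amax(n * HWp + x * Hp + y, k) = bi;
        }
      }
    }
  }
}

static std::vector<ConvLayer> parse_conv(const List& conv_params) {
  std::vector<ConvLayer> layers;
  for (int i = 0; i < conv_params.size(); ++i) {
    List li = conv_params[i];
    ConvLayer cl;
    cl.W = arma::conv_to<arma::fmat>::from(as<arma::mat>(li["W"]));
    cl.b = arma::conv_to<arma::fvec>::from(as<arma::vec>(li["b"]));
    layers.push_back(cl);
  }
  return layers;
}

struct FwdState {
  std::vector<arma::fmat> cols;    // im2col inputs per conv layer
  std::vector<arma::fmat> preact;  // pre-pool post-relu activations
  std::vector<arma::umat> amax;
  arma::fmat flat;                 // flattened features (after dropout if any)
  arma::fmat dropmask;
};

static arma::fmat convnet_fwd(const std::vector<ConvLayer>& conv,
                              const arma::fmat& denseW, const arma::fvec& denseb,
                              const arma::fmat& X, int d, int C,
                              double dropout, bool training, FwdState* st) {
  int N = X.n_rows;
  arma::fmat cur = X;
  int H = d, Cin = C;
  for (size_t l = 0; l < conv.size(); ++l) {
    int K = conv[l].W.n_cols;
    int HW = H * H;
    arma::fmat M(N * HW, Cin * 9, arma::fill::zeros);
    im2col3(cur, 0, N, Cin, H, M);
    arma::fmat A = M * conv[l].W;
    A.each_row() += conv[l].b.t();
    A.transform([](float v) { return v > 0 ? v : 0.0f; });
    int Hp = H / 2;
    arma::fmat P(N * Hp * Hp, K, arma::fill::zeros);
    arma::umat am(N * Hp * Hp, K, arma::fill::zeros);
    pool2(A, N, K, H, P, am);
    // reshape pooled (N*HWp x K) into sample rows (N x K*HWp)
    arma::fmat nxt(N, K * Hp * Hp);
    for (int n = 0; n < N; ++n)
      for (int k = 0; k < K; ++k)
        for (int q = 0; q < Hp * Hp; ++q)
          nxt(n, k * Hp * Hp + q) = P(n * Hp * Hp + q, k);
    if (st) {
      st->cols.push_back(std::move(M));
      st->preact.push_back(std::move(A));
      st->amax.push_back(std::move(am));
    }
    cur = std::move(nxt);
    H = Hp;
    Cin = K;
  }
  if (training && dropout > 0) {
    // xorshift PRNG seeded from R's RNG: one R draw per batch keeps runs
    // seed-reproducible while avoiding 50k slow unif_rand() round trips
    uint64_t s = (uint64_t)(unif_rand() * 9007199254740992.0) | 1u;
    float inv = 1.0f / (1.0f - (float)dropout);
    double thr = dropout * 18446744073709551616.0;  // dropout * 2^64
    arma::fmat mask(cur.n_rows, cur.n_cols);
    for (arma::uword i = 0; i < mask.n_elem; ++i) {
      s ^= s << 13; s ^= s >> 7; s ^= s << 17;
      mask(i) = ((double)s >= thr) ? inv : 0.0f;
    }
    cur = cur % mask;
    if (st) st->dropmask = mask;
  }
  if (st) st->flat = cur;
  arma::fmat logits = cur * denseW;
  logits.each_row() += denseb.t();
  return logits;
}

// [[Rcpp::export]]
NumericMatrix cpp_convnet_logits(List conv_params, NumericMatrix denseW,
                                 NumericVector denseb, NumericMatrix X,
                                 int d, int C) {
  std::vector<ConvLayer> conv = parse_conv(conv_params);
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  arma::fmat Xa = arma::conv_to<arma::fmat>::from(Xd);
  arma::mat Wdd(denseW.begin(), denseW.nrow(), denseW.ncol(), false);
  arma::fmat Wd = arma::conv_to<arma::fmat>::from(Wdd);
  arma::vec bdd(denseb.begin(), denseb.size(), false);
  arma::fvec bd = arma::conv_to<arma::fvec>::from(bdd);
  arma::fmat logits = convnet_fwd(conv, Wd, bd, Xa, d, C, 0.0, false, nullptr);
  return wrap(arma::conv_to<arma::mat>::from(logits));
}

// [[Rcpp::export]]
List cpp_convnet_grad(List conv_params, NumericMatrix denseW,
                      NumericVector denseb, NumericMatrix X,
                      NumericMatrix Y, int d, int C, double dropout) {
  std::vector<ConvLayer> conv = parse_conv(conv_params);
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  arma::fmat Xa = arma::conv_to<arma::fmat>::from(Xd);
  arma::mat Yd(Y.begin(), Y.nrow(), Y.ncol(), false);
  arma::fmat Ya = arma::conv_to<arma::fmat>::from(Yd);
  arma::mat Wdd(denseW.begin(), denseW.nrow(), denseW.ncol(), false);
  arma::fmat Wd = arma::conv_to<arma::fmat>::from(Wdd);
  arma::vec bdd(denseb.begin(), denseb.size(), false);
  arma::fvec bd = arma::conv_to<arma::fvec>::from(bdd);
  int N = Xa.n_rows;
  FwdState st;
  arma::fmat logits = convnet_fwd(conv, Wd, bd, Xa, d, C, dropout, true, &st);
  // softmax cross-entropy
  arma::fvec mx = arma::max(logits, 1);
  arma::fmat P = arma::exp(logits.each_col() - mx);
  P.each_col() /= arma::sum(P, 1);
  double loss = -arma::accu(Ya % arma::log(arma::clamp(P, 1e-12f, 1.0f))) / N;
  arma::fmat dlogits = (P - Ya) / N;
  arma::fmat dDenseW = st.flat.t() * dlogits;
  arma::fvec dDenseb = arma::sum(dlogits, 0).t();
  arma::fmat dflat = dlogits * Wd.t();
  if (dropout > 0) dflat = dflat % st.dropmask;

  int L = conv.size();
  // geometry bookkeeping
  std::vector<int> Hs(L + 1), Cs(L + 1);
  Hs[0] = d; Cs[0] = C;
  for (int l = 0; l < L; ++l) {
    Hs[l + 1] = Hs[l] / 2;
    Cs[l + 1] = conv[l].W.n_cols;
  }
  List conv_grads(L);
  arma::fmat dcur = dflat;  // N x (K * HWp)
  for (int l = L - 1; l >= 0; --l) {
    int K = Cs[l + 1], Hp = Hs[l + 1], H = Hs[l], HWp = Hp * Hp, HW = H * H;
    // rows-per-sample layout back to pooled layout (N*HWp x K)
    arma::fmat dP(N * HWp, K, arma::fill::zeros);
    for (int n = 0; n < N; ++n)
      for (int k = 0; k < K; ++k)
        for (int q = 0; q < HWp; ++q)
          dP(n * HWp + q, k) = dcur(n, k * HWp + q);
    // pool backward
    arma::fmat dA(N * HW, K, arma::fill::zeros);
    for (int n = 0; n < N; ++n)
      for (int k = 0; k < K; ++k)
        for (int q = 0; q < HWp; ++q)
          dA(n * HW + st.amax[l](n * HWp + q, k), k) += dP(n * HWp + q, k);
    // relu backward
    dA.elem(arma::find(st.preact[l] <= 0)).zeros();
    arma::fmat dWl = st.cols[l].t() * dA;
    arma::fvec dbl = arma::sum(dA, 0).t();
    conv_grads[l] = List::create(
      Named("W") = wrap(arma::conv_to<arma::mat>::from(dWl)),
      Named("b") = wrap(arma::conv_to<arma::vec>::from(dbl)));
    if (l > 0) {
      arma::fmat dM = dA * conv[l].W.t();
      arma::fmat dX(N, Cs[l] * HW, arma::fill::zeros);
      col2im3(dM, 0, N, Cs[l], H, dX);
      dcur = dX;
    }
  }
  return List::create(Named("loss") = loss,
                      Named("conv") = conv_grads,
                      Named("dense") = List::create(
                        Named("W") = wrap(arma::conv_to<arma::mat>::from(dDenseW)),
                        Named("b") = wrap(arma::conv_to<arma::vec>::from(dDenseb))));
}
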