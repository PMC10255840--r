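// Dual-branch convolutional network: two identical stacks of 3x3
// valid-padding convolutions with ReLU and 2x2 max pooling, one per input
// map (range-time and Doppler-time), concatenated and fed to a linear
// softmax classifier.  Forward/backward passes are expressed as im2col +
// GEMM so the heavy lifting runs in BLAS; training uses Adam with a step
// learning-rate decay.  All randomness (init, shuffling) flows from one
// integer seed through a private generator so runs are reproducible.
//
// Activations live in a flat layout: an (H*W*bs) x C matrix whose rows
// are column-major pixels, sample blocks stacked vertically.  im2col and
// pooling then reduce to contiguous memcpy/strided loops and the GEMMs
// span the whole minibatch.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
#include <random>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

namespace {

const int N_CONV = 4;
const int CIN[N_CONV] = {3, 16, 32, 64};
const int COUT[N_CONV] = {16, 32, 64, 128};
// pooling follows conv layers 0..2; conv 3 feeds the flatten directly
const bool POOLED[N_CONV] = {true, true, true, false};
const int N_CLASS = 5;

struct Dims {
  int S;
  int conv_hw[N_CONV];  // spatial size after each conv
  int out_hw[N_CONV];   // spatial size after optional pool
  int flat, merged;
};

Dims make_dims(int S) {
  Dims d;
  d.S = S;
  int s = S;
  for (int l = 0; l < N_CONV; ++l) {
    s -= 2;
    if (s < 1)
      stop("network dimensions collapse at convolution layer %d (size %d)",
           l + 1, s);
    d.conv_hw[l] = s;
    if (POOLED[l]) {
      if (s % 2 != 0)
        stop("max-pool layer %d needs an even input size, got %d", l + 1, s);
      s /= 2;
    }
    d.out_hw[l] = s;
  }
  d.flat = COUT[N_CONV - 1] * s * s;
  d.merged = 2 * d.flat;
  return d;
}

// seeded RNG with explicit algorithms so results do not depend on the
// standard library's distribution implementations
struct Rng {
  std::mt19937 gen;
  explicit Rng(unsigned int seed) : gen(seed) {}
  double runif01() { return (static_cast<double>(gen()) + 0.5) / 4294967296.0; }
  double rnorm() {  // Box-Muller
    double u1 = runif01(), u2 = runif01();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int below(int n) { return static_cast<int>(gen() % static_cast<unsigned>(n)); }
};

struct Net {
  Dims dims;
  std::vector<fmat> W[2];  // [branch][layer], (9*Cin) x Cout
  std::vector<fvec> b[2];
  fmat fcW;                // merged x N_CLASS
  fvec fcb;
};

Net net_from_list(const List& wl, int S) {
  Net net;
  net.dims = make_dims(S);
  const char* br[2] = {"rt", "dt"};
  for (int g = 0; g < 2; ++g)
    for (int l = 0; l < N_CONV; ++l) {
      std::string wn = std::string(br[g]) + "_W" + std::to_string(l + 1);
      std::string bn = std::string(br[g]) + "_b" + std::to_string(l + 1);
      mat Wd = Rcpp::as<mat>(wl[wn]);
      vec bd = Rcpp::as<vec>(wl[bn]);
      if ((int)Wd.n_rows != 9 * CIN[l] || (int)Wd.n_cols != COUT[l])
        stop("weight %s has shape %dx%d, expected %dx%d", wn.c_str(),
             (int)Wd.n_rows, (int)Wd.n_cols, 9 * CIN[l], COUT[l]);
      net.W[g].push_back(conv_to<fmat>::from(Wd));
      net.b[g].push_back(conv_to<fvec>::from(bd));
    }
  mat fw = Rcpp::as<mat>(wl["fc_W"]);
  if ((int)fw.n_rows != net.dims.merged || (int)fw.n_cols != N_CLASS)
    stop("fc_W has shape %dx%d, expected %dx%d", (int)fw.n_rows,
         (int)fw.n_cols, net.dims.merged, N_CLASS);
  net.fcW = conv_to<fmat>::from(fw);
  net.fcb = conv_to<fvec>::from(Rcpp::as<vec>(wl["fc_b"]));
  return net;
}

List net_to_list(const Net& net) {
  List out;
  const char* br[2] = {"rt", "dt"};
  for (int g = 0; g < 2; ++g)
    for (int l = 0; l < N_CONV; ++l) {
      out[std::string(br[g]) + "_W" + std::to_string(l + 1)] =
          Rcpp::wrap(conv_to<mat>::from(net.W[g][l]));
      out[std::string(br[g]) + "_b" + std::to_string(l + 1)] =
          Rcpp::wrap(conv_to<vec>::from(net.b[g][l]));
    }
  out["fc_W"] = Rcpp::wrap(conv_to<mat>::from(net.fcW));
  out["fc_b"] = Rcpp::wrap(conv_to<vec>::from(net.fcb));
  return out;
}

// gather minibatch samples from the (S, S, 3, N) double array into the
// flat layout: (S*S*bs) x 3, sample blocks stacked vertically
void gather_input(const double* x, int S, const std::vector<int>& idx,
                  fmat& A) {
  int P = S * S, bs = idx.size();
  A.set_size(static_cast<uword>(P) * bs, 3);
  for (int c = 0; c < 3; ++c) {
    float* dst = A.colptr(c);
    for (int s = 0; s < bs; ++s) {
      const double* src = x + (static_cast<size_t>(idx[s]) * 3 + c) * P;
      float* d = dst + static_cast<size_t>(s) * P;
      for (int i = 0; i < P; ++i) d[i] = static_cast<float>(src[i]);
    }
  }
}

// im2col in the flat layout: A is (Hi*Wi*bs) x Cin, cols (Ho*Wo*bs) x 9*Cin
void im2col_flat(const fmat& A, int Hi, int Wi, int bs, fmat& cols) {
  int Ho = Hi - 2, Wo = Wi - 2, Cin = A.n_cols;
  cols.set_size(static_cast<uword>(Ho) * Wo * bs, 9 * Cin);
  for (int c = 0; c < Cin; ++c) {
    const float* src = A.colptr(c);
    for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di) {
        float* dst = cols.colptr(c * 9 + dj * 3 + di);
        for (int s = 0; s < bs; ++s)
          for (int j = 0; j < Wo; ++j)
            std::memcpy(dst + (static_cast<size_t>(s) * Wo + j) * Ho,
                        src + static_cast<size_t>(s) * Hi * Wi +
                            (j + dj) * Hi + di,
                        sizeof(float) * Ho);
      }
  }
}

// accumulate column gradients back onto the input layout
void col2im_flat(const fmat& dcols, int Hi, int Wi, int bs, fmat& dA) {
  int Ho = Hi - 2, Wo = Wi - 2, Cin = dA.n_cols;
  dA.zeros();
  for (int c = 0; c < Cin; ++c) {
    float* dst = dA.colptr(c);
    for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di) {
        const float* src = dcols.colptr(c * 9 + dj * 3 + di);
        for (int s = 0; s < bs; ++s)
          for (int j = 0; j < Wo; ++j) {
            float* d = dst + static_cast<size_t>(s) * Hi * Wi +
                       (j + dj) * Hi + di;
            const float* sr = src + (static_cast<size_t>(s) * Wo + j) * Ho;
            for (int i = 0; i < Ho; ++i) d[i] += sr[i];
          }
      }
  }
}

void pool_flat(const fmat& Z, int Ho, int Wo, int bs, fmat& A,
               Mat<uword>& pidx) {
  int Hp = Ho / 2, Wp = Wo / 2, C = Z.n_cols;
  A.set_size(static_cast<uword>(Hp) * Wp * bs, C);
  pidx.set_size(A.n_rows, C);
  for (int c = 0; c < C; ++c) {
    const float* src = Z.colptr(c);
    float* dst = A.colptr(c);
    uword* pd = pidx.colptr(c);
    for (int s = 0; s < bs; ++s) {
      const float* sb = src + static_cast<size_t>(s) * Ho * Wo;
      size_t ob = static_cast<size_t>(s) * Hp * Wp;
      for (int j = 0; j < Wp; ++j)
        for (int i = 0; i < Hp; ++i) {
          size_t base = static_cast<size_t>(2 * j) * Ho + 2 * i;
          size_t cand[4] = {base, base + 1, base + Ho, base + Ho + 1};
          float m = sb[cand[0]];
          int a = 0;
          for (int q = 1; q < 4; ++q)
            if (sb[cand[q]] > m) { m = sb[cand[q]]; a = q; }
          dst[ob + j * Hp + i] = m;
          pd[ob + j * Hp + i] = static_cast<size_t>(s) * Ho * Wo + cand[a];
        }
    }
  }
}

void pool_back(const fmat& dA, const Mat<uword>& pidx, int Ho, int Wo,
               int bs, fmat& dZ) {
  dZ.zeros(static_cast<uword>(Ho) * Wo * bs, dA.n_cols);
  for (uword c = 0; c < dA.n_cols; ++c) {
    float* dst = dZ.colptr(c);
    const float* src = dA.colptr(c);
    const uword* pi = pidx.colptr(c);
    for (uword r = 0; r < dA.n_rows; ++r) dst[pi[r]] += src[r];
  }
}

struct BranchCache {
  std::vector<fmat> cols;         // per layer
  std::vector<fmat> z;            // post-ReLU conv outputs
  std::vector<Mat<uword>> pidx;   // pool argmax (input-layout rows)
};

// forward a minibatch through one branch; A0 is the flat input layout;
// returns the flatten matrix (flat x bs)
fmat branch_forward(const Net& net, int g, const fmat& A0, int bs,
                    BranchCache* cache) {
  const Dims& d = net.dims;
  if (cache) {
    cache->cols.resize(N_CONV);
    cache->z.resize(N_CONV);
    cache->pidx.resize(N_CONV);
  }
  fmat A = A0, cols, Z;
  int Hi = d.S;
  for (int l = 0; l < N_CONV; ++l) {
    fmat& C = cache ? cache->cols[l] : cols;
    im2col_flat(A, Hi, Hi, bs, C);
    fmat& Zl = cache ? cache->z[l] : Z;
    Zl = C * net.W[g][l];
    Zl.each_row() += net.b[g][l].t();
    Zl.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    int Ho = d.conv_hw[l];
    if (POOLED[l]) {
      Mat<uword> tmp_idx;
      pool_flat(Zl, Ho, Ho, bs, A, cache ? cache->pidx[l] : tmp_idx);
    } else {
      A = Zl;
    }
    Hi = d.out_hw[l];
  }
  // flatten: per-sample block of A (rows) in (pixel, channel) order
  int P = Hi * Hi, C = COUT[N_CONV - 1];
  fmat feat(d.flat, bs);
  for (int s = 0; s < bs; ++s)
    for (int c = 0; c < C; ++c)
      std::memcpy(feat.colptr(s) + c * P,
                  A.colptr(c) + static_cast<size_t>(s) * P,
                  sizeof(float) * P);
  return feat;
}

struct BranchGrads {
  std::vector<fmat> W;
  std::vector<fvec> b;
};

void branch_backward(const Net& net, int g, const fmat& A0, int bs,
                     const BranchCache& cache, const fmat& dfeat,
                     BranchGrads& grads) {
  const Dims& d = net.dims;
  int Hl = d.out_hw[N_CONV - 1], P = Hl * Hl, C = COUT[N_CONV - 1];
  fmat dA(static_cast<uword>(P) * bs, C);
  for (int s = 0; s < bs; ++s)
    for (int c = 0; c < C; ++c)
      std::memcpy(dA.colptr(c) + static_cast<size_t>(s) * P,
                  dfeat.colptr(s) + c * P, sizeof(float) * P);
  for (int l = N_CONV - 1; l >= 0; --l) {
    int Ho = d.conv_hw[l];
    fmat dZ;
    if (POOLED[l])
      pool_back(dA, cache.pidx[l], Ho, Ho, bs, dZ);
    else
      dZ = dA;
    {  // ReLU gate
      const float* zp = cache.z[l].memptr();
      float* dp = dZ.memptr();
      for (uword i = 0; i < dZ.n_elem; ++i)
        if (zp[i] <= 0.0f) dp[i] = 0.0f;
    }
    grads.W[l] += cache.cols[l].t() * dZ;
    grads.b[l] += sum(dZ, 0).t();
    if (l > 0) {
      fmat dcols = dZ * net.W[g][l].t();
      int Hi = d.out_hw[l - 1];
      dA.set_size(static_cast<uword>(Hi) * Hi * bs, CIN[l]);
      col2im_flat(dcols, Hi, Hi, bs, dA);
    }
  }
}

fmat softmax_cols(fmat z) {
  for (uword j = 0; j < z.n_cols; ++j) {
    fvec c = z.col(j);
    c -= c.max();
    c = exp(c);
    z.col(j) = c / accu(c);
  }
  return z;
}

fmat forward_probs(const Net& net, const double* xrt, const double* xdt,
                   const std::vector<int>& idx) {
  int bs = idx.size();
  fmat Art, Adt;
  gather_input(xrt, net.dims.S, idx, Art);
  gather_input(xdt, net.dims.S, idx, Adt);
  fmat feat = join_cols(branch_forward(net, 0, Art, bs, nullptr),
                        branch_forward(net, 1, Adt, bs, nullptr));
  fmat logits = net.fcW.t() * feat;
  logits.each_col() += net.fcb;
  return softmax_cols(logits);
}

}  // namespace

// [[Rcpp::export(name = ".cnn_dims")]]
List cnn_dims_cpp(int input_size) {
  Dims d = make_dims(input_size);
  Rcpp::IntegerVector conv(N_CONV), outs(N_CONV);
  for (int l = 0; l < N_CONV; ++l) {
    conv[l] = d.conv_hw[l];
    outs[l] = d.out_hw[l];
  }
  return List::create(Named("conv_size") = conv, Named("pooled_size") = outs,
                      Named("flatten") = d.flat, Named("merged") = d.merged);
}

// [[Rcpp::export(name = ".cnn_init")]]
List cnn_init_cpp(int seed, int input_size) {
  Dims d = make_dims(input_size);
  Rng rng(static_cast<unsigned>(seed));
  Net net;
  net.dims = d;
  for (int g = 0; g < 2; ++g)
    for (int l = 0; l < N_CONV; ++l) {
      int K = 9 * CIN[l];
      fmat W(K, COUT[l]);
      double sd = std::sqrt(2.0 / K);  // He initialisation for ReLU stacks
      for (uword i = 0; i < W.n_elem; ++i)
        W(i) = static_cast<float>(sd * rng.rnorm());
      net.W[g].push_back(W);
      net.b[g].push_back(zeros<fvec>(COUT[l]));
    }
  net.fcW.set_size(d.merged, N_CLASS);
  double sd = std::sqrt(1.0 / d.merged);
  for (uword i = 0; i < net.fcW.n_elem; ++i)
    net.fcW(i) = static_cast<float>(sd * rng.rnorm());
  net.fcb = zeros<fvec>(N_CLASS);
  return net_to_list(net);
}

// [[Rcpp::export(name = ".cnn_forward")]]
Rcpp::NumericMatrix cnn_forward_cpp(List weights, Rcpp::NumericVector xrt,
                                    Rcpp::NumericVector xdt, int input_size) {
  Net net = net_from_list(weights, input_size);
  Rcpp::IntegerVector dim = xrt.attr("dim");
  int S = dim[0], N = dim[3];
  if (S != input_size)
    stop("image size %d does not match network input %d", S, input_size);
  Rcpp::NumericMatrix probs(N, N_CLASS);
  const int CHUNK = 64;
  for (int at = 0; at < N; at += CHUNK) {
    int bs = std::min(CHUNK, N - at);
    std::vector<int> idx(bs);
    for (int s = 0; s < bs; ++s) idx[s] = at + s;
    fmat p = forward_probs(net, xrt.begin(), xdt.begin(), idx);
    for (int s = 0; s < bs; ++s)
      for (int c = 0; c < N_CLASS; ++c) probs(at + s, c) = p(c, s);
  }
  return probs;
}

// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train_cpp(List weights, Rcpp::NumericVector xrt,
                   Rcpp::NumericVector xdt, Rcpp::IntegerVector y,
                   Rcpp::NumericVector vrt, Rcpp::NumericVector vdt,
                   Rcpp::IntegerVector yv, List opts) {
  double lr = Rcpp::as<double>(opts["learning_rate"]);
  int epochs = Rcpp::as<int>(opts["epochs"]);
  int batch = Rcpp::as<int>(opts["batch_size"]);
  int step_size = Rcpp::as<int>(opts["step_size"]);
  double gamma = Rcpp::as<double>(opts["gamma"]);
  int seed = Rcpp::as<int>(opts["seed"]);
  int input_size = Rcpp::as<int>(opts["input_size"]);

  Net net = net_from_list(weights, input_size);
  Rcpp::IntegerVector dim = xrt.attr("dim");
  int S = dim[0], N = dim[3];
  int Nv = yv.size();
  if (N != y.size())
    stop("label count %d does not match sample count %d", (int)y.size(), N);
  if (N < 1) stop("empty training split");
  if (S != input_size)
    stop("image size %d does not match network input %d", S, input_size);

  Rng rng(static_cast<unsigned>(seed));

  // Adam state, one entry per weight matrix / bias vector
  std::vector<fmat*> parW;
  std::vector<fvec*> parb;
  for (int g = 0; g < 2; ++g)
    for (int l = 0; l < N_CONV; ++l) {
      parW.push_back(&net.W[g][l]);
      parb.push_back(&net.b[g][l]);
    }
  parW.push_back(&net.fcW);
  parb.push_back(&net.fcb);
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
  for (auto* p : parW) {
    mW.push_back(zeros<fmat>(size(*p)));
    vW.push_back(zeros<fmat>(size(*p)));
  }
  for (auto* p : parb) {
    mb.push_back(zeros<fvec>(size(*p)));
    vb.push_back(zeros<fvec>(size(*p)));
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t_adam = 0;

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  Rcpp::NumericVector h_tl(epochs), h_ta(epochs), h_vl(epochs), h_va(epochs);
  BranchCache crt, cdt;
  BranchGrads grt, gdt;
  for (int l = 0; l < N_CONV; ++l) {
    grt.W.push_back(zeros<fmat>(size(net.W[0][l])));
    grt.b.push_back(zeros<fvec>(size(net.b[0][l])));
    gdt.W.push_back(zeros<fmat>(size(net.W[1][l])));
    gdt.b.push_back(zeros<fvec>(size(net.b[1][l])));
  }

  for (int ep = 0; ep < epochs; ++ep) {
    double lr_ep = lr * std::pow(gamma, ep / step_size);
    for (int i = N - 1; i > 0; --i)  // Fisher-Yates
      std::swap(order[i], order[rng.below(i + 1)]);
    double loss_sum = 0.0;
    int correct = 0;
    for (int at = 0; at < N; at += batch) {
      int bs = std::min(batch, N - at);
      std::vector<int> idx(order.begin() + at, order.begin() + at + bs);
      fmat Art, Adt;
      gather_input(xrt.begin(), S, idx, Art);
      gather_input(xdt.begin(), S, idx, Adt);
      fmat frt = branch_forward(net, 0, Art, bs, &crt);
      fmat fdt = branch_forward(net, 1, Adt, bs, &cdt);
      fmat feat = join_cols(frt, fdt);
      fmat logits = net.fcW.t() * feat;
      logits.each_col() += net.fcb;
      fmat p = softmax_cols(logits);
      for (int s = 0; s < bs; ++s) {
        int lab = y[idx[s]];
        loss_sum += -std::log(std::max(p(lab, s), 1e-12f));
        uword am;
        p.col(s).max(am);
        if ((int)am == lab) ++correct;
      }
      fmat dlog = p;
      for (int s = 0; s < bs; ++s) dlog(y[idx[s]], s) -= 1.0f;
      dlog /= static_cast<float>(bs);
      for (int l = 0; l < N_CONV; ++l) {
        grt.W[l].zeros(); grt.b[l].zeros();
        gdt.W[l].zeros(); gdt.b[l].zeros();
      }
      fmat gfcW = feat * dlog.t();
      fvec gfcb = sum(dlog, 1);
      fmat dfeat = net.fcW * dlog;
      branch_backward(net, 0, Art, bs, crt,
                      dfeat.rows(0, net.dims.flat - 1), grt);
      branch_backward(net, 1, Adt, bs, cdt,
                      dfeat.rows(net.dims.flat, net.dims.merged - 1), gdt);
      // Adam update
      ++t_adam;
      double bc1 = 1.0 - std::pow(b1, t_adam);
      double bc2 = 1.0 - std::pow(b2, t_adam);
      std::vector<fmat*> gW;
      std::vector<fvec*> gb;
      for (int l = 0; l < N_CONV; ++l) { gW.push_back(&grt.W[l]); gb.push_back(&grt.b[l]); }
      for (int l = 0; l < N_CONV; ++l) { gW.push_back(&gdt.W[l]); gb.push_back(&gdt.b[l]); }
      gW.push_back(&gfcW);
      gb.push_back(&gfcb);
      for (size_t k = 0; k < parW.size(); ++k) {
        mW[k] = (float)b1 * mW[k] + (float)(1 - b1) * (*gW[k]);
        vW[k] = (float)b2 * vW[k] + (float)(1 - b2) * square(*gW[k]);
        *parW[k] -= (float)(lr_ep / bc1) * mW[k] /
                    (sqrt(vW[k] / (float)bc2) + (float)eps);
        mb[k] = (float)b1 * mb[k] + (float)(1 - b1) * (*gb[k]);
        vb[k] = (float)b2 * vb[k] + (float)(1 - b2) * square(*gb[k]);
        *parb[k] -= (float)(lr_ep / bc1) * mb[k] /
                    (sqrt(vb[k] / (float)bc2) + (float)eps);
      }
    }
    h_tl[ep] = loss_sum / N;
    h_ta[ep] = static_cast<double>(correct) / N;
    if (Nv > 0) {
      double vloss = 0.0;
      int vcorrect = 0;
      const int CHUNK = 64;
      for (int at = 0; at < Nv; at += CHUNK) {
        int bs = std::min(CHUNK, Nv - at);
        std::vector<int> idx(bs);
        for (int s = 0; s < bs; ++s) idx[s] = at + s;
        fmat p = forward_probs(net, vrt.begin(), vdt.begin(), idx);
        for (int s = 0; s < bs; ++s) {
          vloss += -std::log(std::max(p(yv[at + s], s), 1e-12f));
          uword am;
          p.col(s).max(am);
          if ((int)am == yv[at + s]) ++vcorrect;
        }
      }
      h_vl[ep] = vloss / Nv;
      h_va[ep] = static_cast<double>(vcorrect) / Nv;
    } else {
      h_vl[ep] = NA_REAL;
      h_va[ep] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(Named("weights") = net_to_list(net),
                      Named("train_loss") = h_tl,
                      Named("train_accuracy") = h_ta,
                      Named("val_loss") = h_vl,
                      Named("val_accuracy") = h_va);
}
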