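// Fused single-precision forward/backward for one CNN branch
// (three blocks of 3x3 same-padding conv + ReLU + 2x2 max pool).
// Single precision is used for the convolutional arithmetic (standard
// practice for CNN training); parameters, inputs and returned gradients
// stay double on the R side. All large buffers (im2col matrices,
// activations, gradient scratch) live in a reusable workspace handle so
// a training loop allocates them once instead of per batch. The slower
// double-precision kernels in conv_ops.cpp serve as independent oracles
// in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Layer {
  arma::fmat M;              // im2col of the layer input
  arma::fmat A;              // post-ReLU activations (N*H*W x Co)
  std::vector<float> pooled; // pool output (N,Ho,Wo,Co)
  std::vector<int> idx;      // pool argmax (h + H*w) per pooled element
  std::vector<float> da;     // backward scratch: activation grads
  arma::fmat dM;             // backward scratch: im2col grads
  int H, W, Ci, Co;
};

struct Workspace {
  int N = -1;
  Layer L[3];
  std::vector<float> g;      // backward scratch: pooled-output grads
};

// [[Rcpp::export(name = ".branch_ws_new")]]
SEXP branch_ws_new() {
  return XPtr<Workspace>(new Workspace());
}

template <typename T>
static void im2col_batch_f(const T* x, int N, int H, int W, int Ci,
                           arma::fmat& M) {
  const int k = 3, pad = 1;
  const size_t NH = (size_t)N * H;
  int q = 0;
  for (int ci = 0; ci < Ci; ++ci) {
    const T* xc = x + (size_t)N * H * W * ci;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh, ++q) {
        float* col = M.colptr(q);
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - pad;
          float* dst = col + NH * w;
          if (ws < 0 || ws >= W) {
            std::fill(dst, dst + NH, 0.0f);
            continue;
          }
          const T* src = xc + NH * ws;
          const int h0 = std::max(0, pad - kh);
          const int h1 = std::min(H, H + pad - kh);
          if (h0 > 0) std::fill(dst, dst + (size_t)N * h0, 0.0f);
          if (h1 < H) std::fill(dst + (size_t)N * h1, dst + NH, 0.0f);
          const T* s = src + (size_t)N * (h0 + kh - pad);
          float* d = dst + (size_t)N * h0;
          const size_t len = (size_t)N * (size_t)std::max(0, h1 - h0);
          for (size_t i = 0; i < len; ++i) d[i] = (float)s[i];
        }
      }
    }
  }
}

static arma::fmat weights_f(const NumericVector& w, int rows, int cols) {
  arma::fmat Wf(rows, cols);
  const double* p = w.begin();
  float* q = Wf.memptr();
  for (size_t i = 0; i < (size_t)rows * cols; ++i) q[i] = (float)p[i];
  return Wf;
}

static void pool2_f(const float* x, int N, int H, int W, int C,
                    float* out, int* idx) {
  const int Ho = H / 2, Wo = W / 2;
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t ob =
          (size_t)N * (ho + (size_t)Ho * (wo + (size_t)Wo * c));
        const float* cand[4];
        int candi[4];
        int m = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const int h = 2 * ho + dh, w = 2 * wo + dw;
            cand[m] = x + (size_t)N * (h + (size_t)H * (w + (size_t)W * c));
            candi[m] = h + H * w;
            ++m;
          }
        for (int n = 0; n < N; ++n) {
          float best = cand[0][n]; int bi = candi[0];
          for (int j = 1; j < 4; ++j)
            if (cand[j][n] > best) { best = cand[j][n]; bi = candi[j]; }
          out[ob + n] = best;
          idx[ob + n] = bi;
        }
      }
}

// x: (N,H,W,C0) double array. Returns the pooled branch output and the
// conv3 activations as double arrays; all intermediates stay in ws for
// the paired backward call.
// [[Rcpp::export(name = ".branch_fwd")]]
List branch_fwd(NumericVector x, List weights, List biases, SEXP ws_ptr,
                bool want_a3 = false) {
  XPtr<Workspace> ws(ws_ptr);
  IntegerVector xd = x.attr("dim");
  const int N = xd[0];
  int H = xd[1], W = xd[2], Ci = xd[3];
  ws->N = N;
  NumericVector a3_out;
  for (int l = 0; l < 3; ++l) {
    NumericVector w = weights[l];
    NumericVector b = biases[l];
    IntegerVector wd = w.attr("dim");
    const int Co = wd[3];
    Layer& L = ws->L[l];
    L.H = H; L.W = W; L.Ci = Ci; L.Co = Co;
    const size_t R = (size_t)N * H * W;
    if (L.M.n_rows != R || L.M.n_cols != (size_t)(9 * Ci)) {
      L.M.set_size(R, 9 * Ci);
    }
    if (l == 0) {
      im2col_batch_f(x.begin(), N, H, W, Ci, L.M);
    } else {
      im2col_batch_f(ws->L[l - 1].pooled.data(), N, H, W, Ci, L.M);
    }
    arma::fmat Wf = weights_f(w, 9 * Ci, Co);
    if (L.A.n_rows != R || L.A.n_cols != (size_t)Co) L.A.set_size(R, Co);
    L.A = L.M * Wf;
    for (int c = 0; c < Co; ++c) {
      const float bc = (float)b[c];
      float* ac = L.A.colptr(c);
      for (size_t r = 0; r < R; ++r) {
        const float v = ac[r] + bc;
        ac[r] = v > 0.0f ? v : 0.0f;
      }
    }
    if (l == 2 && want_a3) {
      a3_out = NumericVector((R_xlen_t)(R * Co));
      a3_out.attr("dim") = IntegerVector::create(N, H, W, Co);
      double* p = a3_out.begin();
      const float* a = L.A.memptr();
      for (size_t i = 0; i < R * Co; ++i) p[i] = a[i];
    }
    const int Ho = H / 2, Wo = W / 2;
    const size_t P = (size_t)N * Ho * Wo * Co;
    L.pooled.resize(P);
    L.idx.resize(P);
    pool2_f(L.A.memptr(), N, H, W, Co, L.pooled.data(), L.idx.data());
    H = Ho; W = Wo; Ci = Co;
  }
  NumericVector out((R_xlen_t)ws->L[2].pooled.size());
  out.attr("dim") = IntegerVector::create(N, H, W, Ci);
  {
    double* p = out.begin();
    const float* s = ws->L[2].pooled.data();
    for (size_t i = 0; i < ws->L[2].pooled.size(); ++i) p[i] = s[i];
  }
  return List::create(_["out"] = out, _["a3"] = a3_out);
}

// dout: gradient w.r.t. the pooled branch output (double). Returns conv
// weight/bias gradients and the gradient w.r.t. the conv3 activations
// (for Grad-CAM). Must follow a .branch_fwd call on the same workspace.
// [[Rcpp::export(name = ".branch_bwd")]]
List branch_bwd(SEXP ws_ptr, List weights, NumericVector dout,
                bool want_da3 = false) {
  XPtr<Workspace> ws(ws_ptr);
  const int N = ws->N;
  if (N < 0) stop("workspace holds no forward pass");
  List dws(3), dbs(3);
  NumericVector da3_out;
  ws->g.resize(dout.size());
  for (R_xlen_t i = 0; i < dout.size(); ++i) ws->g[i] = (float)dout[i];
  for (int l = 2; l >= 0; --l) {
    Layer& L = ws->L[l];
    const size_t R = (size_t)N * L.H * L.W;
    // pool backward: scatter pooled grads to activation positions
    L.da.assign(R * L.Co, 0.0f);
    {
      const int Ho = L.H / 2, Wo = L.W / 2;
      for (int c = 0; c < L.Co; ++c) {
        float* dac = L.da.data() + (size_t)N * L.H * L.W * c;
        const size_t cb = (size_t)N * Ho * Wo * c;
        for (size_t j = 0; j < (size_t)Ho * Wo; ++j) {
          const size_t o = cb + (size_t)N * j;
          for (int n = 0; n < N; ++n) {
            dac[(size_t)n + (size_t)N * L.idx[o + n]] += ws->g[o + n];
          }
        }
      }
    }
    if (l == 2 && want_da3) {
      da3_out = NumericVector((R_xlen_t)L.da.size());
      da3_out.attr("dim") = IntegerVector::create(N, L.H, L.W, L.Co);
      double* p = da3_out.begin();
      for (size_t i = 0; i < L.da.size(); ++i) p[i] = L.da[i];
    }
    // ReLU mask
    {
      const float* a = L.A.memptr();
      for (size_t i = 0; i < L.da.size(); ++i) {
        if (a[i] <= 0.0f) L.da[i] = 0.0f;
      }
    }
    arma::fmat G(L.da.data(), R, L.Co, false, true);
    arma::fmat dW = L.M.t() * G;
    arma::frowvec db = arma::sum(G, 0);
    NumericVector w = weights[l];
    NumericVector dwv(w.size());
    dwv.attr("dim") = w.attr("dim");
    for (size_t i = 0; i < (size_t)dW.n_elem; ++i) dwv[i] = dW.memptr()[i];
    NumericVector dbv(L.Co);
    for (int c = 0; c < L.Co; ++c) dbv[c] = db[c];
    dws[l] = dwv; dbs[l] = dbv;
    if (l > 0) {
      // input gradient via col2im of G * W^T; becomes the pooled-output
      // gradient of the layer below
      arma::fmat Wf = weights_f(w, 9 * L.Ci, L.Co);
      if (L.dM.n_rows != R || L.dM.n_cols != (size_t)(9 * L.Ci)) {
        L.dM.set_size(R, 9 * L.Ci);
      }
      L.dM = G * Wf.t();
      ws->g.assign((size_t)N * L.H * L.W * L.Ci, 0.0f);
      const size_t NH = (size_t)N * L.H;
      int q = 0;
      for (int ci = 0; ci < L.Ci; ++ci) {
        float* dxc = ws->g.data() + (size_t)N * L.H * L.W * ci;
        for (int kw = 0; kw < 3; ++kw) {
          for (int kh = 0; kh < 3; ++kh, ++q) {
            const float* col = L.dM.colptr(q);
            for (int w_ = 0; w_ < L.W; ++w_) {
              const int wsrc = w_ + kw - 1;
              if (wsrc < 0 || wsrc >= L.W) continue;
              const int h0 = std::max(0, 1 - kh);
              const int h1 = std::min(L.H, L.H + 1 - kh);
              if (h1 <= h0) continue;
              float* dst = dxc + NH * wsrc + (size_t)N * (h0 + kh - 1);
              const float* src = col + NH * w_ + (size_t)N * h0;
              const size_t len = (size_t)N * (h1 - h0);
              for (size_t i = 0; i < len; ++i) dst[i] += src[i];
            }
          }
        }
      }
    }
  }
  return List::create(_["dw1"] = dws[0], _["db1"] = dbs[0],
                      _["dw2"] = dws[1], _["db2"] = dbs[1],
                      _["dw3"] = dws[2], _["db3"] = dbs[2],
                      _["da3"] = da3_out);
}
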