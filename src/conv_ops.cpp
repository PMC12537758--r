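// Minimal convolution / pooling kernels for the dual-branch fusion
// network. Layout convention matches R arrays: column-major with dims
// (N, H, W, C) -- sample index fastest. Convolutions are odd-kernel,
// stride 1, "same" zero padding, implemented as one whole-batch im2col
// (rows ordered n, then h, then w, so fills are contiguous memcpys)
// followed by a single GEMM (Armadillo/BLAS) straight into the output
// buffer. Max pooling is 2x2 stride 2 with argmax indices kept for the
// backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int* d) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// Whole-batch im2col: M has N*H*W rows (n fastest, then h, then w) and
// k*k*Ci columns (kh fastest, then kw, then ci), matching the
// column-major flattening of a (k, k, Ci, Co) weight array.
static void im2col_batch(const double* x, int N, int H, int W, int Ci,
                         int k, arma::mat& M) {
  const int pad = (k - 1) / 2;
  const size_t NH = (size_t)N * H;
  int q = 0;
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = x + (size_t)N * H * W * ci;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh, ++q) {
        double* col = M.colptr(q);
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - pad;
          double* dst = col + NH * w;
          if (ws < 0 || ws >= W) {
            std::fill(dst, dst + NH, 0.0);
            continue;
          }
          const double* src = xc + NH * ws;
          const int h0 = std::max(0, pad - kh);
          const int h1 = std::min(H, H + pad - kh);
          if (h0 > 0) std::fill(dst, dst + (size_t)N * h0, 0.0);
          if (h1 < H) std::fill(dst + (size_t)N * h1, dst + NH, 0.0);
          if (h1 > h0) {
            std::memcpy(dst + (size_t)N * h0,
                        src + (size_t)N * (h0 + kh - pad),
                        sizeof(double) * (size_t)N * (h1 - h0));
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int N = dx[0], H = dx[1], W = dx[2], Ci = dx[3];
  const int k = dw[0], Co = dw[3];
  if (dw[1] != k || dw[2] != Ci) stop("weight dims do not match input");
  const size_t R = (size_t)N * H * W;
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Ci, Co,
                     false, true);
  NumericVector out((R_xlen_t)(R * Co));
  out.attr("dim") = IntegerVector::create(N, H, W, Co);
  arma::mat M(R, k * k * Ci);
  im2col_batch(x.begin(), N, H, W, Ci, k, M);
  arma::mat Y(out.begin(), R, Co, false, true);
  Y = M * Wm;
  for (int c = 0; c < Co; ++c) {
    double* yc = Y.colptr(c);
    const double bc = b[c];
    for (size_t r = 0; r < R; ++r) yc[r] += bc;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                bool want_dx) {
  int dx_[4], dw_[4];
  get_dims4(x, dx_); get_dims4(w, dw_);
  const int N = dx_[0], H = dx_[1], W = dx_[2], Ci = dx_[3];
  const int k = dw_[0], Co = dw_[3];
  const int pad = (k - 1) / 2;
  const size_t R = (size_t)N * H * W;
  const size_t NH = (size_t)N * H;
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Ci, Co,
                     false, true);
  const arma::mat Gy(const_cast<double*>(dy.begin()), R, Co, false, true);
  arma::mat M(R, k * k * Ci);
  im2col_batch(x.begin(), N, H, W, Ci, k, M);
  arma::mat dW = M.t() * Gy;
  arma::rowvec db = arma::sum(Gy, 0);
  NumericVector dxv;
  if (want_dx) {
    dxv = NumericVector((R_xlen_t)(R * Ci));
    dxv.attr("dim") = IntegerVector::create(N, H, W, Ci);
    arma::mat dM = Gy * Wm.t();   // R x (k*k*Ci)
    double* dst0 = dxv.begin();
    int q = 0;
    for (int ci = 0; ci < Ci; ++ci) {
      double* dxc = dst0 + (size_t)N * H * W * ci;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh, ++q) {
          const double* col = dM.colptr(q);
          for (int w_ = 0; w_ < W; ++w_) {
            const int ws = w_ + kw - pad;
            if (ws < 0 || ws >= W) continue;
            const int h0 = std::max(0, pad - kh);
            const int h1 = std::min(H, H + pad - kh);
            if (h1 <= h0) continue;
            double* dst = dxc + NH * ws + (size_t)N * (h0 + kh - pad);
            const double* src = col + NH * w_ + (size_t)N * h0;
            const size_t len = (size_t)N * (h1 - h0);
            for (size_t i = 0; i < len; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
  NumericVector dwv(w.size());
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, dwv.begin());
  dwv.attr("dim") = w.attr("dim");
  NumericVector dbv(Co);
  std::copy(db.memptr(), db.memptr() + Co, dbv.begin());
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  int d[4];
  get_dims4(x, d);
  const int N = d[0], H = d[1], W = d[2], C = d[3];
  if (H % 2 || W % 2) stop("pooling expects even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)N * Ho * Wo * C);
  IntegerVector idx((R_xlen_t)N * Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(N, Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(N, Ho, Wo, C);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t obase =
          (size_t)N * (ho + (size_t)Ho * (wo + (size_t)Wo * c));
        const double* cand[4];
        int candi[4];
        int m = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const int h = 2 * ho + dh, w = 2 * wo + dw;
            cand[m] = xp + (size_t)N * (h + (size_t)H * (w + (size_t)W * c));
            candi[m] = h + H * w;
            ++m;
          }
        for (int n = 0; n < N; ++n) {
          double best = cand[0][n]; int bi = candi[0];
          for (int j = 1; j < 4; ++j) {
            if (cand[j][n] > best) { best = cand[j][n]; bi = candi[j]; }
          }
          op[obase + n] = best;
          ip[obase + n] = bi;
        }
      }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           int H, int W) {
  int d[4];
  get_dims4(dy, d);
  const int N = d[0], Ho = d[1], Wo = d[2], C = d[3];
  NumericVector dx((R_xlen_t)N * H * W * C);
  dx.attr("dim") = IntegerVector::create(N, H, W, C);
  double* dst = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  for (int c = 0; c < C; ++c) {
    double* dxc = dst + (size_t)N * H * W * c;
    const size_t cbase = (size_t)N * Ho * Wo * c;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t o = cbase + (size_t)N * (ho + (size_t)Ho * wo);
        for (int n = 0; n < N; ++n) {
          dxc[(size_t)n + (size_t)N * ip[o + n]] += dyp[o + n];
        }
      }
  }
  return dx;
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// dy masked by (a > 0); returns a fresh vector.
// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector dy, NumericVector a) {
  if (dy.size() != a.size()) stop("relu_bwd: size mismatch");
  NumericVector out(dy.size());
  out.attr("dim") = dy.attr("dim");
  const double* dp = dy.begin();
  const double* ap = a.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) op[i] = ap[i] > 0 ? dp[i] : 0;
  return out;
}
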