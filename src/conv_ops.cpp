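// Convolution primitives for the conv-net engine: im2col/col2im based
// forward and backward passes for strided convolution and transpose
// convolution.  Tensors are R arrays in (H, W, C, N) order (column-major),
// weights in (kh, kw, C_in, C_out) for conv and (kh, kw, C_out, C_in) for
// transpose conv; both are flattened to GEMM-ready matrices on the R side.
//
// Patch matrices use (L x K) layout — one row per output position, one
// column per kernel tap — so the GEMM result lands directly in the
// (Ho, Wo, C_out) memory order of the output array, and the gather /
// scatter loops run contiguously in memory.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather: out(l, k) = x[hi, wi, c] for output position l = ho + wo*Ho and
// kernel tap k = ki + kj*kh + c*kh*kw; out-of-bounds taps stay zero.
static void im2col_lk(const double *xp, int H, int W, int C, int kh, int kw,
                      int stride, int pad, int Ho, int Wo, arma::mat &out) {
  out.zeros();
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double *dst = out.colptr((c * kw + kj) * kh + ki);
        // valid output rows: 0 <= ho*stride - pad + ki < H
        int ho_lo = std::max(0, (pad - ki + stride - 1) / stride);
        int ho_hi = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double *src = xc + (size_t)wi * H;
          double *d = dst + (size_t)wo * Ho;
          for (int ho = ho_lo; ho <= ho_hi; ++ho)
            d[ho] = src[ho * stride - pad + ki];
        }
      }
    }
  }
}

// Scatter-add adjoint: x[hi, wi, c] += cols(l, k).
static void col2im_add_lk(double *xp, int H, int W, int C, int kh, int kw,
                          int stride, int pad, int Ho, int Wo,
                          const arma::mat &cols) {
  for (int c = 0; c < C; ++c) {
    double *xc = xp + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double *src0 = cols.colptr((c * kw + kj) * kh + ki);
        int ho_lo = std::max(0, (pad - ki + stride - 1) / stride);
        int ho_hi = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double *dst = xc + (size_t)wi * H;
          const double *src = src0 + (size_t)wo * Ho;
          for (int ho = ho_lo; ho <= ho_hi; ++ho)
            dst[ho * stride - pad + ki] += src[ho];
        }
      }
    }
  }
}

static IntegerVector dims_of(const NumericVector &a, int want) {
  IntegerVector d = a.attr("dim");
  if (d.size() != want) stop("expected a %d-d array", want);
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int kh, int kw, int stride,
                             int pad) {
  IntegerVector xd = dims_of(x, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = kh * kw * C;
  if ((int)w.size() % K != 0) stop("weight/input channel mismatch");
  const int Cout = w.size() / K;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  arma::mat Wm(w.begin(), K, Cout, false);
  arma::rowvec bv(b.begin(), Cout, false);
  const arma::uword L = (arma::uword)Ho * Wo;
  NumericVector y((R_xlen_t)L * Cout * N);
  arma::mat cols(L, K);
  for (int n = 0; n < N; ++n) {
    im2col_lk(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride,
              pad, Ho, Wo, cols);
    arma::mat Y(y.begin() + (size_t)n * L * Cout, L, Cout, false, true);
    Y = cols * Wm;
    Y.each_row() += bv;
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int kh, int kw, int stride, int pad) {
  IntegerVector xd = dims_of(x, 4), yd = dims_of(dy, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  const int K = kh * kw * C;
  arma::mat Wm(w.begin(), K, Cout, false);
  const arma::uword L = (arma::uword)Ho * Wo;
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  NumericVector dx((R_xlen_t)H * W * C * N);
  arma::mat cols(L, K), dcols(L, K);
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(const_cast<double *>(dy.begin()) + (size_t)n * L * Cout, L,
                  Cout, false);
    im2col_lk(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride,
              pad, Ho, Wo, cols);
    dW += cols.t() * dyn;
    db += arma::sum(dyn, 0);
    dcols = dyn * Wm.t();
    col2im_add_lk(dx.begin() + (size_t)n * H * W * C, H, W, C, kh, kw,
                  stride, pad, Ho, Wo, dcols);
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
NumericVector cpp_convt2d_fwd(NumericVector x, NumericVector w,
                              NumericVector b, int kh, int kw, int stride,
                              int pad, int outpad) {
  IntegerVector xd = dims_of(x, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K2 = (int)w.size() / C;  // kh*kw*Cout
  const int Cout = K2 / (kh * kw);
  const int Ho = (H - 1) * stride - 2 * pad + kh + outpad;
  const int Wo = (W - 1) * stride - 2 * pad + kw + outpad;
  if (outpad >= stride) stop("output padding must be < stride");
  arma::mat Wm(w.begin(), K2, C, false);
  const arma::uword L = (arma::uword)H * W;
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  arma::mat cols(L, K2);
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double *>(x.begin()) + (size_t)n * L * C, L, C,
                 false);
    cols = xm * Wm.t();  // (L x K2)
    double *yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    col2im_add_lk(yp, Ho, Wo, Cout, kh, kw, stride, pad, H, W, cols);
    for (int c = 0; c < Cout; ++c) {
      double *pc = yp + (size_t)c * Ho * Wo;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) pc[i] += b[c];
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_convt2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                     int kh, int kw, int stride, int pad) {
  IntegerVector xd = dims_of(x, 4), yd = dims_of(dy, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  const int K2 = kh * kw * Cout;
  arma::mat Wm(w.begin(), K2, C, false);
  const arma::uword L = (arma::uword)H * W;
  arma::mat dW(K2, C, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx((R_xlen_t)L * C * N);
  arma::mat dcols(L, K2);
  for (int n = 0; n < N; ++n) {
    const double *dyp = dy.begin() + (size_t)n * Ho * Wo * Cout;
    im2col_lk(dyp, Ho, Wo, Cout, kh, kw, stride, pad, H, W, dcols);
    arma::mat xm(const_cast<double *>(x.begin()) + (size_t)n * L * C, L, C,
                 false);
    dW += dcols.t() * xm;
    for (int c = 0; c < Cout; ++c) {
      const double *pc = dyp + (size_t)c * Ho * Wo;
      double s = 0;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) s += pc[i];
      db[c] += s;
    }
    arma::mat dxm(dx.begin() + (size_t)n * L * C, L, C, false, true);
    dxm = dcols * Wm;
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = IntegerVector::create(kh, kw, Cout, C);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
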