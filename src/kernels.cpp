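// Minimal convolution kernels for the CPU training engine.
// Tensors use R's column-major layout: activations [H, W, C, N],
// weights [kh, kw, Cin, Cout]. "same"-style padding is passed explicitly.

#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

static inline void im2col(const double* xp, int H, int W, int C, int n,
                          int kh, int kw, int stride, int pad,
                          int Ho, int Wo, arma::mat& col) {
  col.zeros();
  const int P = Ho * Wo;
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * stride - pad;
      const int p = ho + Ho * wo;
      for (int c = 0; c < C; ++c) {
        const double* xb = xp + ((size_t)n * C + c) * (size_t)H * W;
        const int roff = kh * kw * c;
        for (int j = 0; j < kw; ++j) {
          const int wi = w0 + j;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xb + (size_t)H * wi;
          for (int i = 0; i < kh; ++i) {
            const int hi = h0 + i;
            if (hi < 0 || hi >= H) continue;
            col(i + kh * j + roff, p) = xcol[hi];
          }
        }
      }
    }
  }
  (void)P;
}

// weight array -> (K x Cout) matrix, K = kh*kw*Cin, row order (i, j, c)
static arma::mat weight_mat(const NumericVector& w, int kh, int kw, int Cin, int Cout) {
  arma::mat Wm(kh * kw * Cin, Cout);
  const double* wp = w.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          Wm(i + kh * (j + kw * c), o) =
            wp[i + (size_t)kh * (j + (size_t)kw * (c + (size_t)Cin * o))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("x must be a 4-d array [H, W, C, N]");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("input has %d channels but kernel expects %d", C, Cin);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm = weight_mat(w, kh, kw, Cin, Cout); // K x Cout
  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(K, P);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat ym = col.t() * Wm; // P x Cout, columns contiguous per channel
    std::memcpy(yp + (size_t)n * P * Cout, ym.memptr(),
                sizeof(double) * (size_t)P * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm = weight_mat(w, kh, kw, Cin, Cout); // K x Cout
  arma::mat dWm(K, Cout, arma::fill::zeros);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat col(K, P);
  double* dxp = dx.begin();
  const double* dyp = dy.begin();

  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, kh, kw, stride, pad, Ho, Wo, col);
    // dy slab for sample n is already (P x Cout) column-major
    arma::mat dym(const_cast<double*>(dyp) + (size_t)n * P * Cout, P, Cout,
                  false, true);
    dWm += col * dym;                 // K x Cout
    arma::mat dcol = Wm * dym.t();    // K x P
    // col2im scatter-add
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad;
        const int p = ho + Ho * wo;
        for (int c = 0; c < C; ++c) {
          double* xb = dxp + ((size_t)n * C + c) * (size_t)H * W;
          const int roff = kh * kw * c;
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            double* xcol = xb + (size_t)H * wi;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              xcol[hi] += dcol(i + kh * j + roff, p);
            }
          }
        }
      }
    }
  }

  NumericVector dW((size_t)kh * kw * Cin * Cout);
  dW.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  double* dwp = dW.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          dwp[i + (size_t)kh * (j + (size_t)kw * (c + (size_t)Cin * o))] =
            dWm(i + kh * (j + kw * c), o);
  return List::create(_["dx"] = dx, _["dw"] = dW);
}
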