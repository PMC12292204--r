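#include <Rcpp.h>
using namespace Rcpp;

// Depthwise temporal convolution kernels.
//
// Layouts are chosen so the R side never has to transpose: time is the
// fastest dimension, the map/source index the slowest, matching an
// (T*B, S) R matrix with rows ordered time-within-batch.
//   demixed : array (T, B, S)   -- demixed signals
//   kernels : matrix (L, M)     -- M = S * D kernels; kernel m filters
//                                  demixed source floor(m / D)
//   output  : array (Tp, B, M)  -- Tp = T - L + 1 (valid convolution,
//                                  stride 1, cross-correlation orientation)

// [[Rcpp::export]]
NumericVector dw_conv_forward_cpp(NumericVector demixed, NumericMatrix kernels,
                                  int D) {
  IntegerVector dm = demixed.attr("dim");
  const int T = dm[0], B = dm[1], S = dm[2];
  const int L = kernels.nrow(), M = kernels.ncol();
  if (M != S * D) stop("kernel count must equal S * D");
  if (T < L) stop("temporal length shorter than kernel");
  const int Tp = T - L + 1;

  NumericVector out(static_cast<R_xlen_t>(Tp) * B * M);
  out.attr("dim") = IntegerVector::create(Tp, B, M);
  const double* x = demixed.begin();
  const double* k0 = kernels.begin();
  double* o = out.begin();

  for (int m = 0; m < M; ++m) {
    const int s = m / D;
    const double* km = k0 + static_cast<size_t>(m) * L;
    for (int b = 0; b < B; ++b) {
      const double* xs = x + (static_cast<size_t>(s) * B + b) * T;
      double* om = o + (static_cast<size_t>(m) * B + b) * Tp;
      for (int l = 0; l < L; ++l) {
        const double kl = km[l];
        const double* xl = xs + l;
        for (int t = 0; t < Tp; ++t) om[t] += kl * xl[t];
      }
    }
  }
  return out;
}

// Gradient of the loss w.r.t. the kernels.
// demixed (T, B, S), grad_out (Tp, B, M); returns matrix (L, M).
// [[Rcpp::export]]
NumericMatrix dw_grad_kernels_cpp(NumericVector demixed, NumericVector grad_out,
                                  int L, int D) {
  IntegerVector dm = demixed.attr("dim");
  const int T = dm[0], B = dm[1];
  IntegerVector gm = grad_out.attr("dim");
  const int Tp = gm[0], M = gm[2];
  if (Tp != T - L + 1) stop("inconsistent temporal lengths");

  NumericMatrix gk(L, M);
  const double* x = demixed.begin();
  const double* g = grad_out.begin();
  double* gk0 = gk.begin();

  for (int m = 0; m < M; ++m) {
    const int s = m / D;
    double* gkm = gk0 + static_cast<size_t>(m) * L;
    for (int b = 0; b < B; ++b) {
      const double* xs = x + (static_cast<size_t>(s) * B + b) * T;
      const double* gmb = g + (static_cast<size_t>(m) * B + b) * Tp;
      for (int l = 0; l < L; ++l) {
        const double* xl = xs + l;
        double acc = 0.0;
        for (int t = 0; t < Tp; ++t) acc += gmb[t] * xl[t];
        gkm[l] += acc;
      }
    }
  }
  return gk;
}

// Gradient of the loss w.r.t. the demixed signals.
// grad_out (Tp, B, M); returns array (T, B, S).
// [[Rcpp::export]]
NumericVector dw_grad_input_cpp(NumericVector grad_out, NumericMatrix kernels,
                                int S, int T, int D) {
  IntegerVector gm = grad_out.attr("dim");
  const int Tp = gm[0], B = gm[1], M = gm[2];
  const int L = kernels.nrow();
  if (Tp != T - L + 1) stop("inconsistent temporal lengths");

  NumericVector gx(static_cast<R_xlen_t>(T) * B * S);
  gx.attr("dim") = IntegerVector::create(T, B, S);
  const double* g = grad_out.begin();
  const double* k0 = kernels.begin();
  double* out = gx.begin();

  for (int m = 0; m < M; ++m) {
    const int s = m / D;
    const double* km = k0 + static_cast<size_t>(m) * L;
    for (int b = 0; b < B; ++b) {
      const double* gmb = g + (static_cast<size_t>(m) * B + b) * Tp;
      double* xs = out + (static_cast<size_t>(s) * B + b) * T;
      for (int l = 0; l < L; ++l) {
        const double kl = km[l];
        double* xl = xs + l;
        for (int t = 0; t < Tp; ++t) xl[t] += kl * gmb[t];
      }
    }
  }
  return gx;
}
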