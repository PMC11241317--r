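// Hot kernels of the 1-D CNN: im2col gather, batch-norm element passes,
// and length-2 max pooling. Activation tensors are (batch, length,
// channels) column-major arrays; flattening to (batch*length, channels)
// is index-preserving because batch varies fastest.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector A, int n, int L, int C, int k, int pad) {
  NumericMatrix M(n * L, k * C);
  const double* a = A.begin();
  double* m = M.begin();
  const R_xlen_t nL = (R_xlen_t)n * L;
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < C; ++c) {
      R_xlen_t col = (R_xlen_t)j * C + c;
      double* dst0 = m + col * nL;
      for (int pos = 0; pos < L; ++pos) {
        int s = pos + j - pad;  // source position in the unpadded signal
        if (s < 0 || s >= L) continue;
        const double* src = a + ((R_xlen_t)c * L + s) * n;
        std::copy(src, src + n, dst0 + (R_xlen_t)pos * n);
      }
    }
  }
  return M;
}

// training-mode batch norm over an (m, C) matrix; returns the normalized
// activations plus the batch statistics the backward pass needs
// [[Rcpp::export]]
List cpp_bn_forward(NumericMatrix X, NumericVector gamma, NumericVector beta,
                    double eps) {
  const int m = X.nrow(), C = X.ncol();
  NumericMatrix out(m, C), xhat(m, C);
  NumericVector mu(C), va(C), inv_sd(C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += x[i];
    const double mc = s / m;
    double v = 0.0;
    for (int i = 0; i < m; ++i) { double d = x[i] - mc; v += d * d; }
    const double vc = v / m;
    const double isd = 1.0 / std::sqrt(vc + eps);
    const double g = gamma[c], b = beta[c];
    double* xh = &xhat(0, c);
    double* o = &out(0, c);
    for (int i = 0; i < m; ++i) {
      xh[i] = (x[i] - mc) * isd;
      o[i] = g * xh[i] + b;
    }
    mu[c] = mc; va[c] = vc; inv_sd[c] = isd;
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = va, _["inv_sd"] = inv_sd);
}

// inference-mode batch norm with fixed (running) statistics
// [[Rcpp::export]]
NumericMatrix cpp_bn_infer(NumericMatrix X, NumericVector gamma,
                           NumericVector beta, NumericVector mu,
                           NumericVector va, double eps) {
  const int m = X.nrow(), C = X.ncol();
  NumericMatrix out(m, C);
  for (int c = 0; c < C; ++c) {
    const double isd = 1.0 / std::sqrt(va[c] + eps);
    const double g = gamma[c], b = beta[c], mc = mu[c];
    const double* x = &X(0, c);
    double* o = &out(0, c);
    for (int i = 0; i < m; ++i) o[i] = g * (x[i] - mc) * isd + b;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericMatrix dY, NumericMatrix xhat,
                     NumericVector inv_sd, NumericVector gamma) {
  const int m = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const double* xh = &xhat(0, c);
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < m; ++i) { sg += dy[i] * xh[i]; sb += dy[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c], isd = inv_sd[c];
    const double a1 = g * isd, a2 = sb / m, a3 = sg / m;
    double* dx = &dX(0, c);
    for (int i = 0; i < m; ++i) {
      dx[i] = a1 * (dy[i] - a2 - xh[i] * a3);
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector A, int n, int L, int C) {
  const int L2 = L / 2;
  NumericVector out((R_xlen_t)n * L2 * C);
  LogicalVector take_first((R_xlen_t)n * L2 * C);
  const double* a = A.begin();
  double* o = out.begin();
  int* tf = take_first.begin();
  for (int c = 0; c < C; ++c) {
    for (int pos = 0; pos < L2; ++pos) {
      const double* s1 = a + ((R_xlen_t)c * L + 2 * pos) * n;
      const double* s2 = s1 + n;
      double* dst = o + ((R_xlen_t)c * L2 + pos) * n;
      int* tft = tf + ((R_xlen_t)c * L2 + pos) * n;
      for (int b = 0; b < n; ++b) {
        const bool first = s1[b] >= s2[b];
        dst[b] = first ? s1[b] : s2[b];
        tft[b] = first;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n, L2, C);
  return List::create(_["out"] = out, _["take_first"] = take_first);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dOut, LogicalVector take_first,
                                    int n, int L, int C) {
  const int L2 = L / 2;
  NumericVector dA((R_xlen_t)n * L * C);  // zero-initialized
  const double* d = dOut.begin();
  const int* tf = take_first.begin();
  double* da = dA.begin();
  for (int c = 0; c < C; ++c) {
    for (int pos = 0; pos < L2; ++pos) {
      const double* src = d + ((R_xlen_t)c * L2 + pos) * n;
      const int* tft = tf + ((R_xlen_t)c * L2 + pos) * n;
      double* d1 = da + ((R_xlen_t)c * L + 2 * pos) * n;
      double* d2 = d1 + n;
      for (int b = 0; b < n; ++b) {
        if (tft[b]) d1[b] = src[b]; else d2[b] = src[b];
      }
    }
  }
  dA.attr("dim") = IntegerVector::create(n, L, C);
  return dA;
}
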