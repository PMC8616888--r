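// Hot loops of the convolution and activation machinery. The matrix products
// themselves go through R's BLAS; these kernels only do the memory-layout
// work (same-padded im2col/col2im) and fused elementwise ReLU operations.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// x: (Ci, L, B) column-major array. Returns the same-padded im2col matrix
// (Ci*K, L*B): column (l, b) stacks the K kernel-offset slices of x, each a
// Ci-block, with zeros outside the signal.
// [[Rcpp::export]]
NumericMatrix cpp_im2col1d(NumericVector x, int Ci, int L, int B, int K) {
  const int P = (K - 1) / 2;
  NumericMatrix cols(Ci * K, L * B);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      double* col = cp + (size_t)(b * (size_t)L + l) * (Ci * K);
      for (int k = 0; k < K; ++k) {
        const int src = l + k - P;
        if (src >= 0 && src < L) {
          std::memcpy(col + (size_t)k * Ci,
                      xp + (size_t)Ci * (src + (size_t)L * b),
                      Ci * sizeof(double));
        } else {
          std::memset(col + (size_t)k * Ci, 0, Ci * sizeof(double));
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col1d: scatter-add a (Ci*K, L*B) column gradient back to
// the (Ci, L, B) input layout, dropping the padded border.
// [[Rcpp::export]]
NumericVector cpp_col2im1d(NumericMatrix dcols, int Ci, int L, int B, int K) {
  const int P = (K - 1) / 2;
  NumericVector out((size_t)Ci * L * B);
  double* op = out.begin();
  const double* cp = dcols.begin();
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      const double* col = cp + (size_t)(b * (size_t)L + l) * (Ci * K);
      for (int k = 0; k < K; ++k) {
        const int dst = l + k - P;
        if (dst >= 0 && dst < L) {
          double* o = op + (size_t)Ci * (dst + (size_t)L * b);
          const double* c = col + (size_t)k * Ci;
          for (int ci = 0; ci < Ci; ++ci) o[ci] += c[ci];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ci, L, B);
  return out;
}

// max(x, 0), preserving the dim attribute.
// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector out(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// Fused ReLU backward: d * (pre > 0), with the shape of `pre`.
// [[Rcpp::export]]
NumericVector cpp_relu_grad(NumericVector d, NumericVector pre) {
  if (d.size() != pre.size()) stop("length mismatch in cpp_relu_grad");
  NumericVector out(d.size());
  const double* dp = d.begin();
  const double* pp = pre.begin();
  double* op = out.begin();
  const R_xlen_t n = d.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = pp[i] > 0 ? dp[i] : 0.0;
  out.attr("dim") = pre.attr("dim");
  return out;
}
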