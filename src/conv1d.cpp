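// 1D convolution kernels for the CNN spectra classifier: im2col gathers are
// plain memcpy block copies, the contractions are BLAS gemm via Armadillo.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// A (n, L, Cin) -> X2 (n*Lo, K*Cin), column (k, c) = A[, k:(k+Lo-1), c].
static mat im2col1d(const cube &A, const int K) {
  const int n = A.n_rows, L = A.n_cols, C = A.n_slices;
  const int Lo = L - K + 1;
  const size_t len = (size_t)n * Lo;
  mat X2(len, (size_t)K * C);
  const double *a = A.memptr();
  double *x = X2.memptr();
  for (int c = 0; c < C; ++c) {
    const size_t base = (size_t)c * n * L;
    for (int k = 0; k < K; ++k) {
      std::memcpy(x, a + base + (size_t)k * n, len * sizeof(double));
      x += len;
    }
  }
  return X2;
}

// [[Rcpp::export(name = ".cpp_conv1d_fwd")]]
arma::cube cpp_conv1d_fwd(const arma::cube &A, const arma::cube &W,
                          const arma::vec &bias) {
  const int K = W.n_rows, Cin = W.n_cols, Cout = W.n_slices;
  const int n = A.n_rows, Lo = A.n_cols - K + 1;
  mat X2 = im2col1d(A, K);
  const mat Wm(const_cast<double *>(W.memptr()), (size_t)K * Cin, Cout, false);
  mat Z = X2 * Wm;
  Z.each_row() += bias.t();
  return cube(Z.memptr(), n, Lo, Cout);
}

// [[Rcpp::export(name = ".cpp_conv1d_bwd")]]
Rcpp::List cpp_conv1d_bwd(const arma::cube &A, const arma::cube &W,
                          const arma::cube &dZ, const bool need_dA) {
  const int K = W.n_rows, Cin = W.n_cols, Cout = W.n_slices;
  const int n = A.n_rows, L = A.n_cols, Lo = dZ.n_cols;
  const mat dZm(const_cast<double *>(dZ.memptr()), (size_t)n * Lo, Cout, false);
  mat X2 = im2col1d(A, K);
  mat dWm = X2.t() * dZm;                       // (K*Cin, Cout)
  cube dW(dWm.memptr(), K, Cin, Cout);
  vec db = sum(dZm, 0).t();
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
      Rcpp::Named("dA") = R_NilValue);
  if (need_dA) {
    // full correlation with the flipped kernel: pad dZ by K-1 on both sides
    cube pad(n, Lo + 2 * (K - 1), Cout, fill::zeros);
    pad.cols(K - 1, K + Lo - 2) = dZ;
    mat G = im2col1d(pad, K);                   // (n*L, K*Cout), k' fastest
    mat Wt((size_t)K * Cout, Cin);
    for (int c = 0; c < Cin; ++c)
      for (int o = 0; o < Cout; ++o)
        for (int k = 0; k < K; ++k)
          Wt((size_t)o * K + k, c) = W(K - 1 - k, c, o);
    mat dAm = G * Wt;                           // (n*L, Cin)
    out["dA"] = cube(dAm.memptr(), n, L, Cin);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_relu")]]
Rcpp::NumericVector cpp_relu(Rcpp::NumericVector x) {
  Rcpp::NumericVector out = Rcpp::clone(x);
  double *p = out.begin();
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
  return out;
}

// dZ = dA where Z > 0 else 0 (ReLU backward), preserving dims.
// [[Rcpp::export(name = ".cpp_relu_bwd")]]
Rcpp::NumericVector cpp_relu_bwd(Rcpp::NumericVector dA,
                                 Rcpp::NumericVector Z) {
  Rcpp::NumericVector out = Rcpp::clone(dA);
  const double *z = Z.begin();
  double *p = out.begin();
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (z[i] <= 0) p[i] = 0;
  return out;
}
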