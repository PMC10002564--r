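// Support kernels for the batched layers: block-wise row shifts for the
// length-preserving 1-d convolution, and 1-d batch normalization over the
// batch dimension (column-major streaming, one pass per column).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// shift each of B stacked length-L row blocks by one row;
// dir > 0 moves row i-1 into row i (zero at block starts)
// [[Rcpp::export]]
NumericMatrix shift_blocks(const NumericMatrix& x, int B, int L, int dir) {
  const int n = B * L, d = x.ncol();
  NumericMatrix out(n, d);
  for (int c = 0; c < d; ++c) {
    const double* xc = &x(0, c);
    double* oc = &out(0, c);
    if (dir > 0) {
      for (int b = 0; b < B; ++b) {
        const int r0 = b * L;
        oc[r0] = 0.0;
        for (int i = 1; i < L; ++i) oc[r0 + i] = xc[r0 + i - 1];
      }
    } else {
      for (int b = 0; b < B; ++b) {
        const int r0 = b * L;
        for (int i = 0; i < L - 1; ++i) oc[r0 + i] = xc[r0 + i + 1];
        oc[r0 + L - 1] = 0.0;
      }
    }
  }
  return out;
}

// batch-norm forward; mode 0 = train (batch statistics), 1 = eval (given
// statistics). Returns the output, the normalized input and the statistics.
// [[Rcpp::export]]
List bn_forward(const NumericMatrix& x, const NumericVector& gamma,
                const NumericVector& beta, const NumericVector& mean_in,
                const NumericVector& var_in, int train, double eps) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix y(n, d), xh(n, d);
  NumericVector mu(d), va(d), sd(d);
  for (int c = 0; c < d; ++c) {
    const double* xc = &x(0, c);
    double m, v;
    if (train) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xc[i];
      m = s / n;
      double q = 0.0;
      for (int i = 0; i < n; ++i) { double t = xc[i] - m; q += t * t; }
      v = q / n;
    } else {
      m = mean_in[c];
      v = var_in[c];
    }
    mu[c] = m; va[c] = v;
    const double isd = 1.0 / std::sqrt(v + eps);
    sd[c] = 1.0 / isd;
    const double g = gamma[c], bb = beta[c];
    double* yc = &y(0, c);
    double* hc = &xh(0, c);
    for (int i = 0; i < n; ++i) {
      const double h = (xc[i] - m) * isd;
      hc[i] = h;
      yc[i] = h * g + bb;
    }
  }
  return List::create(_["y"] = y, _["xh"] = xh, _["mean"] = mu,
                      _["var"] = va, _["sd"] = sd);
}

// batch-norm backward (train mode uses the full batch-statistics Jacobian)
// [[Rcpp::export]]
List bn_backward(const NumericMatrix& g, const NumericMatrix& xh,
                 const NumericVector& sd, const NumericVector& gamma,
                 int train) {
  const int n = g.nrow(), d = g.ncol();
  NumericMatrix dx(n, d);
  NumericVector dgamma(d), dbeta(d);
  for (int c = 0; c < d; ++c) {
    const double* gc = &g(0, c);
    const double* hc = &xh(0, c);
    double sg = 0.0, sgh = 0.0;
    for (int i = 0; i < n; ++i) { sg += gc[i]; sgh += gc[i] * hc[i]; }
    dgamma[c] = sgh;
    dbeta[c] = sg;
    const double gam = gamma[c], isd = 1.0 / sd[c];
    double* dc = &dx(0, c);
    if (train) {
      const double mg = sg / n, mgh = sgh / n;
      for (int i = 0; i < n; ++i) {
        dc[i] = (gc[i] - mg - hc[i] * mgh) * gam * isd;
      }
    } else {
      for (int i = 0; i < n; ++i) dc[i] = gc[i] * gam * isd;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
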