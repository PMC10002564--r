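// Batched block-diagonal multi-head self-attention kernels.
// A minibatch of B length-L blocks is stored as a (B*L) x d matrix; scores
// and context products never leave the per-block L x L tiles. Each (block,
// head) tile of Q/K/V is copied into a contiguous row-major buffer first so
// the inner dot products stream through cache.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void load_tile(const NumericMatrix& X, int r0, int c0,
                             int L, int dh, std::vector<double>& buf) {
  for (int c = 0; c < dh; ++c) {
    const double* col = &X(0, c0 + c);
    for (int i = 0; i < L; ++i) buf[i * dh + c] = col[r0 + i];
  }
}

// [[Rcpp::export]]
List attn_block_forward(const NumericMatrix& Q, const NumericMatrix& K,
                        const NumericMatrix& V, int B, int L, int heads,
                        double scale, double dropout, bool train) {
  const int d = Q.ncol();
  const int dh = d / heads;
  NumericMatrix O(B * L, d);
  const int ntile = B * heads;
  // per (block, head) L x L attention tiles, stored contiguously row-major
  NumericVector A(static_cast<R_xlen_t>(ntile) * L * L);
  bool use_drop = train && dropout > 0;
  NumericVector M(use_drop ? static_cast<R_xlen_t>(ntile) * L * L : 0);
  std::vector<double> S(L), q(L * dh), k(L * dh), v(L * dh), o(L * dh);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh;
      const R_xlen_t t0 = static_cast<R_xlen_t>(b * heads + h) * L * L;
      load_tile(Q, r0, c0, L, dh, q);
      load_tile(K, r0, c0, L, dh, k);
      load_tile(V, r0, c0, L, dh, v);
      for (int i = 0; i < L; ++i) {
        const double* qi = &q[i * dh];
        double mx = -INFINITY;
        for (int j = 0; j < L; ++j) {
          const double* kj = &k[j * dh];
          double s = 0.0;
          for (int c = 0; c < dh; ++c) s += qi[c] * kj[c];
          s *= scale;
          S[j] = s;
          if (s > mx) mx = s;
        }
        double tot = 0.0;
        for (int j = 0; j < L; ++j) {
          S[j] = std::exp(S[j] - mx);
          tot += S[j];
        }
        for (int j = 0; j < L; ++j) {
          double a = S[j] / tot;
          A[t0 + i * L + j] = a;
          double ad = a;
          if (use_drop) {
            double m = (unif_rand() >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
            M[t0 + i * L + j] = m;
            ad *= m;
          }
          S[j] = ad;
        }
        double* oi = &o[i * dh];
        for (int c = 0; c < dh; ++c) oi[c] = 0.0;
        for (int j = 0; j < L; ++j) {
          const double aj = S[j];
          if (aj != 0.0) {
            const double* vj = &v[j * dh];
            for (int c = 0; c < dh; ++c) oi[c] += aj * vj[c];
          }
        }
      }
      for (int c = 0; c < dh; ++c) {
        double* col = &O(0, c0 + c);
        for (int i = 0; i < L; ++i) col[r0 + i] = o[i * dh + c];
      }
    }
  }
  return List::create(_["O"] = O, _["A"] = A, _["M"] = M);
}

// [[Rcpp::export]]
List attn_block_backward(const NumericMatrix& dO, const NumericMatrix& Q,
                         const NumericMatrix& K, const NumericMatrix& V,
                         const NumericVector& A, const NumericVector& M,
                         int B, int L, int heads, double scale) {
  const int d = Q.ncol();
  const int dh = d / heads;
  const bool use_drop = M.size() > 0;
  NumericMatrix dQ(B * L, d), dK(B * L, d), dV(B * L, d);
  std::vector<double> dA(L), Ad(L), q(L * dh), k(L * dh), v(L * dh),
      go(L * dh), gq(L * dh), gk(L * dh), gv(L * dh);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh;
      const R_xlen_t t0 = static_cast<R_xlen_t>(b * heads + h) * L * L;
      load_tile(Q, r0, c0, L, dh, q);
      load_tile(K, r0, c0, L, dh, k);
      load_tile(V, r0, c0, L, dh, v);
      load_tile(dO, r0, c0, L, dh, go);
      std::fill(gq.begin(), gq.end(), 0.0);
      std::fill(gk.begin(), gk.end(), 0.0);
      std::fill(gv.begin(), gv.end(), 0.0);
      for (int i = 0; i < L; ++i) {
        const double* goi = &go[i * dh];
        for (int j = 0; j < L; ++j) {
          const double* vj = &v[j * dh];
          double s = 0.0;
          for (int c = 0; c < dh; ++c) s += goi[c] * vj[c];
          double mk = use_drop ? M[t0 + i * L + j] : 1.0;
          dA[j] = s * mk;
          Ad[j] = A[t0 + i * L + j] * mk;
        }
        for (int j = 0; j < L; ++j) {
          const double aj = Ad[j];
          if (aj != 0.0) {
            double* gvj = &gv[j * dh];
            for (int c = 0; c < dh; ++c) gvj[c] += aj * goi[c];
          }
        }
        double inner = 0.0;
        const double* Ai = &A[t0 + i * L];
        for (int j = 0; j < L; ++j) inner += dA[j] * Ai[j];
        for (int j = 0; j < L; ++j) {
          dA[j] = Ai[j] * (dA[j] - inner) * scale;
        }
        const double* qi = &q[i * dh];
        double* gqi = &gq[i * dh];
        for (int j = 0; j < L; ++j) {
          const double ds = dA[j];
          if (ds != 0.0) {
            const double* kj = &k[j * dh];
            double* gkj = &gk[j * dh];
            for (int c = 0; c < dh; ++c) {
              gqi[c] += ds * kj[c];
              gkj[c] += ds * qi[c];
            }
          }
        }
      }
      for (int c = 0; c < dh; ++c) {
        double* cq = &dQ(0, c0 + c);
        double* ck = &dK(0, c0 + c);
        double* cv = &dV(0, c0 + c);
        for (int i = 0; i < L; ++i) {
          cq[r0 + i] = gq[i * dh + c];
          ck[r0 + i] = gk[i * dh + c];
          cv[r0 + i] = gv[i * dh + c];
        }
      }
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
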