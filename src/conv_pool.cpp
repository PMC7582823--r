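#include <Rcpp.h>
using namespace Rcpp;

// Fused valid 2x2 convolution -> ReLU -> 2x2 max-pool (stride 2) forward pass
// for a batch of single-channel maps.
//
// X: (d1, d2, B) input batch, W: (2, 2, K) kernels, b: length-K biases.
// Conv grid is (d1-1) x (d2-1); pooling floors odd grid edges.
// Returns pooled activations P with dim (K, pu, pv, B) -- kernel index
// fastest so matrix(P, K*pu*pv, B) flattens per-sample feature columns --
// and `argmax`, the 0-based conv-cell index (u + (d1-1)*v) that won each
// pool window (first win on ties, scan order u fastest then v).
// [[Rcpp::export]]
List conv_pool_fwd(NumericVector X, NumericVector W, NumericVector b) {
  IntegerVector xd = X.attr("dim");
  IntegerVector wd = W.attr("dim");
  const int d1 = xd[0], d2 = xd[1], B = xd[2];
  const int K = wd[2];
  const int cu = d1 - 1, cv = d2 - 1;
  const int pu = cu / 2, pv = cv / 2;
  if (pu < 1 || pv < 1)
    stop("input %dx%d too small: conv+pool output would be empty", d1, d2);

  NumericVector P(K * pu * pv * B);
  IntegerVector amax(K * pu * pv * B);
  P.attr("dim") = IntegerVector::create(K, pu, pv, B);
  amax.attr("dim") = IntegerVector::create(K, pu, pv, B);

  const double *x = X.begin(), *w = W.begin(), *bb = b.begin();
  double *p = P.begin();
  int *am = amax.begin();

  for (int n = 0; n < B; ++n) {
    const double *xn = x + (size_t)n * d1 * d2;
    for (int k = 0; k < K; ++k) {
      const double w00 = w[4 * k], w10 = w[4 * k + 1];
      const double w01 = w[4 * k + 2], w11 = w[4 * k + 3];
      const double bk = bb[k];
      for (int q = 0; q < pv; ++q) {
        for (int pp = 0; pp < pu; ++pp) {
          double best = -1.0;  // ReLU output is >= 0; any cell beats -1
          int besti = 0;
          for (int dv = 0; dv < 2; ++dv) {
            const int v = 2 * q + dv;
            const double *col0 = xn + (size_t)v * d1;
            const double *col1 = col0 + d1;
            for (int du = 0; du < 2; ++du) {
              const int u = 2 * pp + du;
              double z = bk + w00 * col0[u] + w10 * col0[u + 1]
                            + w01 * col1[u] + w11 * col1[u + 1];
              if (z < 0) z = 0;
              if (z > best) { best = z; besti = u + cu * v; }
            }
          }
          const size_t o = (size_t)k + (size_t)K * (pp + (size_t)pu * (q + (size_t)pv * n));
          p[o] = best;
          am[o] = besti;
        }
      }
    }
  }
  return List::create(_["P"] = P, _["argmax"] = amax);
}

// Backward pass of the fused layer: given upstream gradients dP on the pooled
// activations plus the forward caches, accumulate kernel and bias gradients.
// Gradient flows only through each pool window's winning conv cell, and only
// where the winning activation is strictly positive (ReLU subgradient 0 at 0).
// Returns dW (2,2,K) and db (K). The input-gradient is not needed (first layer).
// [[Rcpp::export]]
List conv_pool_bwd(NumericVector X, NumericVector dP, NumericVector P,
                   IntegerVector amax) {
  IntegerVector xd = X.attr("dim");
  IntegerVector pd = dP.attr("dim");
  const int d1 = xd[0];
  const int K = pd[0], pu = pd[1], pv = pd[2], B = pd[3];
  const int cu = d1 - 1;

  NumericVector dW(4 * K), db(K);
  dW.attr("dim") = IntegerVector::create(2, 2, K);
  const double *x = X.begin(), *dp = dP.begin(), *p = P.begin();
  const int *am = amax.begin();
  double *dw = dW.begin(), *dbb = db.begin();

  for (int n = 0; n < B; ++n) {
    const double *xn = x + (size_t)n * d1 * ((size_t)xd[1]);
    for (int q = 0; q < pv; ++q) {
      for (int pp = 0; pp < pu; ++pp) {
        for (int k = 0; k < K; ++k) {
          const size_t o = (size_t)k + (size_t)K * (pp + (size_t)pu * (q + (size_t)pv * n));
          const double g = dp[o];
          if (g == 0.0 || p[o] <= 0.0) continue;
          const int u = am[o] % cu, v = am[o] / cu;
          const double *col0 = xn + (size_t)v * d1;
          const double *col1 = col0 + d1;
          dw[4 * k]     += g * col0[u];
          dw[4 * k + 1] += g * col0[u + 1];
          dw[4 * k + 2] += g * col1[u];
          dw[4 * k + 3] += g * col1[u + 1];
          dbb[k] += g;
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}
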