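#include <Rcpp.h>
using namespace Rcpp;

// Column-broadcast kernels for the dense-network hot path: v has one entry
// per column of X (column-major). Single pass, no temporaries.

// [[Rcpp::export]]
NumericMatrix cpp_col_add(NumericMatrix X, NumericVector v) {
  int n = X.nrow(), k = X.ncol();
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    double vj = v[j];
    for (int i = 0; i < n; ++i) out(i, j) = X(i, j) + vj;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_col_mul(NumericMatrix X, NumericVector v) {
  int n = X.nrow(), k = X.ncol();
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    double vj = v[j];
    for (int i = 0; i < n; ++i) out(i, j) = X(i, j) * vj;
  }
  return out;
}

// X * scale + shift, column-wise (fused batch-norm affine).
// [[Rcpp::export]]
NumericMatrix cpp_col_scale_shift(NumericMatrix X, NumericVector scale,
                                  NumericVector shift) {
  int n = X.nrow(), k = X.ncol();
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    double sj = scale[j], bj = shift[j];
    for (int i = 0; i < n; ++i) out(i, j) = X(i, j) * sj + bj;
  }
  return out;
}

// Leaky-ReLU forward: out = X > 0 ? X : slope * X.
// [[Rcpp::export]]
NumericMatrix cpp_lrelu(NumericMatrix X, double slope) {
  int m = X.nrow() * X.ncol();
  NumericMatrix out(X.nrow(), X.ncol());
  for (int i = 0; i < m; ++i) out[i] = X[i] > 0 ? X[i] : slope * X[i];
  return out;
}

// Leaky-ReLU backward: dX = pre > 0 ? dOut : slope * dOut (pre = forward
// input).
// [[Rcpp::export]]
NumericMatrix cpp_lrelu_grad(NumericMatrix dOut, NumericMatrix pre,
                             double slope) {
  int m = dOut.nrow() * dOut.ncol();
  NumericMatrix out(dOut.nrow(), dOut.ncol());
  for (int i = 0; i < m; ++i) out[i] = pre[i] > 0 ? dOut[i] : slope * dOut[i];
  return out;
}

// Batch-norm training forward: per-column batch mean/var (biased), fused
// normalize + affine. Returns out, xhat, invstd, mu, var.
// [[Rcpp::export]]
List cpp_bn_train_forward(NumericMatrix X, NumericVector gamma,
                          NumericVector beta, double eps) {
  int n = X.nrow(), k = X.ncol();
  NumericMatrix out(n, k), xhat(n, k);
  NumericVector mu(k), var(k), invstd(k);
  for (int j = 0; j < k; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, j);
    double m = s / n;
    double ss = 0;
    for (int i = 0; i < n; ++i) {
      double d = X(i, j) - m;
      ss += d * d;
    }
    double v = ss / n;
    double is = 1.0 / std::sqrt(v + eps);
    mu[j] = m; var[j] = v; invstd[j] = is;
    double gj = gamma[j], bj = beta[j];
    for (int i = 0; i < n; ++i) {
      double xh = (X(i, j) - m) * is;
      xhat(i, j) = xh;
      out(i, j) = xh * gj + bj;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["invstd"] = invstd, _["mu"] = mu, _["var"] = var);
}

// Batch-norm backward (training mode).
// [[Rcpp::export]]
List cpp_bn_backward(NumericMatrix dOut, NumericMatrix xhat,
                     NumericVector invstd, NumericVector gamma) {
  int n = dOut.nrow(), k = dOut.ncol();
  NumericMatrix dX(n, k);
  NumericVector dgamma(k), dbeta(k);
  for (int j = 0; j < k; ++j) {
    double s1 = 0, s2 = 0, dg = 0, db = 0;
    double gj = gamma[j];
    for (int i = 0; i < n; ++i) {
      double dxh = dOut(i, j) * gj;
      s1 += dxh;
      s2 += dxh * xhat(i, j);
      dg += dOut(i, j) * xhat(i, j);
      db += dOut(i, j);
    }
    double scale = invstd[j] / n;
    for (int i = 0; i < n; ++i) {
      double dxh = dOut(i, j) * gj;
      dX(i, j) = scale * (n * dxh - s1 - xhat(i, j) * s2);
    }
    dgamma[j] = dg; dbeta[j] = db;
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Inverted dropout using R's RNG (column-major draw order, one uniform per
// element). Returns the masked output and the mask itself.
// [[Rcpp::export]]
List cpp_dropout(NumericMatrix X, double p) {
  int m = X.nrow() * X.ncol();
  NumericMatrix out(X.nrow(), X.ncol()), mask(X.nrow(), X.ncol());
  double inv = 1.0 / (1.0 - p);
  for (int i = 0; i < m; ++i) {
    double keep = unif_rand() >= p ? inv : 0.0;
    mask[i] = keep;
    out[i] = X[i] * keep;
  }
  return List::create(_["out"] = out, _["mask"] = mask);
}

// One fused Adam update; returns new parameter and moment arrays.
// [[Rcpp::export]]
List cpp_adam(NumericVector p, NumericVector g, NumericVector m,
              NumericVector v, double lr, double beta1, double beta2,
              double eps, double bc1, double bc2) {
  int n = p.size();
  NumericVector p2(n), m2(n), v2(n);
  for (int i = 0; i < n; ++i) {
    double mi = beta1 * m[i] + (1 - beta1) * g[i];
    double vi = beta2 * v[i] + (1 - beta2) * g[i] * g[i];
    m2[i] = mi; v2[i] = vi;
    p2[i] = p[i] - lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
  p2.attr("dim") = p.attr("dim");
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}
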