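#include <Rcpp.h>
using namespace Rcpp;

// Layout conventions (column-major as in R):
//  - activation tensors are R arrays dim (H, W, N, C): within a channel,
//    the N image planes are contiguous, so the im2col output -- rows
//    indexed by (h + H*w + H*W*n), columns by (kh + k*kw + k*k*c) -- is a
//    straight reshape-compatible view and convolution is a single GEMM
//    against the (k*k*C_in) x C_out weight matrix.
//  - zero padding of (k-1)/2 keeps spatial size ("same" convolution).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N, int k) {
  const int pad = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  const int cols = k * k * C;
  NumericMatrix out(rows, cols);
  const double* px = x.begin();
  double* pout = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * c;
        double* dst = pout + (R_xlen_t)col * rows;
        for (int n = 0; n < N; ++n) {
          const double* src = px + ((R_xlen_t)c * N + n) * H * W;
          for (int w = 0; w < W; ++w) {
            const int wi = w + kw - pad;
            double* d = dst + (R_xlen_t)n * H * W + (R_xlen_t)w * H;
            if (wi < 0 || wi >= W) {
              for (int h = 0; h < H; ++h) d[h] = 0.0;
            } else {
              const double* s = src + (R_xlen_t)wi * H;
              for (int h = 0; h < H; ++h) {
                const int hi = h + kh - pad;
                d[h] = (hi < 0 || hi >= H) ? 0.0 : s[hi];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add column gradients back onto the input.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int N, int k) {
  const int pad = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericVector out((R_xlen_t)H * W * C * N);
  double* pout = out.begin();
  const double* pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * c;
        const double* src = pc + (R_xlen_t)col * rows;
        for (int n = 0; n < N; ++n) {
          double* dst = pout + ((R_xlen_t)c * N + n) * H * W;
          for (int w = 0; w < W; ++w) {
            const int wi = w + kw - pad;
            if (wi < 0 || wi >= W) continue;
            const double* s = src + (R_xlen_t)n * H * W + (R_xlen_t)w * H;
            double* d = dst + (R_xlen_t)wi * H;
            for (int h = 0; h < H; ++h) {
              const int hi = h + kh - pad;
              if (hi >= 0 && hi < H) d[hi] += s[h];
            }
          }
        }
      }
    }
  }
  return out;
}

// 2x2 stride-2 max pooling applied independently to every (H, W) plane of
// a (H, W, N, C) tensor; also returns 1-based argmax linear indices into
// the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, R_xlen_t n_planes) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * n_planes);
  IntegerVector idx((R_xlen_t)Ho * Wo * n_planes);
  const double* px = x.begin();
  R_xlen_t o = 0;
  for (R_xlen_t cn = 0; cn < n_planes; ++cn) {
    const double* plane = px + cn * H * W;
    const R_xlen_t base = cn * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const int h0 = 2 * h, w0 = 2 * w;
        R_xlen_t best = (R_xlen_t)w0 * H + h0;
        double bv = plane[best];
        const R_xlen_t cand[3] = {(R_xlen_t)w0 * H + h0 + 1,
                                  (R_xlen_t)(w0 + 1) * H + h0,
                                  (R_xlen_t)(w0 + 1) * H + h0 + 1};
        for (int j = 0; j < 3; ++j)
          if (plane[cand[j]] > bv) { bv = plane[cand[j]]; best = cand[j]; }
        out[o] = bv;
        idx[o] = (int)(base + best + 1);
        ++o;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector grad, IntegerVector idx,
                                   R_xlen_t input_len) {
  NumericVector out(input_len);
  for (R_xlen_t i = 0; i < grad.size(); ++i)
    out[idx[i] - 1] += grad[i];
  return out;
}

// out[, j] = Z[, j] * scale[j] + shift[j], optionally rectified.
// Single pass; used for both batch-norm affine steps.
// [[Rcpp::export]]
NumericMatrix cpp_colscale_shift(NumericMatrix Z, NumericVector scale,
                                 NumericVector shift, bool relu) {
  const R_xlen_t n = Z.nrow();
  const int p = Z.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double a = scale[j], b = shift[j];
    const double* src = Z.begin() + (R_xlen_t)j * n;
    double* dst = out.begin() + (R_xlen_t)j * n;
    if (relu)
      for (R_xlen_t i = 0; i < n; ++i) {
        double v = src[i] * a + b;
        dst[i] = v > 0 ? v : 0;
      }
    else
      for (R_xlen_t i = 0; i < n; ++i) dst[i] = src[i] * a + b;
  }
  return out;
}

// Fused ReLU + batch-norm backward.  `act` is the post-ReLU activation
// (zero entries gate the gradient); pass an empty matrix to skip the ReLU
// gate.  Returns dZ (gradient wrt the pre-norm input) plus dgamma, dbeta.
// [[Rcpp::export]]
List cpp_bn_relu_backward(NumericMatrix dout, NumericMatrix act,
                          NumericMatrix Zhat, NumericVector gamma,
                          NumericVector invstd) {
  const R_xlen_t n = dout.nrow();
  const int p = dout.ncol();
  const bool gate = act.nrow() == n;
  NumericMatrix dZ(n, p);
  NumericVector dgamma(p), dbeta(p);
  for (int j = 0; j < p; ++j) {
    const double* pd = dout.begin() + (R_xlen_t)j * n;
    const double* pa = gate ? act.begin() + (R_xlen_t)j * n : nullptr;
    const double* pz = Zhat.begin() + (R_xlen_t)j * n;
    double* pdz = dZ.begin() + (R_xlen_t)j * n;
    double s1 = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double d = (gate && pa[i] <= 0) ? 0.0 : pd[i];
      pdz[i] = d;           // store gated dout temporarily
      s1 += d;
      s2 += d * pz[i];
    }
    dbeta[j] = s1;
    dgamma[j] = s2;
    const double g = gamma[j] * invstd[j];
    const double m1 = s1 / n, m2 = s2 / n;
    for (R_xlen_t i = 0; i < n; ++i)
      pdz[i] = g * (pdz[i] - m1 - pz[i] * m2);
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Per-channel global average pooling of a (H, W, N, C) tensor -> N x C.
// [[Rcpp::export]]
NumericMatrix cpp_gap(NumericVector x, int H, int W, int N, int C) {
  NumericMatrix out(N, C);
  const double* px = x.begin();
  const R_xlen_t hw = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* p = px + ((R_xlen_t)c * N + n) * hw;
      double s = 0;
      for (R_xlen_t i = 0; i < hw; ++i) s += p[i];
      out(n, c) = s / hw;
    }
  return out;
}

// Column means and mean squares in one pass (batch-norm statistics)
// without materializing Z*Z.
// [[Rcpp::export]]
List cpp_col_moments(NumericMatrix Z) {
  const R_xlen_t n = Z.nrow();
  const int p = Z.ncol();
  NumericVector mu(p), msq(p);
  for (int j = 0; j < p; ++j) {
    const double* src = Z.begin() + (R_xlen_t)j * n;
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; ++i) { s += src[i]; s2 += src[i] * src[i]; }
    mu[j] = s / n;
    msq[j] = s2 / n;
  }
  return List::create(_["mu"] = mu, _["msq"] = msq);
}
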