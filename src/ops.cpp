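// Low-level CPU kernels for the convolutional-network engine and mask ops.
// Tensor layout throughout: column-major R arrays [H, W, C, N]
// (row index fastest, as in R matrices); weights for a kH x kW convolution
// are [C*kH*kW, K] with row index r = c*kH*kW + dh*kW + dw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void im2col_same(const double* x, int H, int W, int C,
                               int kH, int kW, arma::mat& cols) {
  const int pH = kH / 2, pW = kW / 2;
  // cols is (C*kH*kW) x (H*W), column j = h + H*w
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dh = 0; dh < kH; ++dh) {
      for (int dw = 0; dw < kW; ++dw) {
        int r = c * kH * kW + dh * kW + dw;
        for (int w = 0; w < W; ++w) {
          int ws = w + dw - pW;
          double* dst = cols.memptr() + (size_t)r +
            (size_t)cols.n_rows * (size_t)H * w;
          if (ws < 0 || ws >= W) {
            for (int h = 0; h < H; ++h) dst[(size_t)cols.n_rows * h] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)H * ws;
          for (int h = 0; h < H; ++h) {
            int hs = h + dh - pH;
            dst[(size_t)cols.n_rows * h] =
              (hs < 0 || hs >= H) ? 0.0 : src[hs];
          }
        }
      }
    }
  }
}

static inline void col2im_same(const arma::mat& cols, int H, int W, int C,
                               int kH, int kW, double* dx) {
  const int pH = kH / 2, pW = kW / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int dh = 0; dh < kH; ++dh) {
      for (int dw = 0; dw < kW; ++dw) {
        int r = c * kH * kW + dh * kW + dw;
        for (int w = 0; w < W; ++w) {
          int ws = w + dw - pW;
          if (ws < 0 || ws >= W) continue;
          const double* src = cols.memptr() + (size_t)r +
            (size_t)cols.n_rows * (size_t)H * w;
          double* dst = xc + (size_t)H * ws;
          for (int h = 0; h < H; ++h) {
            int hs = h + dh - pH;
            if (hs >= 0 && hs < H) dst[hs] += src[(size_t)cols.n_rows * h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                         int H, int W, int C, int N, int kH, int kW) {
  const int K = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), K, false);
  NumericVector y((size_t)H * W * K * N);
  arma::mat cols((size_t)C * kH * kW, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)H * W * C * n, H, W, C, kH, kW, cols);
    arma::mat out(y.begin() + (size_t)H * W * K * n, (size_t)H * W, K,
                  false, true);
    out = cols.t() * wm;
    for (int k = 0; k < K; ++k) out.col(k) += b[k];
  }
  y.attr("dim") = IntegerVector::create(H, W, K, N);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                int H, int W, int C, int N, int kH, int kW) {
  const int K = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), K, false);
  NumericVector dx((size_t)H * W * C * N);
  NumericMatrix dw(w.nrow(), K);
  arma::mat dwm(dw.begin(), w.nrow(), K, false);
  NumericVector db(K);
  arma::mat cols((size_t)C * kH * kW, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)H * W * C * n, H, W, C, kH, kW, cols);
    arma::mat dyn(dy.begin() + (size_t)H * W * K * n, (size_t)H * W, K,
                  false, true);
    dwm += cols * dyn;
    for (int k = 0; k < K; ++k) db[k] += arma::accu(dyn.col(k));
    arma::mat dcols = wm * dyn.t();
    col2im_same(dcols, H, W, C, kH, kW, dx.begin() + (size_t)H * W * C * n);
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max-pool, stride 2; H and W must be even.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // linear index into input plane
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          int h0 = 2 * h, w0 = 2 * w;
          int best = h0 + H * w0;
          double bv = xp[best];
          int cand[3] = { h0 + 1 + H * w0, h0 + H * (w0 + 1),
                          h0 + 1 + H * (w0 + 1) };
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          // output linear position: h + Ho*w (within plane), planes in order
          size_t op = (size_t)(h + Ho * w) +
            (size_t)Ho * Wo * (c + (size_t)C * n);
          y[op] = bv;
          idx[op] = best;
          (void)o;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((size_t)H * W * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t base = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (size_t j = 0; j < (size_t)Ho * Wo; ++j)
        dxp[idx[base + j]] += dy[base + j];
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Connected-component labelling of a binary mask (matrix H x W),
// 4- or 8-connectivity; labels 1..n in scan order, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cc_label(IntegerMatrix mask, int connectivity = 4) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dh4[] = { -1, 1, 0, 0 }, dw4[] = { 0, 0, -1, 1 };
  const int dh8[] = { -1, 1, 0, 0, -1, -1, 1, 1 },
            dw8[] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  const int* dh = connectivity == 8 ? dh8 : dh4;
  const int* dw = connectivity == 8 ? dw8 : dw4;
  const int nd = connectivity == 8 ? 8 : 4;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w)) continue;
      lab(h, w) = ++next;
      stack.push_back(h + H * w);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int ph = p % H, pw = p / H;
        for (int k = 0; k < nd; ++k) {
          int qh = ph + dh[k], qw = pw + dw[k];
          if (qh < 0 || qh >= H || qw < 0 || qw >= W) continue;
          if (mask(qh, qw) && !lab(qh, qw)) {
            lab(qh, qw) = next;
            stack.push_back(qh + H * qw);
          }
        }
      }
    }
  }
  return lab;
}

// Batch normalization over (H, W, N) per channel. Forward returns y plus
// the batch mean and inverse std needed for the backward pass.
// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector g, NumericVector b,
                NumericVector rmean, NumericVector rvar,
                int H, int W, int C, int N, bool train, double eps) {
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  NumericVector mu(C), iv(C);
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (train) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + plane * (c + (size_t)C * n);
        for (size_t j = 0; j < plane; ++j) { s += xp[j]; s2 += xp[j] * xp[j]; }
      }
      double M = (double)plane * N;
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
    } else {
      m = rmean[c]; v = rvar[c];
    }
    mu[c] = m;
    iv[c] = 1.0 / std::sqrt(v + eps);
    double gc = g[c] * iv[c], bc = b[c] - m * gc;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + plane * (c + (size_t)C * n);
      double* yp = y.begin() + plane * (c + (size_t)C * n);
      for (size_t j = 0; j < plane; ++j) yp[j] = gc * xp[j] + bc;
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["y"] = y, _["mu"] = mu, _["iv"] = iv);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector x, NumericVector dy, NumericVector g,
                NumericVector mu, NumericVector iv,
                int H, int W, int C, int N) {
  const size_t plane = (size_t)H * W;
  NumericVector dx(x.size());
  NumericVector dg(C), db(C);
  const double M = (double)plane * N;
  for (int c = 0; c < C; ++c) {
    double s_dy = 0, s_dyx = 0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + plane * (c + (size_t)C * n);
      const double* dp = dy.begin() + plane * (c + (size_t)C * n);
      for (size_t j = 0; j < plane; ++j) {
        double xh = (xp[j] - mu[c]) * iv[c];
        s_dy += dp[j];
        s_dyx += dp[j] * xh;
      }
    }
    dg[c] = s_dyx;
    db[c] = s_dy;
    double m_dy = s_dy / M, m_dyx = s_dyx / M;
    double gi = g[c] * iv[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + plane * (c + (size_t)C * n);
      const double* dp = dy.begin() + plane * (c + (size_t)C * n);
      double* op = dx.begin() + plane * (c + (size_t)C * n);
      for (size_t j = 0; j < plane; ++j) {
        double xh = (xp[j] - mu[c]) * iv[c];
        op[j] = gi * (dp[j] - m_dy - xh * m_dyx);
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// Tissue curve of the 2CXM for a piecewise-linear AIF: closed-form
// bi-exponential impulse response (degenerate volumes -> analytic limits)
// convolved exactly per linear segment. Fp and PS in mL/min/mL.
// [[Rcpp::export]]
NumericVector cxm_tissue_cpp(double Fp, double vp, double PS, double ve,
                             NumericVector ca, NumericVector times) {
  const int n = times.size();
  NumericVector out(n);
  double c1 = 0, k1 = 0, c2 = 0, k2 = 0;
  double fp = Fp / 60.0, ps = PS / 60.0;
  if (fp <= 0) return out;
  if (vp <= 0) {
    if (ps <= 0 || ve <= 0) return out;
    double kappa = fp * ps / (fp + ps);
    c1 = kappa; k1 = kappa / ve;
  } else if (ve <= 0 || ps <= 0) {
    c1 = fp; k1 = fp / vp;
  } else {
    double tr = -((fp + ps) / vp + ps / ve);
    double det = ps * fp / (vp * ve);
    double disc = tr * tr - 4 * det;
    if (disc < 1e-18) { ps *= 1.0 + 1e-6; tr = -((fp + ps) / vp + ps / ve);
      det = ps * fp / (vp * ve); disc = std::max(tr * tr - 4 * det, 0.0); }
    double sq = std::sqrt(disc);
    double l1 = (tr + sq) / 2, l2 = (tr - sq) / 2;
    double m1 = l1 * ve / ps + 1, m2 = l2 * ve / ps + 1;
    c1 = (vp * m1 + ve) * fp / (vp * (m1 - m2));
    c2 = -(vp * m2 + ve) * fp / (vp * (m1 - m2));
    k1 = -l1; k2 = -l2;
  }
  double y1 = 0, y2 = 0;
  for (int i = 0; i < n - 1; ++i) {
    double dt = times[i + 1] - times[i];
    double m = (ca[i + 1] - ca[i]) / dt;
    if (k1 * dt > 1e-12) {
      double E = std::exp(-k1 * dt), I0 = (1 - E) / k1;
      y1 = E * y1 + ca[i] * I0 + m * (dt - I0) / k1;
    } else y1 = y1 + ca[i] * dt + m * dt * dt / 2;
    if (c2 != 0) {
      if (k2 * dt > 1e-12) {
        double E = std::exp(-k2 * dt), I0 = (1 - E) / k2;
        y2 = E * y2 + ca[i] * I0 + m * (dt - I0) / k2;
      } else y2 = y2 + ca[i] * dt + m * dt * dt / 2;
    }
    out[i + 1] = c1 * y1 + c2 * y2;
  }
  return out;
}
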