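// Low-level numerical kernels: 2D convolution (im2col + BLAS gemm), depthwise
// convolution, fused batch-norm/SiLU, block-broadcast helpers and bicubic
// resampling. All feature maps cross the R/C++ boundary as (B*H*W) x C
// matrices, row index r = b*H*W + h*W + w (w fastest), one column per
// channel. Convolution weights are (C*k*k) x Cout matrices with row index
// c*k*k + di*k + dj. Padding is zero-fill.
//
// Inputs are taken as NumericMatrix and wrapped in non-owning Armadillo
// views, and outputs are allocated as R matrices up front, so no data is
// copied across the boundary (feature maps here are tens of MB per layer and
// boundary copies would dominate the runtime).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat aview(NumericMatrix m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the im2col buffer for image b. cols is (Ho*Wo) x (C*k*k).
static void im2col_one(const arma::mat& X, arma::mat& cols,
                       int b, int H, int W, int C,
                       int k, int stride, int pad, int Ho, int Wo) {
  const int base = b * H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        double* col = cols.colptr(c * k * k + di * k + dj);
        for (int ho = 0; ho < Ho; ++ho) {
          const int h = ho * stride - pad + di;
          double* dst = col + ho * Wo;
          if (h < 0 || h >= H) {
            std::fill(dst, dst + Wo, 0.0);
            continue;
          }
          const double* src = xc + base + h * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + dj;
            dst[wo] = (w >= 0 && w < W) ? src[w] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the column buffer back onto the input gradient (col2im).
static void col2im_one(const arma::mat& dcols, arma::mat& dX,
                       int b, int H, int W, int C,
                       int k, int stride, int pad, int Ho, int Wo) {
  const int base = b * H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dX.colptr(c);
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const double* col = dcols.colptr(c * k * k + di * k + dj);
        for (int ho = 0; ho < Ho; ++ho) {
          const int h = ho * stride - pad + di;
          if (h < 0 || h >= H) continue;
          const double* src = col + ho * Wo;
          double* dst = xc + base + h * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + dj;
            if (w >= 0 && w < W) dst[w] += src[wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericMatrix conv2d_fwd(NumericMatrix Xr, NumericMatrix Wr,
                         Nullable<NumericVector> bias,
                         int B, int H, int W, int k, int stride, int pad) {
  const arma::mat X = aview(Xr);
  const arma::mat Wm = aview(Wr);
  const int C = X.n_cols;
  const int Co = Wm.n_cols;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericMatrix Yr(B * Ho * Wo, Co);
  arma::mat Y = aview(Yr);
  if (k == 1 && stride == 1 && pad == 0) {
    Y = X * Wm;
  } else {
    arma::mat cols(Ho * Wo, C * k * k);
    for (int b = 0; b < B; ++b) {
      im2col_one(X, cols, b, H, W, C, k, stride, pad, Ho, Wo);
      Y.rows(b * Ho * Wo, (b + 1) * Ho * Wo - 1) = cols * Wm;
    }
  }
  if (bias.isNotNull()) {
    NumericVector bv(bias);
    for (int j = 0; j < Co; ++j) Y.col(j) += bv[j];
  }
  return Yr;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericMatrix Xr, NumericMatrix Wr, NumericMatrix dYr,
                bool has_bias, int B, int H, int W, int k, int stride, int pad) {
  const arma::mat X = aview(Xr);
  const arma::mat Wm = aview(Wr);
  const arma::mat dY = aview(dYr);
  const int C = X.n_cols;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericMatrix dXr(Xr.nrow(), C);
  NumericMatrix dWr(Wr.nrow(), Wr.ncol());
  arma::mat dX = aview(dXr);
  arma::mat dW = aview(dWr);
  if (k == 1 && stride == 1 && pad == 0) {
    dX = dY * Wm.t();
    dW = X.t() * dY;
  } else {
    arma::mat cols(Ho * Wo, C * k * k);
    for (int b = 0; b < B; ++b) {
      im2col_one(X, cols, b, H, W, C, k, stride, pad, Ho, Wo);
      const auto dYb = dY.rows(b * Ho * Wo, (b + 1) * Ho * Wo - 1);
      dW += cols.t() * dYb;
      arma::mat dcols = dYb * Wm.t();
      col2im_one(dcols, dX, b, H, W, C, k, stride, pad, Ho, Wo);
    }
  }
  List out = List::create(_["dx"] = dXr, _["dw"] = dWr);
  if (has_bias) {
    NumericVector dbr(dY.n_cols);
    for (arma::uword j = 0; j < dY.n_cols; ++j)
      dbr[j] = arma::accu(dY.col(j));
    out["db"] = dbr;
  }
  return out;
}

// [[Rcpp::export(name = ".depthwise_fwd")]]
NumericMatrix depthwise_fwd(NumericMatrix Xr, NumericMatrix Wr,
                            int B, int H, int W, int k, int stride, int pad) {
  const arma::mat X = aview(Xr);
  const arma::mat Wm = aview(Wr);
  const int C = X.n_cols;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericMatrix Yr(B * Ho * Wo, C);
  arma::mat Y = aview(Yr);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    for (int b = 0; b < B; ++b) {
      const int xbase = b * H * W, ybase = b * Ho * Wo;
      for (int di = 0; di < k; ++di) {
        for (int dj = 0; dj < k; ++dj) {
          const double wv = Wm(di * k + dj, c);
          if (wv == 0.0) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + di;
            if (h < 0 || h >= H) continue;
            const double* src = xc + xbase + h * W;
            double* dst = yc + ybase + ho * Wo;
            for (int wo = 0; wo < Wo; ++wo) {
              const int w = wo * stride - pad + dj;
              if (w >= 0 && w < W) dst[wo] += wv * src[w];
            }
          }
        }
      }
    }
  }
  return Yr;
}

// [[Rcpp::export(name = ".depthwise_bwd")]]
List depthwise_bwd(NumericMatrix Xr, NumericMatrix Wr, NumericMatrix dYr,
                   int B, int H, int W, int k, int stride, int pad) {
  const arma::mat X = aview(Xr);
  const arma::mat Wm = aview(Wr);
  const arma::mat dY = aview(dYr);
  const int C = X.n_cols;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericMatrix dXr(Xr.nrow(), C);
  NumericMatrix dWr(k * k, C);
  arma::mat dX = aview(dXr);
  arma::mat dW = aview(dWr);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    const double* gc = dY.colptr(c);
    double* dxc = dX.colptr(c);
    for (int b = 0; b < B; ++b) {
      const int xbase = b * H * W, ybase = b * Ho * Wo;
      for (int di = 0; di < k; ++di) {
        for (int dj = 0; dj < k; ++dj) {
          const double wv = Wm(di * k + dj, c);
          double acc = 0.0;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + di;
            if (h < 0 || h >= H) continue;
            const double* xrow = xc + xbase + h * W;
            double* dxrow = dxc + xbase + h * W;
            const double* grow = gc + ybase + ho * Wo;
            for (int wo = 0; wo < Wo; ++wo) {
              const int w = wo * stride - pad + dj;
              if (w >= 0 && w < W) {
                acc += grow[wo] * xrow[w];
                dxrow[w] += wv * grow[wo];
              }
            }
          }
          dW(di * k + dj, c) += acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dXr, _["dw"] = dWr);
}

// Batch-norm training forward: per-column standardization (biased variance).
// [[Rcpp::export(name = ".bn_fwd_train")]]
List bn_fwd_train(NumericMatrix Xr, NumericVector gamma, NumericVector beta,
                  double eps) {
  const arma::mat X = aview(Xr);
  const int n = X.n_rows, C = X.n_cols;
  NumericMatrix Yr(n, C), Xhr(n, C);
  NumericVector mu(C), var(C), invstd(C);
  arma::mat Y = aview(Yr), Xhat = aview(Xhr);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += x[i]; s2 += x[i] * x[i]; }
    const double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    const double inv = 1.0 / std::sqrt(v + eps);
    mu[c] = m; var[c] = v; invstd[c] = inv;
    const double g = gamma[c], b = beta[c];
    double* xh = Xhat.colptr(c);
    double* y = Y.colptr(c);
    for (int i = 0; i < n; ++i) {
      xh[i] = (x[i] - m) * inv;
      y[i] = xh[i] * g + b;
    }
  }
  return List::create(_["y"] = Yr, _["xhat"] = Xhr, _["mean"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericMatrix Xhr, NumericVector invstd, NumericVector gamma,
            NumericMatrix dYr) {
  const arma::mat Xhat = aview(Xhr);
  const arma::mat dY = aview(dYr);
  const int n = Xhat.n_rows, C = Xhat.n_cols;
  NumericMatrix dXr(n, C);
  NumericVector dgamma(C), dbeta(C);
  arma::mat dX = aview(dXr);
  for (int c = 0; c < C; ++c) {
    const double* xh = Xhat.colptr(c);
    const double* dy = dY.colptr(c);
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s1 += dy[i]; s2 += dy[i] * xh[i]; }
    dgamma[c] = s2; dbeta[c] = s1;
    const double m1 = s1 / n, m2 = s2 / n;
    const double gi = gamma[c] * invstd[c];
    double* dx = dX.colptr(c);
    for (int i = 0; i < n; ++i)
      dx[i] = gi * (dy[i] - m1 - xh[i] * m2);
  }
  return List::create(_["dx"] = dXr, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Fused batch-norm + SiLU (training). Only the normalized map is cached; the
// backward pass reconstructs the pre-activation from it.
// [[Rcpp::export(name = ".bn_silu_fwd_train")]]
List bn_silu_fwd_train(NumericMatrix Xr, NumericVector gamma,
                       NumericVector beta, double eps) {
  const arma::mat X = aview(Xr);
  const int n = X.n_rows, C = X.n_cols;
  NumericMatrix Zr(n, C), Xhr(n, C);
  NumericVector mu(C), var(C), invstd(C);
  arma::mat Z = aview(Zr), Xhat = aview(Xhr);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += x[i]; s2 += x[i] * x[i]; }
    const double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    const double inv = 1.0 / std::sqrt(v + eps);
    mu[c] = m; var[c] = v; invstd[c] = inv;
    const double g = gamma[c], b = beta[c];
    double* xh = Xhat.colptr(c);
    double* z = Z.colptr(c);
    for (int i = 0; i < n; ++i) {
      const double xhv = (x[i] - m) * inv;
      const double yv = xhv * g + b;
      xh[i] = xhv;
      z[i] = yv / (1.0 + std::exp(-yv));
    }
  }
  return List::create(_["z"] = Zr, _["xhat"] = Xhr, _["mean"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".bn_silu_bwd")]]
List bn_silu_bwd(NumericMatrix Xhr, NumericVector invstd, NumericVector gamma,
                 NumericVector beta, NumericMatrix dZr) {
  const arma::mat Xhat = aview(Xhr);
  const arma::mat dZ = aview(dZr);
  const int n = Xhat.n_rows, C = Xhat.n_cols;
  NumericMatrix dXr(n, C);
  NumericVector dgamma(C), dbeta(C);
  arma::mat dX = aview(dXr);
  for (int c = 0; c < C; ++c) {
    const double* xh = Xhat.colptr(c);
    const double* dz = dZ.colptr(c);
    const double g = gamma[c], b = beta[c];
    double* dx = dX.colptr(c);
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double y = xh[i] * g + b;
      const double sg = 1.0 / (1.0 + std::exp(-y));
      const double dy = dz[i] * sg * (1.0 + y * (1.0 - sg));
      dx[i] = dy;                      // holds dL/dy until the second pass
      s1 += dy; s2 += dy * xh[i];
    }
    dgamma[c] = s2; dbeta[c] = s1;
    const double m1 = s1 / n, m2 = s2 / n;
    const double gi = g * invstd[c];
    for (int i = 0; i < n; ++i)
      dx[i] = gi * (dx[i] - m1 - xh[i] * m2);
  }
  return List::create(_["dx"] = dXr, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".scale_shift_cols")]]
NumericMatrix scale_shift_cols(NumericMatrix Xr, NumericVector a,
                               NumericVector b) {
  const arma::mat X = aview(Xr);
  NumericMatrix Yr(Xr.nrow(), Xr.ncol());
  arma::mat Y = aview(Yr);
  for (arma::uword c = 0; c < X.n_cols; ++c)
    Y.col(c) = X.col(c) * a[c] + b[c];
  return Yr;
}

// [[Rcpp::export(name = ".silu_fwd")]]
NumericMatrix silu_fwd(NumericMatrix Xr) {
  NumericMatrix Yr(Xr.nrow(), Xr.ncol());
  const double* x = Xr.begin();
  double* y = Yr.begin();
  const R_xlen_t n = Xr.size();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] / (1.0 + std::exp(-x[i]));
  return Yr;
}

// [[Rcpp::export(name = ".silu_bwd")]]
NumericMatrix silu_bwd(NumericMatrix Xr, NumericMatrix dYr) {
  NumericMatrix dXr(Xr.nrow(), Xr.ncol());
  const double* x = Xr.begin();
  const double* dy = dYr.begin();
  double* dx = dXr.begin();
  const R_xlen_t n = Xr.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    dx[i] = dy[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  return dXr;
}

// Per-image-block channel scaling: multiply rows of block b by gains Z(b, c).
// [[Rcpp::export(name = ".block_scale")]]
NumericMatrix block_scale(NumericMatrix Xr, NumericMatrix Zr, int hw) {
  const arma::mat X = aview(Xr);
  const arma::mat Z = aview(Zr);
  NumericMatrix Yr(Xr.nrow(), Xr.ncol());
  arma::mat Y = aview(Yr);
  const int B = Z.n_rows;
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const double* x = X.colptr(c);
    double* y = Y.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double z = Z(b, c);
      const int off = b * hw;
      for (int i = 0; i < hw; ++i) y[off + i] = x[off + i] * z;
    }
  }
  return Yr;
}

// Y = X * Z_block + A_block (per-image-block channel affine).
// [[Rcpp::export(name = ".block_scale_add")]]
NumericMatrix block_scale_add(NumericMatrix Xr, NumericMatrix Zr,
                              NumericMatrix Ar, int hw) {
  const arma::mat X = aview(Xr);
  const arma::mat Z = aview(Zr);
  const arma::mat A = aview(Ar);
  NumericMatrix Yr(Xr.nrow(), Xr.ncol());
  arma::mat Y = aview(Yr);
  const int B = Z.n_rows;
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const double* x = X.colptr(c);
    double* y = Y.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double z = Z(b, c), a = A(b, c);
      const int off = b * hw;
      for (int i = 0; i < hw; ++i) y[off + i] = x[off + i] * z + a;
    }
  }
  return Yr;
}

// Per-image-block inner products per channel: out(b, c) over block rows.
// [[Rcpp::export(name = ".block_dot")]]
NumericMatrix block_dot(NumericMatrix Xr, NumericMatrix Yr2, int hw) {
  const arma::mat X = aview(Xr);
  const arma::mat Y = aview(Yr2);
  const int B = Xr.nrow() / hw;
  NumericMatrix outr(B, Xr.ncol());
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const double* x = X.colptr(c);
    const double* y = Y.colptr(c);
    for (int b = 0; b < B; ++b) {
      const int off = b * hw;
      double acc = 0.0;
      for (int i = 0; i < hw; ++i) acc += x[off + i] * y[off + i];
      outr(b, c) = acc;
    }
  }
  return outr;
}

// Expand a B x C matrix to (B*hw) x C by repeating each row over its block.
// [[Rcpp::export(name = ".block_expand")]]
NumericMatrix block_expand(NumericMatrix Zr, int hw) {
  const arma::mat Z = aview(Zr);
  const int B = Zr.nrow();
  NumericMatrix Yr(B * hw, Zr.ncol());
  arma::mat Y = aview(Yr);
  for (arma::uword c = 0; c < Z.n_cols; ++c) {
    double* y = Y.colptr(c);
    for (int b = 0; b < B; ++b)
      std::fill(y + b * hw, y + (b + 1) * hw, Z(b, c));
  }
  return Yr;
}

// Cubic-convolution interpolation kernel (total function of the offset).
static inline double cubic_w(double x, double a) {
  const double ax = std::fabs(x);
  if (ax <= 1.0) return (a + 2.0) * ax * ax * ax - (a + 3.0) * ax * ax + 1.0;
  if (ax < 2.0)  return a * ax * ax * ax - 5.0 * a * ax * ax + 8.0 * a * ax - 4.0 * a;
  return 0.0;
}

// Bicubic resampling of an H x W x C array (first index fastest, as in R)
// to Ho x Wo x C. Half-pixel center mapping, clamp-to-edge neighbours,
// output clamped to [lo, hi].
// [[Rcpp::export(name = ".resize_bicubic_cpp")]]
NumericVector resize_bicubic_cpp(NumericVector img, int H, int W, int C,
                                 int Ho, int Wo, double a,
                                 double lo, double hi) {
  NumericVector out(Ho * Wo * C);
  std::vector<double> wy(4 * Ho), wx(4 * Wo);
  std::vector<int> iy(4 * Ho), ix(4 * Wo);
  for (int o = 0; o < Ho; ++o) {
    const double sy = (o + 0.5) * (double)H / Ho - 0.5;
    const int fy = (int)std::floor(sy);
    for (int m = -1; m <= 2; ++m) {
      wy[4 * o + (m + 1)] = cubic_w(sy - (fy + m), a);
      iy[4 * o + (m + 1)] = std::min(std::max(fy + m, 0), H - 1);
    }
  }
  for (int o = 0; o < Wo; ++o) {
    const double sx = (o + 0.5) * (double)W / Wo - 0.5;
    const int fx = (int)std::floor(sx);
    for (int m = -1; m <= 2; ++m) {
      wx[4 * o + (m + 1)] = cubic_w(sx - (fx + m), a);
      ix[4 * o + (m + 1)] = std::min(std::max(fx + m, 0), W - 1);
    }
  }
  for (int c = 0; c < C; ++c) {
    const double* src = &img[c * H * W];
    double* dst = &out[c * Ho * Wo];
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        double v = 0.0;
        for (int mj = 0; mj < 4; ++mj) {
          const double wj = wx[4 * xo + mj];
          if (wj == 0.0) continue;
          const int col = ix[4 * xo + mj];
          double rowsum = 0.0;
          for (int mi = 0; mi < 4; ++mi)
            rowsum += wy[4 * yo + mi] * src[iy[4 * yo + mi] + H * col];
          v += wj * rowsum;
        }
        dst[yo + Ho * xo] = std::min(std::max(v, lo), hi);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}
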