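// Core dense tensor kernels: 2-D convolution and max-pooling, forward and
// backward, on (H, W, C, N) column-major arrays. Convolution is im2col + GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int in, int k, int s, int p, int d) {
  return (in + 2 * p - d * (k - 1) - 1) / s + 1;
}

// col: (kh*kw*Cpg) x (Ho*Wo) for one image and one channel group
static void im2col(const double* x, int H, int W, int Cpg, int c0,
                   int kh, int kw, int s, int p, int d,
                   int Ho, int Wo, arma::mat& col) {
  for (int ci = 0; ci < Cpg; ++ci) {
    const double* xc = x + (size_t)(c0 + ci) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + kj * d;
          double* dst = col.colptr(0) + r; // col(r, pos), pos = ho + Ho*wo
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) col(r, ho + Ho * wo) = 0.0;
            continue;
          }
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s - p + ki * d;
            col(r, ho + Ho * wo) =
              (hi < 0 || hi >= H) ? 0.0 : xc[hi + (size_t)H * wi];
          }
          (void)dst;
        }
      }
    }
  }
}

static void col2im_add(double* dx, int H, int W, int Cpg, int c0,
                       int kh, int kw, int s, int p, int d,
                       int Ho, int Wo, const arma::mat& col) {
  for (int ci = 0; ci < Cpg; ++ci) {
    double* xc = dx + (size_t)(c0 + ci) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + kj * d;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s - p + ki * d;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += col(r, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int dilation, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cpg = wd[2], Co = wd[3];
  if (C != Cpg * groups) stop("conv2d: input channels do not match weights/groups");
  if (Co % groups != 0) stop("conv2d: output channels not divisible by groups");
  int Copg = Co / groups;
  int Ho = conv_out_dim(H, kh, stride, pad, dilation);
  int Wo = conv_out_dim(W, kw, stride, pad, dilation);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  NumericVector y((R_xlen_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat col(kh * kw * Cpg, Ho * Wo);
  const double* xb = x.begin();
  double* yb = y.begin();
  const double* bptr = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bptr = bv.begin(); }
  for (int n = 0; n < N; ++n) {
    const double* xn = xb + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, Cpg, g * Cpg, kh, kw, stride, pad, dilation, Ho, Wo, col);
      arma::mat Wg(const_cast<double*>(w.begin()) +
                     (size_t)g * kh * kw * Cpg * Copg,
                   kh * kw * Cpg, Copg, false, true);
      arma::mat Yg = col.t() * Wg; // (Ho*Wo) x Copg
      for (int cl = 0; cl < Copg; ++cl) {
        int co = g * Copg + cl;
        double* dst = yb + (size_t)Ho * Wo * (co + (size_t)Co * n);
        const double* src = Yg.colptr(cl);
        if (bptr) {
          double b = bptr[co];
          for (int i = 0; i < Ho * Wo; ++i) dst[i] = src[i] + b;
        } else {
          std::memcpy(dst, src, sizeof(double) * Ho * Wo);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    bool has_bias, int stride, int pad, int dilation,
                    int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cpg = wd[2], Co = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int Copg = Co / groups;
  NumericVector dx((R_xlen_t)H * W * C * N), dw(w.size());
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Co : 0);
  arma::mat col(kh * kw * Cpg, Ho * Wo), dcol(kh * kw * Cpg, Ho * Wo);
  const double* xb = x.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xb + (size_t)n * H * W * C;
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, Cpg, g * Cpg, kh, kw, stride, pad, dilation, Ho, Wo, col);
      arma::mat Dyg(const_cast<double*>(dy.begin()) +
                      (size_t)Ho * Wo * ((size_t)g * Copg + (size_t)Co * n),
                    Ho * Wo, Copg, false, true);
      arma::mat Wg(const_cast<double*>(w.begin()) +
                     (size_t)g * kh * kw * Cpg * Copg,
                   kh * kw * Cpg, Copg, false, true);
      arma::mat dWg(dw.begin() + (size_t)g * kh * kw * Cpg * Copg,
                    kh * kw * Cpg, Copg, false, true);
      dWg += col * Dyg;
      dcol = Wg * Dyg.t();
      col2im_add(dxn, H, W, Cpg, g * Cpg, kh, kw, stride, pad, dilation, Ho, Wo,
                 dcol);
      if (has_bias)
        for (int cl = 0; cl < Copg; ++cl)
          db[g * Copg + cl] += arma::accu(Dyg.col(cl));
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2d_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = conv_out_dim(H, k, stride, pad, 1);
  int Wo = conv_out_dim(W, k, stride, pad, 1);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N); // argmax within (H,W) plane
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double* xp = x.begin() + (size_t)q * H * W;
    double* yp = y.begin() + (size_t)q * Ho * Wo;
    int* ip = idx.begin() + (size_t)q * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        int bi = -1;
        for (int kj = 0; kj < k; ++kj) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            double v = xp[hi + (size_t)H * wi];
            if (v > best) { best = v; bi = hi + H * wi; }
          }
        }
        yp[ho + (size_t)Ho * wo] = best;
        ip[ho + (size_t)Ho * wo] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2d_bwd_cpp(IntegerVector idx, NumericVector dy,
                                IntegerVector in_dim) {
  int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = in_dim;
  for (int q = 0; q < C * N; ++q) {
    const double* dyp = dy.begin() + (size_t)q * Ho * Wo;
    const int* ip = idx.begin() + (size_t)q * Ho * Wo;
    double* dxp = dx.begin() + (size_t)q * H * W;
    for (int i = 0; i < Ho * Wo; ++i)
      if (ip[i] >= 0) dxp[ip[i]] += dyp[i];
  }
  return dx;
}
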