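// Numerical kernels for the network: grouped 2-D convolution (forward,
// backward) and batch normalization (statistics, affine application,
// backward). Tensors are plain R arrays in H x W x C x N layout
// (column-major); convolution weights are k x k x (Cin/groups) x Cout.
//
// Padding follows the "same"/ceil convention: output side = ceil(in/stride),
// total padding = max(0, (out-1)*stride + k - in), split floor(total/2) at
// the leading edge (so 224 -> 112 -> 56 and 15 -> 8 for k=3, stride 2).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_side(int in, int stride) {
  return (in + stride - 1) / stride;
}

static inline int pad_begin(int in, int k, int stride) {
  int out = out_side(in, stride);
  int total = (out - 1) * stride + k - in;
  if (total < 0) total = 0;
  return total / 2;
}

// Fill K (k*k*cing x Ho*Wo*N) with the im2col expansion of input channels
// [cstart, cstart+cing) of x. Row index kh + k*kw + k*k*ci matches the
// flattening of a k x k x cing x coutg weight slab.
static void im2col_group(const double* x, int H, int W, int C, int N,
                         int k, int stride, int pt, int pl,
                         int Ho, int Wo, int cstart, int cing,
                         arma::mat& K) {
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t col = (size_t)ho + (size_t)Ho * ((size_t)wo + (size_t)Wo * n);
        double* Kc = K.colptr(col);
        for (int ci = 0; ci < cing; ++ci) {
          const double* xc =
              x + ((size_t)(cstart + ci) + (size_t)C * n) * (size_t)H * W;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pl + kw;
            bool wok = (wi >= 0 && wi < W);
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pt + kh;
              size_t row = (size_t)kh + (size_t)k * ((size_t)kw + (size_t)k * ci);
              Kc[row] = (wok && hi >= 0 && hi < H)
                            ? xc[(size_t)hi + (size_t)H * wi]
                            : 0.0;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 int stride, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], cing = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (C != cing * groups) stop("input channels do not match weight groups");
  if (Cout % groups != 0) stop("output channels not divisible by groups");
  int coutg = Cout / groups;
  int Ho = out_side(H, stride), Wo = out_side(W, stride);
  int pt = pad_begin(H, k, stride), pl = pad_begin(W, k, stride);

  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* op = out.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();

  size_t ncols = (size_t)Ho * Wo * N;
  arma::mat K(k * k * cing, ncols);
  for (int g = 0; g < groups; ++g) {
    im2col_group(xp, H, W, C, N, k, stride, pt, pl, Ho, Wo, g * cing, cing, K);
    arma::mat Wm(const_cast<double*>(wp) +
                     (size_t)g * coutg * k * k * cing,
                 k * k * cing, coutg, false, true);
    arma::mat O = Wm.t() * K;  // coutg x ncols
    for (int oc = 0; oc < coutg; ++oc) {
      int c = g * coutg + oc;
      for (int n = 0; n < N; ++n) {
        double* dst = op + ((size_t)c + (size_t)Cout * n) * (size_t)Ho * Wo;
        size_t base = (size_t)Ho * Wo * n;
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dst[i] = O(oc, base + i);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dout,
                         int stride, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], cing = wd[2], Cout = wd[3];
  int coutg = Cout / groups;
  int Ho = out_side(H, stride), Wo = out_side(W, stride);
  int pt = pad_begin(H, k, stride), pl = pad_begin(W, k, stride);

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((size_t)k * k * cing * Cout);
  dw.attr("dim") = IntegerVector::create(k, k, cing, Cout);

  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dop = dout.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();

  size_t ncols = (size_t)Ho * Wo * N;
  arma::mat K(k * k * cing, ncols);
  arma::mat dO(coutg, ncols);
  for (int g = 0; g < groups; ++g) {
    // gather dout rows for this group's output channels
    for (int oc = 0; oc < coutg; ++oc) {
      int c = g * coutg + oc;
      for (int n = 0; n < N; ++n) {
        const double* src = dop + ((size_t)c + (size_t)Cout * n) * (size_t)Ho * Wo;
        size_t base = (size_t)Ho * Wo * n;
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dO(oc, base + i) = src[i];
      }
    }
    im2col_group(xp, H, W, C, N, k, stride, pt, pl, Ho, Wo, g * cing, cing, K);
    arma::mat dWm = K * dO.t();  // (k*k*cing) x coutg
    std::copy(dWm.begin(), dWm.end(),
              dwp + (size_t)g * coutg * k * k * cing);

    arma::mat Wm(const_cast<double*>(wp) + (size_t)g * coutg * k * k * cing,
                 k * k * cing, coutg, false, true);
    arma::mat dK = Wm * dO;  // (k*k*cing) x ncols, scatter back (col2im)
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          size_t col = (size_t)ho + (size_t)Ho * ((size_t)wo + (size_t)Wo * n);
          const double* Kc = dK.colptr(col);
          for (int ci = 0; ci < cing; ++ci) {
            double* dxc = dxp +
                ((size_t)(g * cing + ci) + (size_t)C * n) * (size_t)H * W;
            for (int kw = 0; kw < k; ++kw) {
              int wi = wo * stride - pl + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                int hi = ho * stride - pt + kh;
                if (hi < 0 || hi >= H) continue;
                size_t row = (size_t)kh + (size_t)k * ((size_t)kw + (size_t)k * ci);
                dxc[(size_t)hi + (size_t)H * wi] += Kc[row];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Per-channel mean and biased variance over the H, W, N axes.
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector mean(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + ((size_t)c + (size_t)C * n) * plane;
      for (size_t i = 0; i < plane; ++i) {
        s += p[i];
        s2 += p[i] * p[i];
      }
    }
    double m = (double)plane * N;
    mean[c] = s / m;
    var[c] = s2 / m - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// out[h,w,c,n] = x[h,w,c,n] * scale[c] + shift[c]
// [[Rcpp::export]]
NumericVector cpp_channel_affine(NumericVector x, NumericVector scale,
                                 NumericVector shift) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector out((size_t)H * W * C * N);
  out.attr("dim") = xd;
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double a = scale[c], b = shift[c];
      const double* p = xp + ((size_t)c + (size_t)C * n) * plane;
      double* q = op + ((size_t)c + (size_t)C * n) * plane;
      for (size_t i = 0; i < plane; ++i) q[i] = p[i] * a + b;
    }
  }
  return out;
}

// Training-mode batch-norm backward using the batch statistics cached at the
// forward pass. Returns dx, dgamma, dbeta.
// [[Rcpp::export]]
List cpp_bn_backward(NumericVector x, NumericVector dout, NumericVector mean,
                     NumericVector var, NumericVector gamma, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dp = dout.begin();
  double* dxp = dx.begin();

  for (int c = 0; c < C; ++c) {
    double sd = std::sqrt(var[c] + eps);
    double mu = mean[c];
    double s1 = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = xp + ((size_t)c + (size_t)C * n) * plane;
      const double* pd = dp + ((size_t)c + (size_t)C * n) * plane;
      for (size_t i = 0; i < plane; ++i) {
        double xh = (px[i] - mu) / sd;
        s1 += pd[i];
        s2 += pd[i] * xh;
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    double a = gamma[c] / sd;
    for (int n = 0; n < N; ++n) {
      const double* px = xp + ((size_t)c + (size_t)C * n) * plane;
      const double* pd = dp + ((size_t)c + (size_t)C * n) * plane;
      double* pq = dxp + ((size_t)c + (size_t)C * n) * plane;
      for (size_t i = 0; i < plane; ++i) {
        double xh = (px[i] - mu) / sd;
        pq[i] = a * (pd[i] - s1 / m - xh * s2 / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
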