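// Convolution and pooling kernels for the tiny detector training engine.
// Tensor layout: column-major R arrays with dim (H, W, C, N), so
// index(h, w, c, n) = h + H*(w + W*(c + C*n)).

#include <Rcpp.h>
using namespace Rcpp;

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// weight layout: dim (kh, kw, cpg, Cout)
static inline int widx(int kh, int kw, int ci, int co, int KH, int KW, int CPG) {
  return kh + KH * (kw + KW * (ci + CPG * co));
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector bias, int stride, int pad,
                            int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int KH = wdim[0], KW = wdim[1], CPG = wdim[2], CO = wdim[3];
  const int Ho = (H + 2 * pad - KH) / stride + 1;
  const int Wo = (W + 2 * pad - KW) / stride + 1;
  const int copg = CO / groups;
  NumericVector y(Ho * (R_xlen_t)Wo * CO * N);
  const double *px = x.begin(), *pw = w.begin(), *pb = bias.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < CO; ++co) {
      const int g = co / copg, ci0 = g * CPG;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = pb[co];
          const int hi0 = ho * stride - pad, wi0 = wo * stride - pad;
          for (int ci = 0; ci < CPG; ++ci)
            for (int kw = 0; kw < KW; ++kw) {
              const int wi = wi0 + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < KH; ++kh) {
                const int hi = hi0 + kh;
                if (hi < 0 || hi >= H) continue;
                acc += px[idx4(hi, wi, ci0 + ci, n, H, W, C)] *
                       pw[widx(kh, kw, ci, co, KH, KW, CPG)];
              }
            }
          py[ho + Ho * (wo + Wo * (co + CO * (R_xlen_t)n))] = acc;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, CO, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xdim, NumericVector w,
                   IntegerVector wdim, NumericVector gy, int stride, int pad,
                   int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int KH = wdim[0], KW = wdim[1], CPG = wdim[2], CO = wdim[3];
  const int Ho = (H + 2 * pad - KH) / stride + 1;
  const int Wo = (W + 2 * pad - KW) / stride + 1;
  const int copg = CO / groups;
  NumericVector gx(x.size()), gw(w.size()), gb(CO);
  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < CO; ++co) {
      const int g = co / copg, ci0 = g * CPG;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double gval = pg[ho + Ho * (wo + Wo * (co + CO * (R_xlen_t)n))];
          if (gval == 0.0) continue;
          pgb[co] += gval;
          const int hi0 = ho * stride - pad, wi0 = wo * stride - pad;
          for (int ci = 0; ci < CPG; ++ci)
            for (int kw = 0; kw < KW; ++kw) {
              const int wi = wi0 + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < KH; ++kh) {
                const int hi = hi0 + kh;
                if (hi < 0 || hi >= H) continue;
                const int xi = idx4(hi, wi, ci0 + ci, n, H, W, C);
                const int wi_ = widx(kh, kw, ci, co, KH, KW, CPG);
                pgx[xi] += gval * pw[wi_];
                pgw[wi_] += gval * px[xi];
              }
            }
        }
    }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, IntegerVector xdim, int k, int stride,
                    int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(Ho * (R_xlen_t)Wo * C * N);
  IntegerVector argmax(y.size());
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = argmax.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int bi = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              const int xi = idx4(hi, wi, c, n, H, W, C);
              if (px[xi] > best) { best = px[xi]; bi = xi; }
            }
          }
          // index order here is (ho, wo) within (c, n): matches layout below
          py[ho + Ho * (wo + Wo * (c + C * (R_xlen_t)n))] = best;
          pa[ho + Ho * (wo + Wo * (c + C * (R_xlen_t)n))] = bi;
          (void)o;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = argmax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gy, IntegerVector argmax,
                             IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  const double *pg = gy.begin();
  const int *pa = argmax.begin();
  double *pgx = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    if (pa[i] >= 0) pgx[pa[i]] += pg[i];
  gx.attr("dim") = xdim;
  return gx;
}
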