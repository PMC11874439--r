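#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// 3-d convolution primitives for the grid CNNs. Arrays use R's column-major
// layout with dim (C, N, N, N): idx = c + C*(x + N*(y + N*z)). Kernels are
// 3x3x3, stride 1, zero padding 1, weights dim (F, C, 3, 3, 3).

static inline R_xlen_t vidx(int c, int x, int y, int z, int C, int N) {
  return c + (R_xlen_t)C * (x + (R_xlen_t)N * (y + (R_xlen_t)N * z));
}
static inline R_xlen_t widx(int f, int c, int kx, int ky, int kz, int F, int C) {
  return f + (R_xlen_t)F * (c + (R_xlen_t)C * (kx + 3 * (ky + 3 * kz)));
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xd,
                            NumericVector w, NumericVector b, int F) {
  int C = xd[0], N = xd[1];
  NumericVector y(F * (R_xlen_t)N * N * N);
  const double* X = x.begin(); const double* W = w.begin();
  double* Y = y.begin();
  for (int z = 0; z < N; ++z)
    for (int yy = 0; yy < N; ++yy)
      for (int xx = 0; xx < N; ++xx) {
        for (int f = 0; f < F; ++f) Y[vidx(f, xx, yy, z, F, N)] = b[f];
        for (int kz = 0; kz < 3; ++kz) {
          int z2 = z + kz - 1; if (z2 < 0 || z2 >= N) continue;
          for (int ky = 0; ky < 3; ++ky) {
            int y2 = yy + ky - 1; if (y2 < 0 || y2 >= N) continue;
            for (int kx = 0; kx < 3; ++kx) {
              int x2 = xx + kx - 1; if (x2 < 0 || x2 >= N) continue;
              const double* xin = X + vidx(0, x2, y2, z2, C, N);
              for (int c = 0; c < C; ++c) {
                double xv = xin[c];
                if (xv == 0.0) continue;
                const double* wp = W + widx(0, c, kx, ky, kz, F, C);
                double* yp = Y + vidx(0, xx, yy, z, F, N);
                for (int f = 0; f < F; ++f) yp[f] += wp[f] * xv;
              }
            }
          }
        }
      }
  y.attr("dim") = IntegerVector::create(F, N, N, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xd, NumericVector w,
                   int F, NumericVector gy) {
  int C = xd[0], N = xd[1];
  NumericVector gx(x.size()), gw(w.size()), gb(F);
  const double* X = x.begin(); const double* W = w.begin();
  const double* GY = gy.begin();
  double* GX = gx.begin(); double* GW = gw.begin();
  for (int z = 0; z < N; ++z)
    for (int yy = 0; yy < N; ++yy)
      for (int xx = 0; xx < N; ++xx) {
        const double* gyp = GY + vidx(0, xx, yy, z, F, N);
        for (int f = 0; f < F; ++f) gb[f] += gyp[f];
        for (int kz = 0; kz < 3; ++kz) {
          int z2 = z + kz - 1; if (z2 < 0 || z2 >= N) continue;
          for (int ky = 0; ky < 3; ++ky) {
            int y2 = yy + ky - 1; if (y2 < 0 || y2 >= N) continue;
            for (int kx = 0; kx < 3; ++kx) {
              int x2 = xx + kx - 1; if (x2 < 0 || x2 >= N) continue;
              const double* xin = X + vidx(0, x2, y2, z2, C, N);
              double* gxp = GX + vidx(0, x2, y2, z2, C, N);
              for (int c = 0; c < C; ++c) {
                const double* wp = W + widx(0, c, kx, ky, kz, F, C);
                double* gwp = GW + widx(0, c, kx, ky, kz, F, C);
                double xv = xin[c], gxv = 0;
                for (int f = 0; f < F; ++f) {
                  double g = gyp[f];
                  gxv += wp[f] * g;
                  gwp[f] += xv * g;
                }
                gxp[c] += gxv;
              }
            }
          }
        }
      }
  gx.attr("dim") = xd;
  gw.attr("dim") = IntegerVector::create(F, C, 3, 3, 3);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x max pooling; N must be even. Returns pooled values and argmax indices
// (1-based into the input vector) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, IntegerVector xd) {
  int C = xd[0], N = xd[1], M = N / 2;
  NumericVector y(C * (R_xlen_t)M * M * M);
  IntegerVector amax(y.size());
  const double* X = x.begin();
  for (int z = 0; z < M; ++z)
    for (int yy = 0; yy < M; ++yy)
      for (int xx = 0; xx < M; ++xx)
        for (int c = 0; c < C; ++c) {
          double best = -1e300; R_xlen_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                R_xlen_t ii = vidx(c, 2 * xx + dx, 2 * yy + dy, 2 * z + dz, C, N);
                if (X[ii] > best) { best = X[ii]; bi = ii; }
              }
          R_xlen_t oi = vidx(c, xx, yy, z, C, M);
          y[oi] = best; amax[oi] = (int)(bi + 1);
        }
  y.attr("dim") = IntegerVector::create(C, M, M, M);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector argmax, NumericVector gy,
                             IntegerVector xd) {
  NumericVector gx((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i] - 1] += gy[i];
  gx.attr("dim") = xd;
  return gx;
}
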