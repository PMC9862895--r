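// Compiled kernels: voxel occupancy grids and the 3D convolution /
// max-pooling layers used by the ligandability CNN. Array layout is
// R column-major with dims (D, H, W, C, N).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline long idx5(int d, int h, int w, int c, int n,
                        int D, int H, int W, int C) {
  return d + (long)D * (h + (long)H * (w + (long)W * (c + (long)C * n)));
}

// [[Rcpp::export]]
NumericVector occupancy_grid_cpp(NumericMatrix coords, NumericVector radii,
                                 IntegerMatrix chan, NumericVector center,
                                 double spacing, int size) {
  const int K = chan.ncol();
  const int natom = coords.nrow();
  NumericVector out((long)size * size * size * K);
  const double half = (size - 1) / 2.0;
  // occupancy(d) >= 1e-8  <=>  d <= r * 1e8^(1/12)
  const double cut_factor = std::pow(1e8, 1.0 / 12.0);
  for (int a = 0; a < natom; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const double r = radii[a];
    const double cut = r * cut_factor;
    // voxel index window overlapping the cutoff sphere
    int lo[3], hi[3];
    const double pos[3] = {ax, ay, az};
    bool empty = false;
    for (int ax3 = 0; ax3 < 3; ++ax3) {
      double rel = (pos[ax3] - center[ax3]) / spacing + half;
      lo[ax3] = (int)std::ceil(rel - cut / spacing);
      hi[ax3] = (int)std::floor(rel + cut / spacing);
      if (lo[ax3] < 0) lo[ax3] = 0;
      if (hi[ax3] > size - 1) hi[ax3] = size - 1;
      if (lo[ax3] > hi[ax3]) empty = true;
    }
    if (empty) continue;
    for (int k = 0; k < K; ++k) {
      if (!chan(a, k)) continue;
      for (int iz = lo[2]; iz <= hi[2]; ++iz) {
        const double dz = center[2] + spacing * (iz - half) - az;
        for (int iy = lo[1]; iy <= hi[1]; ++iy) {
          const double dy = center[1] + spacing * (iy - half) - ay;
          for (int ix = lo[0]; ix <= hi[0]; ++ix) {
            const double dx = center[0] + spacing * (ix - half) - ax;
            const double d2 = dx * dx + dy * dy + dz * dz;
            double occ;
            if (d2 <= 0) {
              occ = 1.0;
            } else {
              const double q = (r * r) / d2;
              const double t = q * q * q * q * q * q;
              // second-order expansion of 1 - exp(-t) for small t
              // (relative error < 2e-7 at the switch point)
              occ = t < 0.01 ? t * (1.0 - 0.5 * t) : 1.0 - std::exp(-t);
            }
            if (occ < 1e-8) continue;
            long o = ix + (long)size * (iy + (long)size * (iz + (long)size * k));
            if (occ > out[o]) out[o] = occ;
          }
        }
      }
    }
  }
  return out;
}

// 3x3x3 convolution, stride 1, zero padding 1: output spatial = input.
// One contiguous inner loop per kernel tap so the compiler can vectorize.
// [[Rcpp::export]]
NumericVector conv3d_fw_cpp(NumericVector x, IntegerVector xdim,
                            NumericVector w, NumericVector b, int cout) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3], N = xdim[4];
  const long DHW = (long)D * H * W;
  NumericVector y((long)DHW * cout * N);
  const double* xp0 = &x[0];
  const double* wp = &w[0];
  double* yp0 = &y[0];
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < cout; ++co) {
      double* yc = yp0 + DHW * (co + (long)cout * n);
      const double bias = b[co];
      for (long i = 0; i < DHW; ++i) yc[i] = bias;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = xp0 + DHW * (ci + (long)Cin * n);
        for (int kw = 0; kw < 3; ++kw) {
          const int wlo = kw == 0 ? 1 : 0, whi = kw == 2 ? W - 2 : W - 1;
          for (int kh = 0; kh < 3; ++kh) {
            const int hlo = kh == 0 ? 1 : 0, hhi = kh == 2 ? H - 2 : H - 1;
            for (int kd = 0; kd < 3; ++kd) {
              const int dlo = kd == 0 ? 1 : 0, dhi = kd == 2 ? D - 2 : D - 1;
              const double wv = wp[kd + 3L * (kh + 3L * (kw + 3L * (ci + (long)Cin * co)))];
              if (wv == 0) continue;
              for (int ww = wlo; ww <= whi; ++ww)
                for (int hh = hlo; hh <= hhi; ++hh) {
                  double* yb = yc + (long)D * (hh + (long)H * ww);
                  const double* xb = xc + (kd - 1) +
                    (long)D * ((hh + kh - 1) + (long)H * (ww + kw - 1));
                  for (int dd = dlo; dd <= dhi; ++dd) yb[dd] += wv * xb[dd];
                }
            }
          }
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
List conv3d_bw_cpp(NumericVector x, IntegerVector xdim, NumericVector w,
                   int cout, NumericVector gy) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3], N = xdim[4];
  const long DHW = (long)D * H * W;
  NumericVector gx((long)DHW * Cin * N);
  NumericVector gw(27L * Cin * cout);
  NumericVector gb(cout);
  const double* xp0 = &x[0];
  const double* wp = &w[0];
  const double* gyp0 = &gy[0];
  double* gxp0 = &gx[0];
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < cout; ++co) {
      const double* gyc = gyp0 + DHW * (co + (long)cout * n);
      double gbacc = 0;
      for (long i = 0; i < DHW; ++i) gbacc += gyc[i];
      gb[co] += gbacc;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = xp0 + DHW * (ci + (long)Cin * n);
        double* gxc = gxp0 + DHW * (ci + (long)Cin * n);
        for (int kw = 0; kw < 3; ++kw) {
          const int wlo = kw == 0 ? 1 : 0, whi = kw == 2 ? W - 2 : W - 1;
          for (int kh = 0; kh < 3; ++kh) {
            const int hlo = kh == 0 ? 1 : 0, hhi = kh == 2 ? H - 2 : H - 1;
            for (int kd = 0; kd < 3; ++kd) {
              const int dlo = kd == 0 ? 1 : 0, dhi = kd == 2 ? D - 2 : D - 1;
              const long wi = kd + 3L * (kh + 3L * (kw + 3L * (ci + (long)Cin * co)));
              const double wv = wp[wi];
              double gwacc = 0;
              for (int ww = wlo; ww <= whi; ++ww)
                for (int hh = hlo; hh <= hhi; ++hh) {
                  const double* gyb = gyc + (long)D * (hh + (long)H * ww);
                  const long off = (kd - 1) +
                    (long)D * ((hh + kh - 1) + (long)H * (ww + kw - 1));
                  const double* xb = xc + off;
                  double* gxb = gxc + off;
                  for (int dd = dlo; dd <= dhi; ++dd) {
                    gwacc += gyb[dd] * xb[dd];
                    gxb[dd] += wv * gyb[dd];
                  }
                }
              gw[wi] += gwacc;
            }
          }
        }
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling, stride 2, floor semantics
// [[Rcpp::export]]
List maxpool_fw_cpp(NumericVector x, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int D2 = D / 2, H2 = H / 2, W2 = W / 2;
  NumericVector y((long)D2 * H2 * W2 * C * N);
  IntegerVector arg((long)D2 * H2 * W2 * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ww = 0; ww < W2; ++ww)
        for (int hh = 0; hh < H2; ++hh)
          for (int dd = 0; dd < D2; ++dd) {
            double best = -1e300;
            long besti = -1;
            for (int kw = 0; kw < 2; ++kw)
              for (int kh = 0; kh < 2; ++kh)
                for (int kd = 0; kd < 2; ++kd) {
                  const long xi = idx5(2 * dd + kd, 2 * hh + kh, 2 * ww + kw,
                                       c, n, D, H, W, C);
                  if (x[xi] > best) { best = x[xi]; besti = xi; }
                }
            const long yi = idx5(dd, hh, ww, c, n, D2, H2, W2, C);
            y[yi] = best;
            arg[yi] = (int)besti;
          }
  return List::create(_["y"] = y, _["argmax"] = arg,
                      _["ydim"] = IntegerVector::create(D2, H2, W2, C, N));
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(NumericVector gy, IntegerVector argmax,
                             IntegerVector xdim) {
  const long nx = (long)xdim[0] * xdim[1] * xdim[2] * xdim[3] * xdim[4];
  NumericVector gx(nx);
  for (long i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  return gx;
}
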