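#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as column-major R arrays with dims (X, Y, Z, C, N):
// spatial axes first (X fastest), then channel, then sample. 2D images use
// Z = 1. All kernels below share that layout.

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Unfold sliding conv windows into a matrix with one row per output voxel
// (rows ordered x-fastest, sample outermost) and one column per kernel
// element x input channel (kx fastest, channel outermost).
// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_im2col3d(NumericVector x, IntegerVector xdim,
                           IntegerVector k, IntegerVector stride,
                           IntegerVector pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const int KX = k[0], KY = k[1], KZ = k[2];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  const int PX = pad[0], PY = pad[1], PZ = pad[2];
  const int OX = out_extent(X, KX, SX, PX);
  const int OY = out_extent(Y, KY, SY, PY);
  const int OZ = out_extent(Z, KZ, SZ, PZ);
  const R_xlen_t nrow = (R_xlen_t)N * OX * OY * OZ;
  const int ncol = KX * KY * KZ * C;
  NumericMatrix out(nrow, ncol);
  const double *xp = x.begin();
  double *op = out.begin();
  const R_xlen_t planeXY = (R_xlen_t)X * Y;
  const R_xlen_t volXYZ = planeXY * Z;
  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < KZ; ++kz) {
      for (int ky = 0; ky < KY; ++ky) {
        for (int kx = 0; kx < KX; ++kx) {
          const int col = kx + KX * (ky + KY * (kz + KZ * c));
          double *ocol = op + (R_xlen_t)col * nrow;
          for (int n = 0; n < N; ++n) {
            const double *xn = xp + ((R_xlen_t)n * C + c) * volXYZ;
            for (int oz = 0; oz < OZ; ++oz) {
              const int iz = oz * SZ - PZ + kz;
              const bool zok = (iz >= 0 && iz < Z);
              for (int oy = 0; oy < OY; ++oy) {
                const int iy = oy * SY - PY + ky;
                const bool yok = (iy >= 0 && iy < Y);
                R_xlen_t row = (R_xlen_t)OX *
                  (oy + (R_xlen_t)OY * (oz + (R_xlen_t)OZ * n));
                if (!zok || !yok) {
                  for (int ox = 0; ox < OX; ++ox) ocol[row + ox] = 0.0;
                  continue;
                }
                const double *base = xn + (R_xlen_t)iz * planeXY +
                  (R_xlen_t)iy * X;
                for (int ox = 0; ox < OX; ++ox) {
                  const int ix = ox * SX - PX + kx;
                  ocol[row + ox] =
                    (ix >= 0 && ix < X) ? base[ix] : 0.0;
                }
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col3d: scatter-add a column matrix back onto the input
// grid (used for the gradient with respect to the convolution input).
// [[Rcpp::export(rng = false)]]
NumericVector cpp_col2im3d(NumericMatrix cols, IntegerVector xdim,
                           IntegerVector k, IntegerVector stride,
                           IntegerVector pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const int KX = k[0], KY = k[1], KZ = k[2];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  const int PX = pad[0], PY = pad[1], PZ = pad[2];
  const int OX = out_extent(X, KX, SX, PX);
  const int OY = out_extent(Y, KY, SY, PY);
  const int OZ = out_extent(Z, KZ, SZ, PZ);
  const R_xlen_t nrow = (R_xlen_t)N * OX * OY * OZ;
  NumericVector x((R_xlen_t)X * Y * Z * C * N);
  double *xp = x.begin();
  const double *cp = cols.begin();
  const R_xlen_t planeXY = (R_xlen_t)X * Y;
  const R_xlen_t volXYZ = planeXY * Z;
  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < KZ; ++kz) {
      for (int ky = 0; ky < KY; ++ky) {
        for (int kx = 0; kx < KX; ++kx) {
          const int col = kx + KX * (ky + KY * (kz + KZ * c));
          const double *ccol = cp + (R_xlen_t)col * nrow;
          for (int n = 0; n < N; ++n) {
            double *xn = xp + ((R_xlen_t)n * C + c) * volXYZ;
            for (int oz = 0; oz < OZ; ++oz) {
              const int iz = oz * SZ - PZ + kz;
              if (iz < 0 || iz >= Z) continue;
              for (int oy = 0; oy < OY; ++oy) {
                const int iy = oy * SY - PY + ky;
                if (iy < 0 || iy >= Y) continue;
                const R_xlen_t row = (R_xlen_t)OX *
                  (oy + (R_xlen_t)OY * (oz + (R_xlen_t)OZ * n));
                double *base = xn + (R_xlen_t)iz * planeXY +
                  (R_xlen_t)iy * X;
                for (int ox = 0; ox < OX; ++ox) {
                  const int ix = ox * SX - PX + kx;
                  if (ix >= 0 && ix < X) base[ix] += ccol[row + ox];
                }
              }
            }
          }
        }
      }
    }
  }
  return x;
}

// Depthwise convolution: one filter per channel, w is (KX*KY*KZ) x C.
// Also backs average pooling (uniform fixed weights).
// [[Rcpp::export(rng = false)]]
NumericVector cpp_dwconv3d(NumericVector x, IntegerVector xdim,
                           NumericMatrix w, IntegerVector k,
                           IntegerVector stride, IntegerVector pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const int KX = k[0], KY = k[1], KZ = k[2];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  const int PX = pad[0], PY = pad[1], PZ = pad[2];
  const int OX = out_extent(X, KX, SX, PX);
  const int OY = out_extent(Y, KY, SY, PY);
  const int OZ = out_extent(Z, KZ, SZ, PZ);
  NumericVector out((R_xlen_t)OX * OY * OZ * C * N);
  const double *xp = x.begin();
  double *op = out.begin();
  const R_xlen_t planeXY = (R_xlen_t)X * Y, volXYZ = planeXY * Z;
  const R_xlen_t oplaneXY = (R_xlen_t)OX * OY, ovolXYZ = oplaneXY * OZ;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xn = xp + ((R_xlen_t)n * C + c) * volXYZ;
      double *on = op + ((R_xlen_t)n * C + c) * ovolXYZ;
      const double *wc = &w(0, c);
      for (int oz = 0; oz < OZ; ++oz) {
        for (int oy = 0; oy < OY; ++oy) {
          for (int ox = 0; ox < OX; ++ox) {
            double acc = 0.0;
            int wi = 0;
            for (int kz = 0; kz < KZ; ++kz) {
              const int iz = oz * SZ - PZ + kz;
              for (int ky = 0; ky < KY; ++ky) {
                const int iy = oy * SY - PY + ky;
                for (int kx = 0; kx < KX; ++kx, ++wi) {
                  const int ix = ox * SX - PX + kx;
                  if (ix >= 0 && ix < X && iy >= 0 && iy < Y &&
                      iz >= 0 && iz < Z)
                    acc += wc[wi] *
                      xn[(R_xlen_t)iz * planeXY + (R_xlen_t)iy * X + ix];
                }
              }
            }
            on[(R_xlen_t)oz * oplaneXY + (R_xlen_t)oy * OX + ox] = acc;
          }
        }
      }
    }
  }
  return out;
}

// Gradient of cpp_dwconv3d with respect to its input (weights fixed).
// [[Rcpp::export(rng = false)]]
NumericVector cpp_dwconv3d_bwd_x(NumericVector gy, IntegerVector xdim,
                                 NumericMatrix w, IntegerVector k,
                                 IntegerVector stride, IntegerVector pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const int KX = k[0], KY = k[1], KZ = k[2];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  const int PX = pad[0], PY = pad[1], PZ = pad[2];
  const int OX = out_extent(X, KX, SX, PX);
  const int OY = out_extent(Y, KY, SY, PY);
  const int OZ = out_extent(Z, KZ, SZ, PZ);
  NumericVector gx((R_xlen_t)X * Y * Z * C * N);
  double *gp = gx.begin();
  const double *yp = gy.begin();
  const R_xlen_t planeXY = (R_xlen_t)X * Y, volXYZ = planeXY * Z;
  const R_xlen_t oplaneXY = (R_xlen_t)OX * OY, ovolXYZ = oplaneXY * OZ;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double *gn = gp + ((R_xlen_t)n * C + c) * volXYZ;
      const double *yn = yp + ((R_xlen_t)n * C + c) * ovolXYZ;
      const double *wc = &w(0, c);
      for (int oz = 0; oz < OZ; ++oz) {
        for (int oy = 0; oy < OY; ++oy) {
          for (int ox = 0; ox < OX; ++ox) {
            const double g =
              yn[(R_xlen_t)oz * oplaneXY + (R_xlen_t)oy * OX + ox];
            if (g == 0.0) continue;
            int wi = 0;
            for (int kz = 0; kz < KZ; ++kz) {
              const int iz = oz * SZ - PZ + kz;
              for (int ky = 0; ky < KY; ++ky) {
                const int iy = oy * SY - PY + ky;
                for (int kx = 0; kx < KX; ++kx, ++wi) {
                  const int ix = ox * SX - PX + kx;
                  if (ix >= 0 && ix < X && iy >= 0 && iy < Y &&
                      iz >= 0 && iz < Z)
                    gn[(R_xlen_t)iz * planeXY + (R_xlen_t)iy * X + ix] +=
                      g * wc[wi];
                }
              }
            }
          }
        }
      }
    }
  }
  return gx;
}

// Max pooling; returns the pooled values and 1-based argmax indices into the
// flattened input (for the backward scatter). Padded positions count as -Inf.
// [[Rcpp::export(rng = false)]]
List cpp_maxpool3d(NumericVector x, IntegerVector xdim, IntegerVector k,
                   IntegerVector stride, IntegerVector pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const int KX = k[0], KY = k[1], KZ = k[2];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  const int PX = pad[0], PY = pad[1], PZ = pad[2];
  const int OX = out_extent(X, KX, SX, PX);
  const int OY = out_extent(Y, KY, SY, PY);
  const int OZ = out_extent(Z, KZ, SZ, PZ);
  const R_xlen_t olen = (R_xlen_t)OX * OY * OZ * C * N;
  NumericVector out(olen);
  NumericVector amax(olen);  // double to hold large indices safely
  const double *xp = x.begin();
  const R_xlen_t planeXY = (R_xlen_t)X * Y, volXYZ = planeXY * Z;
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * volXYZ;
      for (int oz = 0; oz < OZ; ++oz) {
        for (int oy = 0; oy < OY; ++oy) {
          for (int ox = 0; ox < OX; ++ox, ++o) {
            double best = R_NegInf;
            R_xlen_t bidx = -1;
            for (int kz = 0; kz < KZ; ++kz) {
              const int iz = oz * SZ - PZ + kz;
              if (iz < 0 || iz >= Z) continue;
              for (int ky = 0; ky < KY; ++ky) {
                const int iy = oy * SY - PY + ky;
                if (iy < 0 || iy >= Y) continue;
                for (int kx = 0; kx < KX; ++kx) {
                  const int ix = ox * SX - PX + kx;
                  if (ix < 0 || ix >= X) continue;
                  const R_xlen_t idx = base + (R_xlen_t)iz * planeXY +
                    (R_xlen_t)iy * X + ix;
                  if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
                }
              }
            }
            out[o] = best;
            amax[o] = (double)(bidx + 1);
          }
        }
      }
    }
  }
  return List::create(_["values"] = out, _["argmax"] = amax);
}

// Scatter pooled-output gradients back to the argmax positions.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_maxpool3d_bwd(NumericVector gy, NumericVector argmax,
                                double xlen) {
  NumericVector gx((R_xlen_t)xlen);
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const R_xlen_t idx = (R_xlen_t)argmax[i] - 1;
    if (idx >= 0) gx[idx] += gy[i];
  }
  return gx;
}

// Trilinear resampling of a single-channel volume at arbitrary (0-based)
// source coordinates; out-of-volume samples return `fill`. Drives rotation,
// elastic deformation and resizing.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_warp3d(NumericVector x, IntegerVector xdim,
                         NumericVector mapx, NumericVector mapy,
                         NumericVector mapz, double fill) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  const R_xlen_t n = mapx.size();
  NumericVector out(n);
  const double *xp = x.begin();
  const R_xlen_t planeXY = (R_xlen_t)X * Y;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double sx = mapx[i], sy = mapy[i], sz = mapz[i];
    if (sx < 0 || sy < 0 || sz < 0 || sx > X - 1 || sy > Y - 1 ||
        sz > Z - 1) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
        z0 = (int)std::floor(sz);
    if (x0 == X - 1) x0--;
    if (y0 == Y - 1) y0--;
    if (z0 == Z - 1) z0--;
    if (X == 1) x0 = 0;
    if (Y == 1) y0 = 0;
    if (Z == 1) z0 = 0;
    const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
    const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1),
              z1 = std::min(z0 + 1, Z - 1);
    const double c000 = xp[(R_xlen_t)z0 * planeXY + (R_xlen_t)y0 * X + x0];
    const double c100 = xp[(R_xlen_t)z0 * planeXY + (R_xlen_t)y0 * X + x1];
    const double c010 = xp[(R_xlen_t)z0 * planeXY + (R_xlen_t)y1 * X + x0];
    const double c110 = xp[(R_xlen_t)z0 * planeXY + (R_xlen_t)y1 * X + x1];
    const double c001 = xp[(R_xlen_t)z1 * planeXY + (R_xlen_t)y0 * X + x0];
    const double c101 = xp[(R_xlen_t)z1 * planeXY + (R_xlen_t)y0 * X + x1];
    const double c011 = xp[(R_xlen_t)z1 * planeXY + (R_xlen_t)y1 * X + x0];
    const double c111 = xp[(R_xlen_t)z1 * planeXY + (R_xlen_t)y1 * X + x1];
    const double c00 = c000 * (1 - fx) + c100 * fx;
    const double c10 = c010 * (1 - fx) + c110 * fx;
    const double c01 = c001 * (1 - fx) + c101 * fx;
    const double c11 = c011 * (1 - fx) + c111 * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Per-pixel maximum over an inclusive axial slab: the MIP workhorse.
// x has dims (X, Y, Z); returns (X, Y) maxima over z in [zlo, zhi] (0-based).
// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_mip_axial(NumericVector x, IntegerVector xdim,
                            int zlo, int zhi) {
  const int X = xdim[0], Y = xdim[1];
  const R_xlen_t planeXY = (R_xlen_t)X * Y;
  NumericMatrix out(X, Y);
  std::fill(out.begin(), out.end(), R_NegInf);
  const double *xp = x.begin();
  double *op = out.begin();
  for (int z = zlo; z <= zhi; ++z) {
    const double *pz = xp + (R_xlen_t)z * planeXY;
    for (R_xlen_t i = 0; i < planeXY; ++i)
      if (pz[i] > op[i]) op[i] = pz[i];
  }
  return out;
}
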