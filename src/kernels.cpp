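#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grids are cubic (or square), even-sized, with the zero-frequency (or
// real-space center) voxel at index n/2 (0-based) along each axis, i.e.
// index i corresponds to coordinate i - n/2.
//
// Slice extraction/insertion use Kaiser-Bessel gridding (width kb_w
// grid units, shape kb_beta) on a zero-padded transform; the matching
// real-space correction (the kernel's continuous transform) is applied
// in R (gridding_weights), which must stay in sync with the callers.

static inline double kb_i0(double x) {
#ifdef __cpp_lib_math_special_functions
  return std::cyl_bessel_i(0.0, x);
#else
  double s = 1.0, term = 1.0;
  for (int k = 1; k < 60; ++k) {
    term *= (x / (2.0 * k)) * (x / (2.0 * k));
    s += term;
    if (term < 1e-16 * s) break;
  }
  return s;
#endif
}

static inline double kb_kernel(double u, double kb_w, double kb_beta) {
  const double t = 2.0 * u / kb_w;
  const double q = 1.0 - t * t;
  if (q <= 0.0) return 0.0;
  return kb_i0(kb_beta * std::sqrt(q));
}

// Kaiser-Bessel sample of a centered complex 3D grid (re, im) on the
// central slice defined by rotation rows r1 = M[1,], r2 = M[2,]: the
// slice point for 2D frequency (kx, ky) is kx*r1 + ky*r2. Returns an
// nout x nout complex matrix (centered). Points outside the grid are 0.
// [[Rcpp::export(name = ".cpp_slice_sample")]]
ComplexMatrix cpp_slice_sample(NumericVector re, NumericVector im,
                               IntegerVector dim, NumericMatrix rot,
                               int nout, double kb_w, double kb_beta) {
  const int n = dim[0];
  const int c = n / 2;
  const int co = nout / 2;
  const int rad = (int)(kb_w / 2);
  ComplexMatrix out(nout, nout);
  const double r11 = rot(0, 0), r12 = rot(0, 1), r13 = rot(0, 2);
  const double r21 = rot(1, 0), r22 = rot(1, 1), r23 = rot(1, 2);
  const double *pre = REAL(re), *pim = REAL(im);
  const R_xlen_t n2 = (R_xlen_t)n * n;
  double wx[8], wy[8], wz[8];
  for (int j = 0; j < nout; ++j) {
    const double ky = j - co;
    for (int i = 0; i < nout; ++i) {
      const double kx = i - co;
      const double x = kx * r11 + ky * r21 + c;
      const double y = kx * r12 + ky * r22 + c;
      const double z = kx * r13 + ky * r23 + c;
      const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                z0 = (int)std::floor(z);
      double accre = 0.0, accim = 0.0;
      if (x0 - rad + 1 >= 0 && x0 + rad < n && y0 - rad + 1 >= 0 &&
          y0 + rad < n && z0 - rad + 1 >= 0 && z0 + rad < n) {
        for (int t = 0; t < 2 * rad; ++t) {
          const int o = t - rad + 1;
          wx[t] = kb_kernel(x0 + o - x, kb_w, kb_beta);
          wy[t] = kb_kernel(y0 + o - y, kb_w, kb_beta);
          wz[t] = kb_kernel(z0 + o - z, kb_w, kb_beta);
        }
        for (int dz = 0; dz < 2 * rad; ++dz) {
          for (int dy = 0; dy < 2 * rad; ++dy) {
            const double wyz = wy[dy] * wz[dz];
            const R_xlen_t base = (R_xlen_t)n * (y0 + dy - rad + 1) +
                                  n2 * (z0 + dz - rad + 1) + (x0 - rad + 1);
            for (int dx = 0; dx < 2 * rad; ++dx) {
              const double w = wx[dx] * wyz;
              accre += w * pre[base + dx];
              accim += w * pim[base + dx];
            }
          }
        }
      }
      Rcomplex v; v.r = accre; v.i = accim;
      out(i, j) = v;
    }
  }
  return out;
}

// Adjoint of cpp_slice_sample: spread a weighted complex slice into the
// 3D numerator (nre, nim) and its scalar weights into wt, in place.
// [[Rcpp::export(name = ".cpp_slice_insert")]]
void cpp_slice_insert(NumericVector nre, NumericVector nim, NumericVector wt,
                      IntegerVector dim, ComplexMatrix slice,
                      NumericMatrix slice_wt, NumericMatrix rot,
                      double kb_w, double kb_beta) {
  const int n = dim[0];
  const int c = n / 2;
  const int ns = slice.nrow();
  const int cs = ns / 2;
  const int rad = (int)(kb_w / 2);
  const double r11 = rot(0, 0), r12 = rot(0, 1), r13 = rot(0, 2);
  const double r21 = rot(1, 0), r22 = rot(1, 1), r23 = rot(1, 2);
  double *pre = REAL(nre), *pim = REAL(nim), *pwt = REAL(wt);
  const R_xlen_t n2 = (R_xlen_t)n * n;
  double wx[8], wy[8], wz[8];
  for (int j = 0; j < ns; ++j) {
    const double ky = j - cs;
    for (int i = 0; i < ns; ++i) {
      const double kx = i - cs;
      const double x = kx * r11 + ky * r21 + c;
      const double y = kx * r12 + ky * r22 + c;
      const double z = kx * r13 + ky * r23 + c;
      const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                z0 = (int)std::floor(z);
      if (x0 - rad + 1 < 0 || x0 + rad >= n || y0 - rad + 1 < 0 ||
          y0 + rad >= n || z0 - rad + 1 < 0 || z0 + rad >= n)
        continue;
      for (int t = 0; t < 2 * rad; ++t) {
        const int o = t - rad + 1;
        wx[t] = kb_kernel(x0 + o - x, kb_w, kb_beta);
        wy[t] = kb_kernel(y0 + o - y, kb_w, kb_beta);
        wz[t] = kb_kernel(z0 + o - z, kb_w, kb_beta);
      }
      const Rcomplex v = slice(i, j);
      const double w0 = slice_wt(i, j);
      for (int dz = 0; dz < 2 * rad; ++dz) {
        for (int dy = 0; dy < 2 * rad; ++dy) {
          const double wyz = wy[dy] * wz[dz];
          const R_xlen_t base = (R_xlen_t)n * (y0 + dy - rad + 1) +
                                n2 * (z0 + dz - rad + 1) + (x0 - rad + 1);
          for (int dx = 0; dx < 2 * rad; ++dx) {
            const double w = wx[dx] * wyz;
            pre[base + dx] += w * v.r;
            pim[base + dx] += w * v.i;
            pwt[base + dx] += w * w0;
          }
        }
      }
    }
  }
}

// Real-space trilinear resampling of a cubic volume under a rotation:
// out(q) = vol(t(R) %*% q), coordinates relative to the center voxel
// n/2. Points sampling outside the grid become 0.
// [[Rcpp::export(name = ".cpp_resample_rotated")]]
NumericVector cpp_resample_rotated(NumericVector vol, IntegerVector dim,
                                   NumericMatrix rot) {
  const int n = dim[0];
  const int c = n / 2;
  NumericVector out((R_xlen_t)n * n * n);
  const double *pv = REAL(vol);
  double *po = REAL(out);
  const R_xlen_t n2 = (R_xlen_t)n * n;
  // rows of t(R) are columns of R
  const double a11 = rot(0, 0), a21 = rot(0, 1), a31 = rot(0, 2);
  const double a12 = rot(1, 0), a22 = rot(1, 1), a32 = rot(1, 2);
  const double a13 = rot(2, 0), a23 = rot(2, 1), a33 = rot(2, 2);
  R_xlen_t o = 0;
  for (int k = 0; k < n; ++k) {
    const double qz = k - c;
    for (int j = 0; j < n; ++j) {
      const double qy = j - c;
      for (int i = 0; i < n; ++i, ++o) {
        const double qx = i - c;
        const double x = a11 * qx + a12 * qy + a13 * qz + c;
        const double y = a21 * qx + a22 * qy + a23 * qz + c;
        const double z = a31 * qx + a32 * qy + a33 * qz + c;
        const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                  z0 = (int)std::floor(z);
        if (x0 < 0 || x0 + 1 >= n || y0 < 0 || y0 + 1 >= n || z0 < 0 ||
            z0 + 1 >= n) {
          po[o] = 0.0;
          continue;
        }
        const double fx = x - x0, fy = y - y0, fz = z - z0;
        double acc = 0.0;
        for (int dz = 0; dz <= 1; ++dz) {
          const double wz = dz ? fz : 1.0 - fz;
          for (int dy = 0; dy <= 1; ++dy) {
            const double wy = dy ? fy : 1.0 - fy;
            for (int dx = 0; dx <= 1; ++dx) {
              const double w = (dx ? fx : 1.0 - fx) * wy * wz;
              const R_xlen_t idx = (R_xlen_t)(x0 + dx) +
                                   (R_xlen_t)n * (y0 + dy) + n2 * (z0 + dz);
              acc += w * pv[idx];
            }
          }
        }
        po[o] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
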