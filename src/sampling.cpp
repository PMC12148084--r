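#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zero-padded trilinear lookup on a column-major 3D grid.
// u,v,w are continuous voxel coordinates (0-based, voxel-center convention).
static inline double tri_sample(const double* vol, int nx, int ny, int nz,
                                double u, double v, double w) {
  if (u <= -1.0 || v <= -1.0 || w <= -1.0 ||
      u >= (double)nx || v >= (double)ny || w >= (double)nz)
    return 0.0;
  int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
  double fu = u - i0, fv = v - j0, fw = w - k0;
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk) {
    int k = k0 + dk;
    if (k < 0 || k >= nz) continue;
    double wk = dk ? fw : 1.0 - fw;
    for (int dj = 0; dj < 2; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= ny) continue;
      double wj = dj ? fv : 1.0 - fv;
      for (int di = 0; di < 2; ++di) {
        int i = i0 + di;
        if (i < 0 || i >= nx) continue;
        double wi = di ? fu : 1.0 - fu;
        acc += wi * wj * wk * vol[i + nx * (j + (R_xlen_t)ny * k)];
      }
    }
  }
  return acc;
}

// Spatial gradient of the trilinear interpolant in voxel units.
static inline void tri_grad(const double* vol, int nx, int ny, int nz,
                            double u, double v, double w, double* g) {
  g[0] = g[1] = g[2] = 0.0;
  if (u <= -1.0 || v <= -1.0 || w <= -1.0 ||
      u >= (double)nx || v >= (double)ny || w >= (double)nz)
    return;
  int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
  double fu = u - i0, fv = v - j0, fw = w - k0;
  for (int dk = 0; dk < 2; ++dk) {
    int k = k0 + dk;
    if (k < 0 || k >= nz) continue;
    double wk = dk ? fw : 1.0 - fw;
    double dwk = dk ? 1.0 : -1.0;
    for (int dj = 0; dj < 2; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= ny) continue;
      double wj = dj ? fv : 1.0 - fv;
      double dwj = dj ? 1.0 : -1.0;
      for (int di = 0; di < 2; ++di) {
        int i = i0 + di;
        if (i < 0 || i >= nx) continue;
        double wi = di ? fu : 1.0 - fu;
        double dwi = di ? 1.0 : -1.0;
        double val = vol[i + nx * (j + (R_xlen_t)ny * k)];
        g[0] += dwi * wj * wk * val;
        g[1] += wi * dwj * wk * val;
        g[2] += wi * wj * dwk * val;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t m = pts.nrow();
  NumericVector out(m);
  const double* v = vol.begin();
  for (R_xlen_t p = 0; p < m; ++p) {
    double u = (pts(p, 0) - origin[0]) / spacing[0];
    double vv = (pts(p, 1) - origin[1]) / spacing[1];
    double w = (pts(p, 2) - origin[2]) / spacing[2];
    out[p] = tri_sample(v, nx, ny, nz, u, vv, w);
  }
  return out;
}

// Gradient with respect to the world-coordinate query point (per mm).
// [[Rcpp::export]]
NumericMatrix cpp_trilinear_grad(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t m = pts.nrow();
  NumericMatrix out(m, 3);
  const double* v = vol.begin();
  double g[3];
  for (R_xlen_t p = 0; p < m; ++p) {
    double u = (pts(p, 0) - origin[0]) / spacing[0];
    double vv = (pts(p, 1) - origin[1]) / spacing[1];
    double w = (pts(p, 2) - origin[2]) / spacing[2];
    tri_grad(v, nx, ny, nz, u, vv, w, g);
    out(p, 0) = g[0] / spacing[0];
    out(p, 1) = g[1] / spacing[1];
    out(p, 2) = g[2] / spacing[2];
  }
  return out;
}

// Fused value + world-space gradient (single neighbourhood fetch).
// [[Rcpp::export]]
List cpp_trilinear_valgrad(NumericVector vol, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t m = pts.nrow();
  NumericVector val(m);
  NumericMatrix grad(m, 3);
  const double* v = vol.begin();
  for (R_xlen_t p = 0; p < m; ++p) {
    double u = (pts(p, 0) - origin[0]) / spacing[0];
    double vv = (pts(p, 1) - origin[1]) / spacing[1];
    double w = (pts(p, 2) - origin[2]) / spacing[2];
    if (u <= -1.0 || vv <= -1.0 || w <= -1.0 ||
        u >= (double)nx || vv >= (double)ny || w >= (double)nz)
      continue;
    int i0 = (int)std::floor(u), j0 = (int)std::floor(vv),
        k0 = (int)std::floor(w);
    double fu = u - i0, fv = vv - j0, fw = w - k0;
    double acc = 0, g0 = 0, g1 = 0, g2 = 0;
    for (int dk = 0; dk < 2; ++dk) {
      int k = k0 + dk;
      if (k < 0 || k >= nz) continue;
      double wk = dk ? fw : 1.0 - fw;
      double dwk = dk ? 1.0 : -1.0;
      for (int dj = 0; dj < 2; ++dj) {
        int j = j0 + dj;
        if (j < 0 || j >= ny) continue;
        double wj = dj ? fv : 1.0 - fv;
        double dwj = dj ? 1.0 : -1.0;
        for (int di = 0; di < 2; ++di) {
          int i = i0 + di;
          if (i < 0 || i >= nx) continue;
          double wi = di ? fu : 1.0 - fu;
          double dwi = di ? 1.0 : -1.0;
          double x = v[i + nx * (j + (R_xlen_t)ny * k)];
          acc += wi * wj * wk * x;
          g0 += dwi * wj * wk * x;
          g1 += wi * dwj * wk * x;
          g2 += wi * wj * dwk * x;
        }
      }
    }
    val[p] = acc;
    grad(p, 0) = g0 / spacing[0];
    grad(p, 1) = g1 / spacing[1];
    grad(p, 2) = g2 / spacing[2];
  }
  return List::create(Named("value") = val, Named("grad") = grad);
}

// Nearest-neighbour lookup (labelmap warping); 0 outside.
// [[Rcpp::export]]
IntegerVector cpp_nearest(IntegerVector vol, IntegerVector dim,
                          NumericVector spacing, NumericVector origin,
                          NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t m = pts.nrow();
  IntegerVector out(m);
  for (R_xlen_t p = 0; p < m; ++p) {
    int i = (int)std::lround((pts(p, 0) - origin[0]) / spacing[0]);
    int j = (int)std::lround((pts(p, 1) - origin[1]) / spacing[1]);
    int k = (int)std::lround((pts(p, 2) - origin[2]) / spacing[2]);
    out[p] = (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
                 ? 0
                 : vol[i + nx * (j + (R_xlen_t)ny * k)];
  }
  return out;
}
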