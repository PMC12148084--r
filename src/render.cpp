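#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Beer-Lambert line-integral renderer with interpolating quadrature.
// Rays r(lambda) = S + lambda (P - S), lambda in [0,1]; each ray is clipped
// to the support box of the zero-padded trilinear interpolant
// [origin - spacing, origin + dim * spacing] and sampled at M uniformly
// spaced lambdas; pixel value = ||P - S|| * sum_{m=1}^{M-1} V[r(lambda_m)] dlambda.

static inline double tri_sample2(const double* vol, int nx, int ny, int nz,
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

static inline void tri_splat(double* grid, int nx, int ny, int nz,
                             double u, double v, double w, double val) {
  if (u <= -1.0 || v <= -1.0 || w <= -1.0 ||
      u >= (double)nx || v >= (double)ny || w >= (double)nz)
    return;
  int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
  double fu = u - i0, fv = v - j0, fw = w - k0;
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
        grid[i + nx * (j + (R_xlen_t)ny * k)] += wi * wj * wk * val;
      }
    }
  }
}

// Clip lambda in [0,1] against the axis-aligned support box; returns false
// if the ray misses the box entirely.
static inline bool clip_ray(const double* S, const double* D,
                            const double* lo, const double* hi,
                            bool clip, double& l0, double& l1) {
  l0 = 0.0;
  l1 = 1.0;
  if (!clip) return true;
  for (int a = 0; a < 3; ++a) {
    double d = D[a];
    if (std::fabs(d) < 1e-12) {
      if (S[a] < lo[a] || S[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - S[a]) / d;
      double tb = (hi[a] - S[a]) / d;
      if (ta > tb) std::swap(ta, tb);
      if (ta > l0) l0 = ta;
      if (tb < l1) l1 = tb;
      if (l0 >= l1) return false;
    }
  }
  return true;
}

static inline int ray_samples(double chord_mm, double step_mm, int n_samples) {
  if (n_samples > 0) return n_samples;
  int m = (int)std::ceil(chord_mm / step_mm) + 1;
  return m < 2 ? 2 : m;
}

// [[Rcpp::export]]
NumericVector cpp_render(NumericVector vol, IntegerVector dim,
                         NumericVector spacing, NumericVector origin,
                         NumericMatrix src, NumericMatrix dst,
                         double step_mm, int n_samples, bool clip) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - spacing[a];
    hi[a] = origin[a] + dim[a] * spacing[a];
  }
  R_xlen_t P = dst.nrow();
  NumericVector out(P);
  const double* v = vol.begin();
  for (R_xlen_t p = 0; p < P; ++p) {
    double S[3], D[3];
    for (int a = 0; a < 3; ++a) {
      S[a] = src(src.nrow() == 1 ? 0 : p, a);
      D[a] = dst(p, a) - S[a];
    }
    double len = std::sqrt(D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
    double l0, l1;
    if (!clip_ray(S, D, lo, hi, clip, l0, l1)) continue;
    int M = ray_samples((l1 - l0) * len, step_mm, n_samples);
    double dl = (l1 - l0) / (M - 1);
    double acc = 0.0;
    for (int m = 0; m < M - 1; ++m) {
      double lam = l0 + m * dl;
      double u = (S[0] + lam * D[0] - origin[0]) / spacing[0];
      double vv = (S[1] + lam * D[1] - origin[1]) / spacing[1];
      double w = (S[2] + lam * D[2] - origin[2]) / spacing[2];
      acc += tri_sample2(v, nx, ny, nz, u, vv, w);
    }
    out[p] = len * dl * acc;
  }
  return out;
}

// Adjoint of cpp_render with respect to the volume values: given the
// gradient of a scalar loss in each pixel, splat it back onto the voxel grid
// through the same quadrature and trilinear weights.
// [[Rcpp::export]]
NumericVector cpp_render_adjoint(IntegerVector dim, NumericVector spacing,
                                 NumericVector origin, NumericMatrix src,
                                 NumericMatrix dst, double step_mm,
                                 int n_samples, bool clip,
                                 NumericVector gpix) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - spacing[a];
    hi[a] = origin[a] + dim[a] * spacing[a];
  }
  R_xlen_t P = dst.nrow();
  NumericVector grid((R_xlen_t)nx * ny * nz);
  double* g = grid.begin();
  for (R_xlen_t p = 0; p < P; ++p) {
    double gp = gpix[p];
    if (gp == 0.0) continue;
    double S[3], D[3];
    for (int a = 0; a < 3; ++a) {
      S[a] = src(src.nrow() == 1 ? 0 : p, a);
      D[a] = dst(p, a) - S[a];
    }
    double len = std::sqrt(D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
    double l0, l1;
    if (!clip_ray(S, D, lo, hi, clip, l0, l1)) continue;
    int M = ray_samples((l1 - l0) * len, step_mm, n_samples);
    double dl = (l1 - l0) / (M - 1);
    double coef = gp * len * dl;
    for (int m = 0; m < M - 1; ++m) {
      double lam = l0 + m * dl;
      double u = (S[0] + lam * D[0] - origin[0]) / spacing[0];
      double vv = (S[1] + lam * D[1] - origin[1]) / spacing[1];
      double w = (S[2] + lam * D[2] - origin[2]) / spacing[2];
      tri_splat(g, nx, ny, nz, u, vv, w, coef);
    }
  }
  return grid;
}
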