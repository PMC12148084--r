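#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-form SE(3) exponential. With xi = (w, rho), theta = ||w||,
//   A = sin(theta)/theta, B = (1-cos(theta))/theta^2,
//   C = (theta-sin(theta))/theta^3,
// the rotation is R = cos(theta) I + A [w]x + B w w^T and the translation
// t = V rho with V = A I + B [w]x + C w w^T. A Taylor branch below
// theta < 1e-6 avoids division by zero.
struct Se3Coef {
  double ct, A, B, C;
};

static inline Se3Coef se3_coef(double th2) {
  Se3Coef c;
  if (th2 < 1e-12) {
    c.ct = 1.0 - th2 / 2.0;
    c.A = 1.0 - th2 / 6.0;
    c.B = 0.5 - th2 / 24.0;
    c.C = 1.0 / 6.0 - th2 / 120.0;
  } else {
    double th = std::sqrt(th2);
    double s = std::sin(th), co = std::cos(th);
    c.ct = co;
    c.A = s / th;
    c.B = (1.0 - co) / th2;
    c.C = (th - s) / (th2 * th);
  }
  return c;
}

// out = exp(xi) applied to point p (matrix-free closed form).
static inline void exp_apply(const double* xi, const double* p, double* out) {
  const double wx = xi[0], wy = xi[1], wz = xi[2];
  const double rx = xi[3], ry = xi[4], rz = xi[5];
  Se3Coef c = se3_coef(wx * wx + wy * wy + wz * wz);
  const double px = p[0], py = p[1], pz = p[2];
  // R p = ct p + A (w x p) + B (w . p) w
  double cxp0 = wy * pz - wz * py, cxp1 = wz * px - wx * pz,
         cxp2 = wx * py - wy * px;
  double wdp = wx * px + wy * py + wz * pz;
  // t = A rho + B (w x rho) + C (w . rho) w
  double cxr0 = wy * rz - wz * ry, cxr1 = wz * rx - wx * rz,
         cxr2 = wx * ry - wy * rx;
  double wdr = wx * rx + wy * ry + wz * rz;
  out[0] = c.ct * px + c.A * cxp0 + c.B * wdp * wx + c.A * rx + c.B * cxr0 +
           c.C * wdr * wx;
  out[1] = c.ct * py + c.A * cxp1 + c.B * wdp * wy + c.A * ry + c.B * cxr1 +
           c.C * wdr * wy;
  out[2] = c.ct * pz + c.A * cxp2 + c.B * wdp * wz + c.A * rz + c.B * cxr2 +
           c.C * wdr * wz;
}

// Full matrix form, row-major R (9) and t (3).
static inline void exp_se3_one(const double* xi, double* R, double* t) {
  const double wx = xi[0], wy = xi[1], wz = xi[2];
  Se3Coef c = se3_coef(wx * wx + wy * wy + wz * wz);
  R[0] = c.ct + c.B * wx * wx;
  R[1] = -c.A * wz + c.B * wx * wy;
  R[2] = c.A * wy + c.B * wx * wz;
  R[3] = c.A * wz + c.B * wy * wx;
  R[4] = c.ct + c.B * wy * wy;
  R[5] = -c.A * wx + c.B * wy * wz;
  R[6] = -c.A * wy + c.B * wz * wx;
  R[7] = c.A * wx + c.B * wz * wy;
  R[8] = c.ct + c.B * wz * wz;
  const double rx = xi[3], ry = xi[4], rz = xi[5];
  double cxr0 = wy * rz - wz * ry, cxr1 = wz * rx - wx * rz,
         cxr2 = wx * ry - wy * rx;
  double wdr = wx * rx + wy * ry + wz * rz;
  t[0] = c.A * rx + c.B * cxr0 + c.C * wdr * wx;
  t[1] = c.A * ry + c.B * cxr1 + c.C * wdr * wy;
  t[2] = c.A * rz + c.B * cxr2 + c.C * wdr * wz;
}

// [[Rcpp::export]]
NumericMatrix cpp_exp_se3_batch(NumericMatrix xi) {
  int n = xi.nrow();
  if (xi.ncol() != 6) stop("twist table must have 6 columns");
  NumericMatrix out(n, 12);  // R row-major (9), then t (3)
  double x[6], R[9], t[3];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 6; ++j) {
      x[j] = xi(i, j);
      if (!std::isfinite(x[j])) stop("non-finite twist entry");
    }
    exp_se3_one(x, R, t);
    for (int j = 0; j < 9; ++j) out(i, j) = R[j];
    for (int j = 0; j < 3; ++j) out(i, 9 + j) = t[j];
  }
  return out;
}

// Apply exp(xi_i) to point p_i for each row.
// [[Rcpp::export]]
NumericMatrix cpp_twist_apply(NumericMatrix xi, NumericMatrix pts) {
  int n = xi.nrow();
  if (pts.nrow() != n) stop("row count mismatch");
  if (xi.ncol() != 6 || pts.ncol() != 3) stop("bad dimensions");
  NumericMatrix out(n, 3);
  const double* xic = xi.begin();
  const double* pc = pts.begin();
  double* oc = out.begin();
  double x[6], p[3], o[3];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 6; ++j) x[j] = xic[i + (R_xlen_t)n * j];
    for (int j = 0; j < 3; ++j) p[j] = pc[i + (R_xlen_t)n * j];
    exp_apply(x, p, o);
    for (int j = 0; j < 3; ++j) oc[i + (R_xlen_t)n * j] = o[j];
  }
  return out;
}

// Sensitivity contraction for the polyrigid objective: given per-voxel mixed
// twists Xi, voxel positions X and the backpropagated spatial gradient
// `base` (M x 3, d loss / d Phi(x)), returns S (M x 6) with
//   S[i, j] = base_i . d(exp(Xi_i) x_i)/d Xi_ij,
// the differential of the exponential evaluated by forward differences with
// step h on the mixed twist (exact to O(h); the map is smooth).
// [[Rcpp::export]]
NumericMatrix cpp_twist_sens(NumericMatrix xi, NumericMatrix pts,
                             NumericMatrix base, double h) {
  int n = xi.nrow();
  if (pts.nrow() != n || base.nrow() != n) stop("row count mismatch");
  NumericMatrix out(n, 6);
  const double* xic = xi.begin();
  const double* pc = pts.begin();
  const double* bc = base.begin();
  double* oc = out.begin();
  double x[6], p[3], b[3], o0[3], o1[3];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 6; ++j) x[j] = xic[i + (R_xlen_t)n * j];
    for (int j = 0; j < 3; ++j) {
      p[j] = pc[i + (R_xlen_t)n * j];
      b[j] = bc[i + (R_xlen_t)n * j];
    }
    if (b[0] == 0.0 && b[1] == 0.0 && b[2] == 0.0) continue;
    exp_apply(x, p, o0);
    for (int j = 0; j < 6; ++j) {
      x[j] += h;
      exp_apply(x, p, o1);
      x[j] -= h;
      oc[i + (R_xlen_t)n * j] =
          (b[0] * (o1[0] - o0[0]) + b[1] * (o1[1] - o0[1]) +
           b[2] * (o1[2] - o0[2])) / h;
    }
  }
  return out;
}
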