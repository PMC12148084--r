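#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), separable over axes, with anisotropic physical
// spacing. Operates on squared distances; infinite inputs (no seed in the
// scanline yet) are skipped rather than inserted as parabolas.

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform on samples at physical positions i*s.
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& vbuf, std::vector<double>& zbuf) {
  int* v = vbuf.data();
  double* z = zbuf.data();
  double s2 = s * s;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double sq = 0.0;
    while (k >= 0) {
      int p = v[k];
      sq = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
           (2.0 * s2 * (q - p));
      if (sq <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : sq;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int idx = 0;
  for (int q = 0; q < n; ++q) {
    while (z[idx + 1] < q) ++idx;
    int p = v[idx];
    d[q] = s2 * (double)(q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out1(nmax);
  std::vector<int> vbuf(nmax);
  std::vector<double> zbuf(nmax + 1);

  for (int k = 0; k < nz; ++k)  // x axis
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f.data(), out1.data(), nx, spacing[0], vbuf, zbuf);
      for (int i = 0; i < nx; ++i) d[base + i] = out1[i];
    }
  for (int k = 0; k < nz; ++k)  // y axis
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (R_xlen_t)nx * j];
      dt1d(f.data(), out1.data(), ny, spacing[1], vbuf, zbuf);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)nx * j] = out1[j];
    }
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)  // z axis
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = d[base + nxy * k];
      dt1d(f.data(), out1.data(), nz, spacing[2], vbuf, zbuf);
      for (int k = 0; k < nz; ++k) d[base + nxy * k] = out1[k];
    }

  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i)
    res[i] = (d[i] == INF) ? R_PosInf : std::sqrt(d[i]);
  return res;
}
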