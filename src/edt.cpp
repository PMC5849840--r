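#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas) at sample
// positions x[0..n-1] (strictly increasing, physical mm). f holds squared
// distances (may be +Inf); result written into d.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 const std::vector<double> &x, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int first = -1;
  for (int q = 0; q < n; ++q)
    if (f[q] < INF) { first = q; break; }
  if (first < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = first;
  z[0] = -INF;
  z[1] = INF;
  for (int q = first + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + x[q] * x[q]) - (f[p] + x[p] * x[p])) /
          (2.0 * (x[q] - x[p]));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < x[q]) ++j;
    int p = v[j];
    double dx = x[q] - x[p];
    d[q] = dx * dx + f[p];
  }
}

// Exact Euclidean distance transform of a 3D mask with per-axis spacing.
// Returns, per voxel, the distance (mm) from its center to the nearest
// occupied voxel center (0 inside the mask, +Inf if the mask is empty).
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims,
                    NumericVector spacing) {
  if (dims.size() != 3 || spacing.size() != 3)
    stop("dims and spacing must each have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  if (mask.size() != N) stop("mask length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();

  NumericVector out(N);
  double *o = REAL(out);
  const int *msk = LOGICAL(mask);
  for (R_xlen_t i = 0; i < N; ++i) o[i] = (msk[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), xs(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass 1: along x (fastest-varying axis)
  for (int i = 0; i < nx; ++i) xs[i] = i * spacing[0];
  for (int kk = 0; kk < nz; ++kk) {
    for (int jj = 0; jj < ny; ++jj) {
      R_xlen_t base = (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      for (int i = 0; i < nx; ++i) f[i] = o[base + i];
      dt1d(f, d, xs, nx, v, z);
      for (int i = 0; i < nx; ++i) o[base + i] = d[i];
    }
  }
  // pass 2: along y
  for (int j = 0; j < ny; ++j) xs[j] = j * spacing[1];
  for (int kk = 0; kk < nz; ++kk) {
    for (int ii = 0; ii < nx; ++ii) {
      R_xlen_t base = ii + (R_xlen_t)nx * ny * kk;
      for (int j = 0; j < ny; ++j) f[j] = o[base + (R_xlen_t)nx * j];
      dt1d(f, d, xs, ny, v, z);
      for (int j = 0; j < ny; ++j) o[base + (R_xlen_t)nx * j] = d[j];
    }
  }
  // pass 3: along z
  for (int k = 0; k < nz; ++k) xs[k] = k * spacing[2];
  const R_xlen_t stridez = (R_xlen_t)nx * ny;
  for (int jj = 0; jj < ny; ++jj) {
    for (int ii = 0; ii < nx; ++ii) {
      R_xlen_t base = ii + (R_xlen_t)nx * jj;
      for (int k = 0; k < nz; ++k) f[k] = o[base + stridez * k];
      dt1d(f, d, xs, nz, v, z);
      for (int k = 0; k < nz; ++k) o[base + stridez * k] = d[k];
    }
  }
  for (R_xlen_t i = 0; i < N; ++i)
    o[i] = (o[i] == INF) ? INF : std::sqrt(o[i]);
  out.attr("dim") = dims;
  return out;
}
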