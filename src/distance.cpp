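#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), sample spacing w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -DBL_MAX;
  z[1] = DBL_MAX;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      // intersection abscissa in physical coordinates (units of w)
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DBL_MAX;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < w * q) ++k;
    double dq = w * q - w * v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (mm) from each true voxel to the nearest false voxel
// centre, honouring anisotropic spacing. False voxels get 0.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double BIG = 1e30;
  for (R_xlen_t s = 0; s < n; ++s) out[s] = mask[s] ? BIG : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[z];
    }
  for (R_xlen_t s = 0; s < n; ++s) out[s] = std::sqrt(out[s]);
  return out;
}
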