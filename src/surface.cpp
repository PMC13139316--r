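#include <Rcpp.h>
using namespace Rcpp;

// Separable Gaussian smoothing of a 3D field, sigma in voxel units per axis,
// zero padding (appropriate for indicator fields embedded in background 0).
// [[Rcpp::export]]
NumericVector gauss_smooth_cpp(NumericVector vol, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double ksum = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += ker[i + rad];
  }
  for (size_t i = 0; i < ker.size(); ++i) ker[i] /= ksum;

  NumericVector a = clone(vol), b(n);
  auto pass = [&](NumericVector& src, NumericVector& dst, int axis) {
    R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : (R_xlen_t)nx * ny);
    int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
    for (int z = 0; z < (axis == 2 ? 1 : nz); ++z)
      for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
        for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
          R_xlen_t base = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          for (int p = 0; p < len; ++p) {
            double acc = 0.0;
            for (int k = -rad; k <= rad; ++k) {
              int pp = p + k;
              if (pp < 0 || pp >= len) continue;
              acc += ker[k + rad] * src[base + stride * pp];
            }
            dst[base + stride * p] = acc;
          }
        }
  };
  pass(a, b, 0);
  pass(b, a, 1);
  pass(a, b, 2);
  return b;
}

static inline double tri_area(const double* p1, const double* p2, const double* p3) {
  double u[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
  double v[3] = {p3[0] - p1[0], p3[1] - p1[1], p3[2] - p1[2]};
  double c0 = u[1] * v[2] - u[2] * v[1];
  double c1 = u[2] * v[0] - u[0] * v[2];
  double c2 = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(c0 * c0 + c1 * c1 + c2 * c2);
}

// Total area of the iso-level surface of a scalar field sampled at voxel
// centres, by marching tetrahedra (each cell split into 6 tetrahedra around
// the main diagonal, linear interpolation along edges). Field values outside
// the grid are treated as 0, so a component touching the border is closed off.
// [[Rcpp::export]]
double mt_area_cpp(NumericVector vol, IntegerVector dim, NumericVector spacing, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner offsets
  static const int coff[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

  auto sample = [&](int x, int y, int z) -> double {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0.0;
    return vol[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };

  double area = 0.0;
  double cp[8][3], cv[8];
  // cells span voxel centres (x..x+1 etc.); include a one-cell border
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + coff[c][0], cy = y + coff[c][1], cz = z + coff[c][2];
          cv[c] = sample(cx, cy, cz);
          cp[c][0] = cx * sx; cp[c][1] = cy * sy; cp[c][2] = cz * sz;
          if (cv[c] > iso) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int above[4], na = 0, nb = 0;
          int bel[4];
          for (int k = 0; k < 4; ++k) {
            if (cv[id[k]] > iso) above[na++] = id[k]; else bel[nb++] = id[k];
          }
          if (na == 0 || na == 4) continue;
          auto interp = [&](int a, int b, double* out) {
            double t0 = (iso - cv[a]) / (cv[b] - cv[a]);
            for (int j = 0; j < 3; ++j) out[j] = cp[a][j] + t0 * (cp[b][j] - cp[a][j]);
          };
          if (na == 1 || na == 3) {
            int apex = (na == 1) ? above[0] : bel[0];
            int* others = (na == 1) ? bel : above;
            double p1[3], p2[3], p3[3];
            interp(apex, others[0], p1);
            interp(apex, others[1], p2);
            interp(apex, others[2], p3);
            area += tri_area(p1, p2, p3);
          } else { // na == 2: quad
            double p1[3], p2[3], p3[3], p4[3];
            interp(above[0], bel[0], p1);
            interp(above[0], bel[1], p2);
            interp(above[1], bel[1], p3);
            interp(above[1], bel[0], p4);
            area += tri_area(p1, p2, p3);
            area += tri_area(p1, p3, p4);
          }
        }
      }
  return area;
}

// Voxel-face surface area: exposed faces of true voxels, for degenerate
// components too thin for meshing.
// [[Rcpp::export]]
double face_area_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double fa[3] = {spacing[1] * spacing[2], spacing[0] * spacing[2],
                        spacing[0] * spacing[1]};
  const int nb[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  double area = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)]) continue;
        for (int k = 0; k < 6; ++k) {
          int xx = x + nb[k][0], yy = y + nb[k][1], zz = z + nb[k][2];
          bool neigh = (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
            ? (bool)mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] : false;
          if (!neigh) area += fa[k / 2];
        }
      }
  return area;
}
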