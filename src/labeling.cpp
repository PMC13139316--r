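#include <Rcpp.h>
#include <queue>
#include <array>
using namespace Rcpp;

static std::vector<std::array<int,3>> conn_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        off.push_back({{dx, dy, dz}});
      }
  return off;
}

// Connected-component labeling on a 3D logical array (column-major, x fastest).
// Provisional labels are assigned by BFS in linear scan order, then relabeled
// so label 1 is the largest component (ties: smallest linear voxel index).
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> off = conn_offsets(connectivity);

  std::vector<R_xlen_t> comp_size;
  std::vector<R_xlen_t> comp_first;
  int next = 0;
  std::queue<R_xlen_t> q;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    comp_size.push_back(0);
    comp_first.push_back(s);
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      ++comp_size[next - 1];
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && lab[w] == 0) { lab[w] = next; q.push(w); }
      }
    }
  }

  // order components by decreasing size, ties by smallest first voxel index
  std::vector<int> ord(next);
  for (int i = 0; i < next; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (comp_size[a] != comp_size[b]) return comp_size[a] > comp_size[b];
    return comp_first[a] < comp_first[b];
  });
  std::vector<int> remap(next + 1, 0);
  for (int r = 0; r < next; ++r) remap[ord[r] + 1] = r + 1;
  for (R_xlen_t s = 0; s < n; ++s)
    if (lab[s] != 0) lab[s] = remap[lab[s]];
  return lab;
}

// Binary erosion / dilation with a discrete ball (voxel-index metric).
// Outside the grid counts as background.
// [[Rcpp::export]]
LogicalVector morph_ball_cpp(LogicalVector mask, IntegerVector dim, int radius, bool erode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  std::vector<std::array<int,3>> off;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius)
          off.push_back({{dx, dy, dz}});

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t s = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        bool acc = erode;
        for (size_t k = 0; k < off.size(); ++k) {
          int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          bool val;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            val = false;
          else
            val = mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
          if (erode) { if (!val) { acc = false; break; } }
          else       { if (val)  { acc = true;  break; } }
        }
        out[s] = acc;
      }
  return out;
}
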