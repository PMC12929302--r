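#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Neighbor offsets for 6/18/26-connectivity on a 3D grid.
// On a single-slice grid (nz == 1) the same tables reduce to 4/8-connectivity.
static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Label connected foreground components of a binary 3D array (column-major,
// dims = c(nx, ny, nz)). Ids are assigned in order of first encounter while
// scanning linear (column-major) order, so labelling is deterministic.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(IntegerVector vox, IntegerVector dims, int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vox.size() != n) stop("voxel length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity);
  int next_id = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (vox[i] == 0 || lab[i] != 0) continue;
    ++next_id;
    lab[i] = next_id;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front();
      q.pop();
      int cx = (int)(cur % nx);
      int cy = (int)((cur / nx) % ny);
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < off.size(); ++k) {
        int x = cx + off[k][0], y = cy + off[k][1], z = cz + off[k][2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        R_xlen_t j = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (vox[j] != 0 && lab[j] == 0) {
          lab[j] = next_id;
          q.push(j);
        }
      }
    }
  }
  return lab;
}

// Flood fill the background from all border voxels (6-connectivity on the
// background, the complement-connectivity pairing with 26-connected
// foreground). Returns 1 where a background voxel is reachable from the
// volume border, 0 elsewhere. Used to identify enclosed cavities.
// [[Rcpp::export(name = ".border_background3d")]]
IntegerVector border_background3d(IntegerVector vox, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vox.size() != n) stop("voxel length does not match dims");
  IntegerVector reach(n, 0);
  std::vector<std::array<int, 3>> off = neighbor_offsets(6);
  std::queue<R_xlen_t> q;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && x != nx - 1 && y != 0 && y != ny - 1 && z != 0 && z != nz - 1)
          continue;
        R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (vox[i] == 0 && reach[i] == 0) {
          reach[i] = 1;
          q.push(i);
        }
      }
  while (!q.empty()) {
    R_xlen_t cur = q.front();
    q.pop();
    int cx = (int)(cur % nx);
    int cy = (int)((cur / nx) % ny);
    int cz = (int)(cur / ((R_xlen_t)nx * ny));
    for (size_t k = 0; k < off.size(); ++k) {
      int x = cx + off[k][0], y = cy + off[k][1], z = cz + off[k][2];
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      R_xlen_t j = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
      if (vox[j] == 0 && reach[j] == 0) {
        reach[j] = 1;
        q.push(j);
      }
    }
  }
  return reach;
}
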