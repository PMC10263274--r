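#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Disjoint-set with path halving.
static inline int ds_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static inline void ds_union(std::vector<int> &parent, int a, int b) {
  int ra = ds_find(parent, a), rb = ds_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// Two-pass union-find connected-component labelling of a 3D logical mask.
// `mask` is a logical vector in column-major order with dims (nz, ny, nx);
// connectivity is 6, 18 or 26. Returns an integer vector of the same length
// with components numbered 1..k in raster order of their first voxel.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims,
                          int connectivity = 26) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // Backward half of the neighbourhood (already-visited voxels in raster order).
  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        // keep strictly earlier voxels: index = z + nz*(y + ny*x)
        long long delta = (long long)dz + (long long)nz * (dy + (long long)ny * dx);
        if (delta < 0) offs.push_back({dz, dy, dx});
      }

  IntegerVector labels(n, 0);
  std::vector<int> parent;
  parent.reserve(1024);
  int next = 0;  // provisional labels are 0-based internally

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!mask[i]) continue;
        int lab = -1;
        for (const auto &o : offs) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          R_xlen_t j = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (!mask[j]) continue;
          int lj = labels[j] - 1;
          if (lab < 0) lab = ds_find(parent, lj);
          else ds_union(parent, lab, lj);
        }
        if (lab < 0) {
          lab = next++;
          parent.push_back(lab);
        } else {
          lab = ds_find(parent, lab);
        }
        labels[i] = lab + 1;
      }

  // Compress to consecutive labels in raster order of first occurrence.
  std::vector<int> remap(next, 0);
  int k = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i] == 0) continue;
    int r = ds_find(parent, labels[i] - 1);
    if (remap[r] == 0) remap[r] = ++k;
    labels[i] = remap[r];
  }
  labels.attr("dim") = dims;
  return labels;
}
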