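#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Union-find with path compression and size tracking
static int uf_find(std::vector<int> &parent, int i) {
  int root = i;
  while (parent[root] != root) root = parent[root];
  while (parent[i] != root) { int nxt = parent[i]; parent[i] = root; i = nxt; }
  return root;
}

static void neighbor_offsets(const IntegerVector &dims, int connectivity,
                             std::vector<std::array<int,3>> &offs) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        offs.push_back({dx, dy, dz});
      }
}

// Threshold-free cluster enhancement of a non-negative 3D map.
// TFCE(v) = sum over thresholds h = dh, 2dh, ..., h <= max(vals), of
// e(h, v)^E * h^H * dh, where e(h, v) is the voxel count of the connected
// component containing v in the h-superthreshold set (vals >= h).
// Implemented by sweeping thresholds downward with an incremental
// union-find, so each threshold step costs O(active voxels).
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector vals, IntegerVector dims,
                       double E, double H, double dh, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) if (vals[i] > vmax) vmax = vals[i];
  if (vmax <= 0.0 || dh <= 0.0) return out;
  int nsteps = (int)std::floor(vmax / dh + 1e-9);
  if (nsteps < 1) return out;

  std::vector<std::array<int,3>> offs;
  neighbor_offsets(dims, connectivity, offs);

  // voxels with positive value, sorted by value descending
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i) if (vals[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return vals[a] > vals[b]; });

  std::vector<int> parent(n, -1), csize(n, 0);
  std::vector<char> active(n, 0);
  size_t ptr = 0;

  for (int k = nsteps; k >= 1; --k) {
    double h = k * dh;
    // activate voxels with value >= h and union with active neighbours
    while (ptr < order.size() && vals[order[ptr]] >= h) {
      int v = order[ptr++];
      parent[v] = v; csize[v] = 1; active[v] = 1;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (size_t o = 0; o < offs.size(); ++o) {
        int xx = x + offs[o][0], yy = y + offs[o][1], zz = z + offs[o][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (!active[w]) continue;
        int rv = uf_find(parent, v), rw = uf_find(parent, w);
        if (rv != rw) {
          if (csize[rv] < csize[rw]) std::swap(rv, rw);
          parent[rw] = rv;
          csize[rv] += csize[rw];
        }
      }
    }
    double hH = std::pow(h, H) * dh;
    for (size_t j = 0; j < ptr; ++j) {
      int v = order[j];
      out[v] += std::pow((double)csize[uf_find(parent, v)], E) * hH;
    }
  }
  return out;
}

// Connected-component labelling of a logical 3D mask (labels in discovery
// order along the linear index).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n);
  std::vector<std::array<int,3>> offs;
  neighbor_offsets(dims, connectivity, offs);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    labels[i] = next;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (size_t o = 0; o < offs.size(); ++o) {
        int xx = x + offs[o][0], yy = y + offs[o][1], zz = z + offs[o][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (mask[w] && labels[w] == 0) { labels[w] = next; stack.push_back(w); }
      }
    }
  }
  return labels;
}
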