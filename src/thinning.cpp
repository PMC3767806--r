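// 3D topology-preserving thinning and component labeling on binary voxel
// grids. Foreground uses 26-connectivity, background 6-connectivity.
//
// A voxel is "simple" (deletable without changing topology) iff its
// topological numbers are both 1: exactly one 26-connected foreground
// component in the 26-neighborhood, and exactly one 6-connected background
// component in the 18-neighborhood that is 6-adjacent to the voxel
// (Bertrand-Malandain characterization for the (26,6) connectivity pair).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + (long)ny * z);
}

// Extract the 3x3x3 neighborhood of (x,y,z); out-of-grid cells are background.
static inline void neighborhood(const int* img, int nx, int ny, int nz,
                                int x, int y, int z, int nb[27]) {
  int t = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++t) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[t] = (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
                  ? img[idx3(xx, yy, zz, nx, ny)] : 0;
      }
}

// Offsets of cell t in the flattened 3x3x3 cube (t = dx+1 + 3*(dy+1) + 9*(dz+1)).
static inline void unflatten(int t, int& dx, int& dy, int& dz) {
  dx = t % 3 - 1; dy = (t / 3) % 3 - 1; dz = t / 9 - 1;
}

// Number of 26-connected foreground components among the 26 neighbors.
static int fg_components26(const int nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++ncomp;
    std::queue<int> q; q.push(s); seen[s] = true;
    while (!q.empty()) {
      int t = q.front(); q.pop();
      int tx, ty, tz; unflatten(t, tx, ty, tz);
      for (int u = 0; u < 27; ++u) {
        if (u == 13 || seen[u] || !nb[u]) continue;
        int ux, uy, uz; unflatten(u, ux, uy, uz);
        if (std::abs(ux - tx) <= 1 && std::abs(uy - ty) <= 1 &&
            std::abs(uz - tz) <= 1)
          { seen[u] = true; q.push(u); }
      }
    }
  }
  return ncomp;
}

// Number of 6-connected background components within the 18-neighborhood
// that contain a face neighbor of the center.
static int bg_components6(const int nb[27]) {
  bool in18[27], seen[27] = {false};
  for (int t = 0; t < 27; ++t) {
    int dx, dy, dz; unflatten(t, dx, dy, dz);
    in18[t] = (t != 13) && (std::abs(dx) + std::abs(dy) + std::abs(dz) <= 2);
  }
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    int sx, sy, sz; unflatten(s, sx, sy, sz);
    // seeds: background face neighbors of the center
    if (!in18[s] || nb[s] || seen[s]) continue;
    if (std::abs(sx) + std::abs(sy) + std::abs(sz) != 1) continue;
    ++ncomp;
    std::queue<int> q; q.push(s); seen[s] = true;
    while (!q.empty()) {
      int t = q.front(); q.pop();
      int tx, ty, tz; unflatten(t, tx, ty, tz);
      for (int u = 0; u < 27; ++u) {
        if (!in18[u] || seen[u] || nb[u]) continue;
        int ux, uy, uz; unflatten(u, ux, uy, uz);
        if (std::abs(ux - tx) + std::abs(uy - ty) + std::abs(uz - tz) == 1)
          { seen[u] = true; q.push(u); }
      }
    }
  }
  return ncomp;
}

static inline bool is_simple(const int nb[27]) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

static inline int count_fg_neighbors26(const int nb[27]) {
  int n = 0;
  for (int t = 0; t < 27; ++t) if (t != 13 && nb[t]) ++n;
  return n;
}

// [[Rcpp::export(name = ".cpp_skeletonize")]]
IntegerVector cpp_skeletonize(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> img(mask.begin(), mask.end());
  // fixed subiteration order: -x, +x, -y, +y, -z, +z borders
  const int dir[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  int nb[27];
  bool changed = true;
  std::vector<long> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            long i = idx3(x, y, z, nx, ny);
            if (!img[i]) continue;
            int xx = x + dir[d][0], yy = y + dir[d][1], zz = z + dir[d][2];
            bool border = !(xx >= 0 && xx < nx && yy >= 0 && yy < ny &&
                            zz >= 0 && zz < nz) ||
                          !img[idx3(xx, yy, zz, nx, ny)];
            if (!border) continue;
            neighborhood(img.data(), nx, ny, nz, x, y, z, nb);
            if (count_fg_neighbors26(nb) == 1) continue;  // curve endpoint
            if (is_simple(nb)) cand.push_back(i);
          }
      // sequential deletion with re-check preserves topology exactly
      for (size_t c = 0; c < cand.size(); ++c) {
        long i = cand[c];
        int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((long)nx * ny));
        neighborhood(img.data(), nx, ny, nz, x, y, z, nb);
        if (count_fg_neighbors26(nb) == 1) continue;
        if (is_simple(nb)) { img[i] = 0; changed = true; }
      }
    }
  }
  return IntegerVector(img.begin(), img.end());
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }
  int nlab = 0;
  std::queue<long> q;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++nlab;
    q.push(s);
    while (!q.empty()) {
      long i = q.front(); q.pop();
      int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((long)nx * ny));
      for (size_t k = 0; k < offs.size(); k += 3) {
        int xx = x + offs[k], yy = y + offs[k+1], zz = z + offs[k+2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        long j = idx3(xx, yy, zz, nx, ny);
        if (mask[j] && !lab[j]) { lab[j] = nlab; q.push(j); }
      }
    }
  }
  lab.attr("n_components") = nlab;
  return lab;
}
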