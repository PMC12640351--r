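#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// --- simple-point machinery on the 3x3x3 neighborhood ---------------------
//
// A voxel is "simple" (deletable without changing topology) when
//  (a) its object neighbors form exactly one 26-connected component, and
//  (b) its background 6-neighbors belong to exactly one 6-connected
//      component of background voxels within the 18-neighborhood
// (Malandain & Bertrand characterization for (26,6) digital topology).

static const int NB = 27;  // local cube, index = (dx+1) + 3*(dy+1) + 9*(dz+1)

static inline int nbidx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// number of 26-connected components of object voxels in N26
static int count_obj_components(const bool nb[NB]) {
  bool seen[NB] = {false};
  int comps = 0;
  int stack[NB];
  for (int s = 0; s < NB; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int v = stack[--top];
      int vx = v % 3, vy = (v / 3) % 3, vz = v / 9;
      for (int w = 0; w < NB; ++w) {
        if (w == 13 || !nb[w] || seen[w]) continue;
        int wx = w % 3, wy = (w / 3) % 3, wz = w / 9;
        int ax = vx > wx ? vx - wx : wx - vx;
        int ay = vy > wy ? vy - wy : wy - vy;
        int az = vz > wz ? vz - wz : wz - vz;
        if (ax <= 1 && ay <= 1 && az <= 1) {
          seen[w] = true;
          stack[top++] = w;
        }
      }
    }
  }
  return comps;
}

// number of 6-connected background components in the 18-neighborhood that
// touch a face neighbor of the center
static int count_bg_components(const bool nb[NB]) {
  bool in18[NB], seen[NB] = {false};
  for (int s = 0; s < NB; ++s) {
    int sx = s % 3 - 1, sy = (s / 3) % 3 - 1, sz = s / 9 - 1;
    int a = (sx < 0 ? -sx : sx) + (sy < 0 ? -sy : sy) + (sz < 0 ? -sz : sz);
    in18[s] = (a >= 1 && a <= 2);
  }
  int comps = 0;
  int stack[NB];
  for (int s = 0; s < NB; ++s) {
    if (!in18[s] || nb[s] || seen[s]) continue;
    // only seed from face neighbors of the center
    int sx = s % 3 - 1, sy = (s / 3) % 3 - 1, sz = s / 9 - 1;
    if ((sx != 0) + (sy != 0) + (sz != 0) != 1) continue;
    ++comps;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int v = stack[--top];
      int vx = v % 3, vy = (v / 3) % 3, vz = v / 9;
      for (int w = 0; w < NB; ++w) {
        if (!in18[w] || nb[w] || seen[w]) continue;
        int wx = w % 3, wy = (w / 3) % 3, wz = w / 9;
        int d = (vx > wx ? vx - wx : wx - vx) + (vy > wy ? vy - wy : wy - vy) +
                (vz > wz ? vz - wz : wz - vz);
        if (d == 1) {
          seen[w] = true;
          stack[top++] = w;
        }
      }
    }
  }
  return comps;
}

struct Grid {
  const int nx, ny, nz;
  std::vector<uint8_t> v;
  Grid(int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_), v((size_t)nx_ * ny_ * nz_, 0) {}
  inline bool at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return v[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] != 0;
  }
  inline void set(int x, int y, int z, bool b) {
    v[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] = b ? 1 : 0;
  }
};

static void fill_nb(const Grid &g, int x, int y, int z, bool nb[NB]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        nb[nbidx(dx, dy, dz)] = g.at(x + dx, y + dy, z + dz);
}

static inline int nb_obj_count(const bool nb[NB]) {
  int c = 0;
  for (int s = 0; s < NB; ++s)
    if (s != 13 && nb[s]) ++c;
  return c;
}

// Deletability under isthmus anchoring: a voxel whose object neighborhood
// ever splits into >= 2 components is a curve-interior (isthmus) voxel and
// is anchored permanently; otherwise it may be deleted when it is simple.
// Blobs therefore collapse all the way to a single voxel (no endpoints),
// while curves keep their anchored interiors.
static inline bool deletable(const Grid &g, std::vector<uint8_t> &anchor,
                             int x, int y, int z) {
  size_t lin = (size_t)x + (size_t)g.nx * (y + (size_t)g.ny * z);
  if (anchor[lin]) return false;
  bool nb[NB];
  fill_nb(g, x, y, z, nb);
  int cstar = count_obj_components(nb);
  if (cstar >= 2) {
    anchor[lin] = 1;
    return false;
  }
  if (cstar != 1) return false;  // isolated voxel
  return count_bg_components(nb) == 1;
}

// Homotopic curve thinning of a 3D mask by sequential boundary peeling with
// six directional subiterations and isthmus anchoring; deterministic in
// scan order.
// [[Rcpp::export]]
LogicalVector cpp_thin_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  Grid g(nx, ny, nz);
  for (R_xlen_t i = 0; i < mask.size(); ++i) g.v[i] = mask[i] ? 1 : 0;
  std::vector<uint8_t> anchor(g.v.size(), 0);

  const int dirs[6][3] = {{0, 0, -1}, {0, 0, 1}, {0, -1, 0},
                          {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};
  std::vector<std::array<int, 3> > cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            if (!g.at(x, y, z)) continue;
            if (g.at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
            if (deletable(g, anchor, x, y, z)) cand.push_back({x, y, z});
          }
      for (auto &p : cand) {
        // re-check: earlier deletions in this pass may change the status
        if (deletable(g, anchor, p[0], p[1], p[2])) {
          g.set(p[0], p[1], p[2], false);
          changed = true;
        }
      }
    }
  }

  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = g.v[i] != 0;
  return out;
}
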