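#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

typedef long long ll;

// Exact orientation predicate on the integer corner lattice:
// det of (b-a, c-a, d-a). Coordinates stay below ~2^13 so the
// determinant fits comfortably in 64 bits.
static inline ll orient3d(const std::vector<std::array<ll, 3> > &P,
                          int a, int b, int c, int d) {
  ll ux = P[b][0] - P[a][0], uy = P[b][1] - P[a][1], uz = P[b][2] - P[a][2];
  ll vx = P[c][0] - P[a][0], vy = P[c][1] - P[a][1], vz = P[c][2] - P[a][2];
  ll wx = P[d][0] - P[a][0], wy = P[d][1] - P[a][1], wz = P[d][2] - P[a][2];
  return ux * (vy * wz - vz * wy) - uy * (vx * wz - vz * wx) +
         uz * (vx * wy - vy * wx);
}

struct Face {
  int a, b, c;
  bool alive;
};

// Candidate hull points for a voxel mask: the corners of every voxel,
// reduced to the x-extreme corners on each (y,z) lattice line (interior
// corners on a line are convex combinations of the extremes).
// vox holds 0-based voxel indices; voxel (i,j,k) spans corners
// {i,i+1} x {j,j+1} x {k,k+1}.
// [[Rcpp::export]]
IntegerMatrix cpp_corner_candidates(IntegerMatrix vox) {
  std::unordered_map<ll, std::pair<int, int> > mm;
  mm.reserve(vox.nrow() * 4);
  for (int r = 0; r < vox.nrow(); ++r) {
    int x = vox(r, 0), y = vox(r, 1), z = vox(r, 2);
    for (int dy = 0; dy <= 1; ++dy) {
      for (int dz = 0; dz <= 1; ++dz) {
        ll key = ((ll)(y + dy) << 24) | (ll)(z + dz);
        auto it = mm.find(key);
        if (it == mm.end()) {
          mm[key] = std::make_pair(x, x + 1);
        } else {
          if (x < it->second.first) it->second.first = x;
          if (x + 1 > it->second.second) it->second.second = x + 1;
        }
      }
    }
  }
  IntegerMatrix out(2 * (int)mm.size(), 3);
  int r = 0;
  for (auto &kv : mm) {
    int y = (int)(kv.first >> 24), z = (int)(kv.first & 0xFFFFFF);
    out(r, 0) = kv.second.first;  out(r, 1) = y; out(r, 2) = z; ++r;
    out(r, 0) = kv.second.second; out(r, 1) = y; out(r, 2) = z; ++r;
  }
  return out;
}

// Volume of the 3D convex hull of integer lattice points, computed by an
// incremental hull with exact integer predicates. Returns volume in
// lattice units; the caller scales by the physical voxel volume.
// [[Rcpp::export]]
double cpp_hull_volume_lattice(IntegerMatrix pts) {
  int n0 = pts.nrow();
  if (n0 < 4) stop("need at least 4 points for a 3D hull");
  std::vector<std::array<ll, 3> > P;
  P.reserve(n0);
  for (int i = 0; i < n0; ++i)
    P.push_back({(ll)pts(i, 0), (ll)pts(i, 1), (ll)pts(i, 2)});
  std::sort(P.begin(), P.end());
  P.erase(std::unique(P.begin(), P.end()), P.end());
  int n = (int)P.size();
  if (n < 4) stop("degenerate point set (fewer than 4 distinct points)");

  // initial non-degenerate tetrahedron
  int i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i)
    if (P[i] != P[0]) i1 = i;
  for (int i = i1 + 1; i < n && i2 < 0; ++i) {
    ll ux = P[i1][0] - P[0][0], uy = P[i1][1] - P[0][1], uz = P[i1][2] - P[0][2];
    ll vx = P[i][0] - P[0][0], vy = P[i][1] - P[0][1], vz = P[i][2] - P[0][2];
    ll cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    if (cx != 0 || cy != 0 || cz != 0) i2 = i;
  }
  if (i2 < 0) stop("degenerate point set (collinear)");
  for (int i = i2 + 1; i < n && i3 < 0; ++i)
    if (orient3d(P, 0, i1, i2, i) != 0) i3 = i;
  if (i3 < 0) stop("degenerate point set (coplanar)");

  std::vector<Face> faces;
  {
    int t[4] = {0, i1, i2, i3};
    int opp[4][4] = {{0, 1, 2, 3}, {0, 3, 1, 2}, {1, 3, 2, 0}, {0, 2, 3, 1}};
    for (int f = 0; f < 4; ++f) {
      int a = t[opp[f][0]], b = t[opp[f][1]], c = t[opp[f][2]], d = t[opp[f][3]];
      if (orient3d(P, a, b, c, d) > 0) std::swap(b, c);  // d must be inside
      faces.push_back({a, b, c, true});
    }
  }

  std::vector<int> visible;
  std::unordered_map<ll, int> edges;  // directed edge (u,v) -> count
  for (int p = 1; p < n; ++p) {
    if (p == i1 || p == i2 || p == i3) continue;
    visible.clear();
    for (int f = 0; f < (int)faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (orient3d(P, faces[f].a, faces[f].b, faces[f].c, p) > 0)
        visible.push_back(f);
    }
    if (visible.empty()) continue;
    edges.clear();
    for (int f : visible) {
      int v[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int e = 0; e < 3; ++e) {
        ll key = ((ll)v[e] << 24) | (ll)v[(e + 1) % 3];
        edges[key]++;
      }
      faces[f].alive = false;
    }
    for (auto &kv : edges) {
      int u = (int)(kv.first >> 24), v = (int)(kv.first & 0xFFFFFF);
      ll rkey = ((ll)v << 24) | (ll)u;
      if (edges.find(rkey) == edges.end())  // horizon edge
        faces.push_back({u, v, p, true});
    }
  }

  // signed volume relative to vertex 0 (a hull vertex, lexicographic min);
  // outward-oriented faces give non-negative tetrahedron contributions.
  ll six_vol = 0;
  for (auto &f : faces) {
    if (!f.alive) continue;
    six_vol += orient3d(P, f.a, f.b, f.c, 0) < 0
                   ? -orient3d(P, f.a, f.b, f.c, 0)
                   : orient3d(P, f.a, f.b, f.c, 0);
  }
  return (double)six_vol / 6.0;
}
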