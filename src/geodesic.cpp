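#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <unordered_map>
#include <limits>
using namespace Rcpp;

// Geodesic endpoint-to-root path lengths along a skeleton voxel graph.
// coords: 1-based voxel indices (n x 3); nodes are 26-adjacent voxels,
// edge weight = Euclidean distance between physical voxel centers.
// The root of each connected component is the skeleton voxel whose center
// lies nearest (Euclidean) to the supplied cell centroid (physical units);
// ties go to the lowest node index.
// [[Rcpp::export]]
List cpp_skeleton_geodesics(IntegerMatrix coords, NumericVector spacing,
                            NumericVector centroid) {
  const int n = coords.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  std::unordered_map<long long, int> id;
  id.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    long long key = ((long long)coords(i, 0) << 42) |
                    ((long long)coords(i, 1) << 21) | (long long)coords(i, 2);
    id[key] = i;
  }

  std::vector<std::vector<int> > adj(n);
  std::vector<std::vector<double> > w(n);
  for (int i = 0; i < n; ++i) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          long long key = ((long long)(coords(i, 0) + dx) << 42) |
                          ((long long)(coords(i, 1) + dy) << 21) |
                          (long long)(coords(i, 2) + dz);
          auto it = id.find(key);
          if (it == id.end() || it->second <= i) continue;
          double step = std::sqrt(dx * sx * dx * sx + dy * sy * dy * sy +
                                  dz * sz * dz * sz);
          adj[i].push_back(it->second);
          w[i].push_back(step);
          adj[it->second].push_back(i);
          w[it->second].push_back(step);
        }
  }

  IntegerVector degree(n);
  for (int i = 0; i < n; ++i) degree[i] = (int)adj[i].size();

  // connected components (on the skeleton graph)
  std::vector<int> comp(n, -1);
  int ncomp = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    comp[s] = ncomp;
    stack.push_back(s);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      for (int u : adj[v])
        if (comp[u] < 0) {
          comp[u] = ncomp;
          stack.push_back(u);
        }
    }
    ++ncomp;
  }

  // per-component root: voxel center nearest to centroid
  std::vector<int> root(ncomp, -1);
  std::vector<double> best(ncomp, std::numeric_limits<double>::infinity());
  for (int i = 0; i < n; ++i) {
    double cx = (coords(i, 0) - 0.5) * sx - centroid[0];
    double cy = (coords(i, 1) - 0.5) * sy - centroid[1];
    double cz = (coords(i, 2) - 0.5) * sz - centroid[2];
    double d2 = cx * cx + cy * cy + cz * cz;
    if (d2 < best[comp[i]]) {
      best[comp[i]] = d2;
      root[comp[i]] = i;
    }
  }

  // multi-source Dijkstra (components are disjoint, so one queue suffices)
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int c = 0; c < ncomp; ++c) {
    dist[root[c]] = 0.0;
    pq.push(QE(0.0, root[c]));
  }
  while (!pq.empty()) {
    QE t = pq.top();
    pq.pop();
    int v = t.second;
    if (t.first > dist[v]) continue;
    for (size_t e = 0; e < adj[v].size(); ++e) {
      int u = adj[v][e];
      double nd = t.first + w[v][e];
      if (nd < dist[u]) {
        dist[u] = nd;
        pq.push(QE(nd, u));
      }
    }
  }

  IntegerVector roots(ncomp);
  for (int c = 0; c < ncomp; ++c) roots[c] = root[c] + 1;

  return List::create(_["degree"] = degree, _["component"] = comp,
                      _["n_components"] = ncomp, _["roots"] = roots,
                      _["dist"] = NumericVector(dist.begin(), dist.end()));
}
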