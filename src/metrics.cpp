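#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// BFS from a source over an adjacency-list graph; dist = -1 marks unreachable.
static void bfs(const std::vector<std::vector<int>>& nbrs, int src,
                std::vector<int>& dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[src] = 0;
  std::queue<int> q;
  q.push(src);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int v : nbrs[u]) {
      if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
    }
  }
}

static std::vector<std::vector<int>> adjacency_lists(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nbrs(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) nbrs[i].push_back(j);
  return nbrs;
}

// All-pairs unweighted shortest-path lengths; unreachable pairs are -1.
// [[Rcpp::export]]
IntegerMatrix bfs_distances_cpp(IntegerMatrix adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nbrs = adjacency_lists(adj);
  IntegerMatrix out(n, n);
  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i) {
    bfs(nbrs, i, dist);
    for (int j = 0; j < n; ++j) out(i, j) = dist[j];
  }
  return out;
}

// Global efficiency of a graph given as adjacency lists restricted to the
// node subset `sub` (indices into the full graph). Mean of 1/d over ordered
// pairs within the subset, distances computed inside the induced subgraph.
static double subgraph_global_efficiency(const IntegerMatrix& adj,
                                         const std::vector<int>& sub) {
  int k = (int)sub.size();
  if (k < 2) return 0.0;
  std::vector<std::vector<int>> nbrs(k);
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b)
      if (a != b && adj(sub[a], sub[b]) != 0) nbrs[a].push_back(b);
  std::vector<int> dist(k);
  double s = 0.0;
  for (int a = 0; a < k; ++a) {
    bfs(nbrs, a, dist);
    for (int b = 0; b < k; ++b)
      if (b != a && dist[b] > 0) s += 1.0 / dist[b];
  }
  return s / ((double)k * (k - 1));
}

// Nodal and whole-network topological metrics of one binary undirected graph.
//
// Conventions (documented in the R wrappers):
//  - nodal clustering is 0 for degree < 2; network Cp is the mean over nodes
//  - nodal path length is the mean distance to *reachable* nodes (0 for an
//    isolated node); network Lp is the mean over finite-distance unordered
//    pairs, with the number of unreachable pairs reported alongside
//  - nodal/global efficiency: mean inverse distance, 1/Inf = 0
//  - nodal local efficiency: global efficiency of the neighbour-induced
//    subgraph; E_loc is the unweighted mean over all nodes
// [[Rcpp::export]]
List graph_metrics_cpp(IntegerMatrix adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nbrs = adjacency_lists(adj);

  NumericVector degree(n), clustering(n), nodal_lp(n), nodal_eglob(n),
      nodal_eloc(n);
  double lp_sum = 0.0;
  long long finite_pairs = 0, unreachable_pairs = 0;

  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i) {
    int k = (int)nbrs[i].size();
    degree[i] = k;

    // clustering: edges among neighbours / (k choose 2)
    if (k >= 2) {
      int t = 0;
      for (int a = 0; a < k; ++a)
        for (int b = a + 1; b < k; ++b)
          if (adj(nbrs[i][a], nbrs[i][b]) != 0) ++t;
      clustering[i] = 2.0 * t / ((double)k * (k - 1));
    } else {
      clustering[i] = 0.0;
    }

    nodal_eloc[i] = subgraph_global_efficiency(adj, nbrs[i]);

    bfs(nbrs, i, dist);
    double dsum = 0.0, inv = 0.0;
    int reach = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dist[j] > 0) {
        dsum += dist[j];
        inv += 1.0 / dist[j];
        ++reach;
        if (j > i) { lp_sum += dist[j]; ++finite_pairs; }
      } else if (j > i) {
        ++unreachable_pairs;
      }
    }
    nodal_lp[i] = reach > 0 ? dsum / reach : 0.0;
    nodal_eglob[i] = n > 1 ? inv / (n - 1) : 0.0;
  }

  double cp = 0.0, eloc = 0.0, eglob = 0.0;
  for (int i = 0; i < n; ++i) {
    cp += clustering[i];
    eloc += nodal_eloc[i];
    eglob += nodal_eglob[i];
  }
  cp /= n; eloc /= n; eglob /= n;
  double lp = finite_pairs > 0 ? lp_sum / finite_pairs : R_PosInf;

  return List::create(
      _["degree"] = degree, _["clustering"] = clustering,
      _["nodal_lp"] = nodal_lp, _["nodal_eglob"] = nodal_eglob,
      _["nodal_eloc"] = nodal_eloc, _["cp"] = cp, _["lp"] = lp,
      _["eglob"] = eglob, _["eloc"] = eloc,
      _["n_unreachable_pairs"] = (double)unreachable_pairs);
}
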