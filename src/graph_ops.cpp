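#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// Dense bitset adjacency: row v occupies `words` uint64 words.
struct BitAdj {
  int n, words;
  std::vector<uint64_t> bits;
  BitAdj(int n_) : n(n_), words((n_ + 63) / 64), bits((size_t)n_ * ((n_ + 63) / 64), 0) {}
  inline void set(int i, int j) {
    bits[(size_t)i * words + (j >> 6)] |= (uint64_t)1 << (j & 63);
    bits[(size_t)j * words + (i >> 6)] |= (uint64_t)1 << (i & 63);
  }
  inline void clear(int i, int j) {
    bits[(size_t)i * words + (j >> 6)] &= ~((uint64_t)1 << (j & 63));
    bits[(size_t)j * words + (i >> 6)] &= ~((uint64_t)1 << (i & 63));
  }
  inline bool has(int i, int j) const {
    return (bits[(size_t)i * words + (j >> 6)] >> (j & 63)) & 1;
  }
  // edges common to the neighborhoods of i and j
  inline int common(int i, int j) const {
    const uint64_t *a = &bits[(size_t)i * words];
    const uint64_t *b = &bits[(size_t)j * words];
    int c = 0;
    for (int w = 0; w < words; ++w)
      c += __builtin_popcountll(a[w] & b[w]);
    return c;
  }
};

static BitAdj build_adj(const IntegerMatrix &edges, int n_nodes) {
  BitAdj adj(n_nodes);
  for (int e = 0; e < edges.nrow(); ++e)
    adj.set(edges(e, 0) - 1, edges(e, 1) - 1);
  return adj;
}

static std::vector<std::vector<int>> adj_lists(const IntegerMatrix &edges,
                                               int n_nodes) {
  std::vector<std::vector<int>> adj(n_nodes);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    adj[i].push_back(j);
    adj[j].push_back(i);
  }
  return adj;
}

// [[Rcpp::export]]
NumericVector cpp_local_clustering(IntegerMatrix edges, int n_nodes) {
  BitAdj adj = build_adj(edges, n_nodes);
  std::vector<std::vector<int>> nb = adj_lists(edges, n_nodes);
  NumericVector ci(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    int k = nb[v].size();
    if (k < 2) { ci[v] = 0.0; continue; }
    long links2 = 0;  // neighbor-neighbor edges, counted twice
    for (int u : nb[v]) links2 += adj.common(v, u);
    ci[v] = (double)links2 / ((double)k * (k - 1));
  }
  return ci;
}

// BFS distances from src over adjacency lists; -1 where unreachable.
static void bfs(const std::vector<std::vector<int>> &adj, int src,
                std::vector<int> &dist) {
  std::fill(dist.begin(), dist.end(), -1);
  std::queue<int> q;
  dist[src] = 0;
  q.push(src);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (int u : adj[v])
      if (dist[u] < 0) { dist[u] = dist[v] + 1; q.push(u); }
  }
}

// Mean shortest path over connected pairs in the largest component.
// [[Rcpp::export]]
List cpp_path_length(IntegerMatrix edges, int n_nodes) {
  std::vector<std::vector<int>> adj = adj_lists(edges, n_nodes);
  std::vector<int> comp(n_nodes, -1);
  int n_comp = 0;
  std::vector<int> dist(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    if (comp[v] >= 0) continue;
    bfs(adj, v, dist);
    for (int u = 0; u < n_nodes; ++u)
      if (dist[u] >= 0) comp[u] = n_comp;
    ++n_comp;
  }
  std::vector<int> comp_size(n_comp, 0);
  for (int v = 0; v < n_nodes; ++v) ++comp_size[comp[v]];
  int big = 0;
  for (int c = 1; c < n_comp; ++c)
    if (comp_size[c] > comp_size[big]) big = c;
  double dsum = 0.0;
  long npairs = 0;
  for (int v = 0; v < n_nodes; ++v) {
    if (comp[v] != big) continue;
    bfs(adj, v, dist);
    for (int u = v + 1; u < n_nodes; ++u)
      if (comp[u] == big) { dsum += dist[u]; ++npairs; }
  }
  double L = npairs > 0 ? dsum / npairs : NA_REAL;
  return List::create(_["path_length"] = L,
                      _["n_components"] = n_comp,
                      _["lcc_size"] = comp_size[big],
                      _["component"] = IntegerVector(comp.begin(), comp.end()));
}

// Degree-preserving Maslov-Sneppen rewiring by double-edge swaps.
// Draws randomness from R's RNG (set.seed() governs reproducibility);
// performs n_swaps successful swaps or stops after max_tries_mult * n_swaps
// attempts (near-complete graphs admit few valid swaps).
// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix edges, int n_nodes, int n_swaps,
                double max_tries_mult) {
  int m = edges.nrow();
  BitAdj adj = build_adj(edges, n_nodes);
  std::vector<std::pair<int,int>> el(m);
  for (int e = 0; e < m; ++e)
    el[e] = std::make_pair(edges(e, 0) - 1, edges(e, 1) - 1);
  RNGScope scope;
  long done = 0, tries = 0;
  long max_tries = (long)(max_tries_mult * (double)n_swaps) + 100;
  while (done < n_swaps && tries < max_tries) {
    ++tries;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2 || e1 >= m || e2 >= m) continue;
    int a = el[e1].first, b = el[e1].second;
    int c = el[e2].first, d = el[e2].second;
    if (unif_rand() < 0.5) std::swap(c, d);  // random orientation
    if (a == c || a == d || b == c || b == d) continue;
    if (adj.has(a, d) || adj.has(c, b)) continue;
    adj.clear(a, b); adj.clear(c, d);
    adj.set(a, d); adj.set(c, b);
    el[e1] = std::make_pair(a, d);
    el[e2] = std::make_pair(c, b);
    ++done;
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    int i = el[e].first, j = el[e].second;
    if (i > j) std::swap(i, j);
    out(e, 0) = i + 1;
    out(e, 1) = j + 1;
  }
  return List::create(_["edges"] = out, _["swaps_done"] = (double)done);
}
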