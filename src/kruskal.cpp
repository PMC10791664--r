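#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path compression + union by rank.
static int uf_find(std::vector<int>& parent, int x) {
  int root = x;
  while (parent[root] != root) root = parent[root];
  while (parent[x] != root) { int nxt = parent[x]; parent[x] = root; x = nxt; }
  return root;
}

// Kruskal edge selection over a pre-sorted edge list (callers sort by
// (distance, i, j) for deterministic tie-breaking). ei/ej are 1-based node
// indices; returns 1-based indices into the edge list of the accepted
// edges. If fewer than n-1 edges are accepted the graph is disconnected
// and the partial forest is returned (callers check the length).
// [[Rcpp::export]]
IntegerVector kruskal_select(IntegerVector ei, IntegerVector ej, int n) {
  int m = ei.size();
  std::vector<int> parent(n), rank_(n, 0);
  for (int k = 0; k < n; ++k) parent[k] = k;
  std::vector<int> out;
  out.reserve(n - 1);
  int taken = 0;
  for (int k = 0; k < m && taken < n - 1; ++k) {
    int a = uf_find(parent, ei[k] - 1);
    int b = uf_find(parent, ej[k] - 1);
    if (a == b) continue;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) rank_[a]++;
    out.push_back(k + 1);
    ++taken;
  }
  return wrap(out);
}

// Connected-component count of an edge list on n nodes.
// [[Rcpp::export]]
int component_count(IntegerVector ei, IntegerVector ej, int n) {
  std::vector<int> parent(n), rank_(n, 0);
  for (int k = 0; k < n; ++k) parent[k] = k;
  int comps = n;
  for (int k = 0; k < ei.size(); ++k) {
    int a = uf_find(parent, ei[k] - 1);
    int b = uf_find(parent, ej[k] - 1);
    if (a == b) continue;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) rank_[a]++;
    --comps;
  }
  return comps;
}
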