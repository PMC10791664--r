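#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest paths on inverse-weight distances d = 1/w for a dense
// symmetric nonnegative weight matrix. Dijkstra from every source; for the
// dense small graphs handled here (n up to a few hundred) linear minimum
// selection beats a binary heap, so the O(n^2) variant is used per source.
// Unreachable pairs are returned as R_PosInf.
// [[Rcpp::export]]
NumericMatrix apsp_inverse_weight(NumericMatrix W) {
  int n = W.nrow();
  NumericMatrix D(n, n);
  std::vector<double> dist(n);
  std::vector<bool> done(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(done.begin(), done.end(), false);
    dist[s] = 0.0;
    for (int iter = 0; iter < n; ++iter) {
      int u = -1;
      double best = R_PosInf;
      for (int v = 0; v < n; ++v) {
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      }
      if (u < 0) break;
      done[u] = true;
      for (int v = 0; v < n; ++v) {
        double w = W(u, v);
        if (v == u || w <= 0.0 || done[v]) continue;
        double cand = dist[u] + 1.0 / w;
        if (cand < dist[v]) dist[v] = cand;
      }
    }
    for (int v = 0; v < n; ++v) D(s, v) = dist[v];
  }
  return D;
}
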