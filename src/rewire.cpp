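#include <Rcpp.h>
using namespace Rcpp;

// Weighted double-edge swaps. Edges are given as 0-based endpoint vectors
// (ei < ej); weights travel with their edge slot so the multiset of edge
// weights is preserved exactly, as is the binary degree sequence. A swap
// picks two edges (a,b), (c,d) on four distinct nodes and rewires to
// (a,d),(c,b) or (a,c),(b,d); swaps that would create a self-loop or a
// parallel edge are rejected (weights are never merged). Uses R's RNG so
// results are reproducible from set.seed() on the R side.
//
// [[Rcpp::export]]
List rewire_swaps_cpp(IntegerVector ei, IntegerVector ej, int n_nodes,
                      int target_swaps, double max_attempts) {
  const int m = ei.size();
  IntegerVector a = clone(ei), b = clone(ej);
  std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
  for (int e = 0; e < m; ++e) {
    adj[(size_t)a[e] * n_nodes + b[e]] = 1;
    adj[(size_t)b[e] * n_nodes + a[e]] = 1;
  }
  auto has = [&](int u, int v) { return adj[(size_t)u * n_nodes + v] != 0; };
  auto set_edge = [&](int u, int v, char val) {
    adj[(size_t)u * n_nodes + v] = val;
    adj[(size_t)v * n_nodes + u] = val;
  };

  int accepted = 0;
  double attempts = 0.0;
  while (accepted < target_swaps && attempts < max_attempts) {
    attempts += 1.0;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int u1 = a[e1], v1 = b[e1], u2 = a[e2], v2 = b[e2];
    // orientation coin: optionally flip the second edge
    if (unif_rand() < 0.5) std::swap(u2, v2);
    // proposed: (u1,v2) and (u2,v1)
    if (u1 == v2 || u2 == v1) continue;
    if (u1 == u2 || v1 == v2) continue;  // four distinct endpoints required
    if (has(u1, v2) || has(u2, v1)) continue;
    set_edge(u1, v1, 0);
    set_edge(u2, v2, 0);
    set_edge(u1, v2, 1);
    set_edge(u2, v1, 1);
    a[e1] = std::min(u1, v2); b[e1] = std::max(u1, v2);
    a[e2] = std::min(u2, v1); b[e2] = std::max(u2, v1);
    ++accepted;
  }

  return List::create(_["ei"] = a, _["ej"] = b, _["accepted"] = accepted,
                      _["exhausted"] = accepted < target_swaps);
}
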