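#include <Rcpp.h>
using namespace Rcpp;

// Swap-based latticization: double-edge swaps accepted only when they do not
// increase the total |pos(u) - pos(v)| distance of edges from the diagonal
// of the adjacency matrix under the node ordering `pos`. Uses R's RNG so
// results are reproducible under set.seed().
//
// E: m x 2 edge list, 1-based vertex indices. pos: length-n permutation.
// Returns the rewired edge list.
// [[Rcpp::export(name = ".latticize_edges")]]
IntegerMatrix latticize_edges(IntegerMatrix E, int n, IntegerVector pos,
                              int n_accept, int max_attempts) {
  int m = E.nrow();
  IntegerMatrix out = clone(E);
  std::vector<bool> adj((size_t)n * n, false);
  for (int e = 0; e < m; e++) {
    int u = out(e, 0) - 1, v = out(e, 1) - 1;
    adj[(size_t)u * n + v] = adj[(size_t)v * n + u] = true;
  }
  int accepted = 0, attempts = 0;
  while (accepted < n_accept && attempts < max_attempts) {
    attempts++;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = out(e1, 0), b = out(e1, 1);
    int c = out(e2, 0), d = out(e2, 1);
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == c || a == d || b == c || b == d) continue;
    if (adj[(size_t)(a - 1) * n + (d - 1)] ||
        adj[(size_t)(c - 1) * n + (b - 1)]) continue;
    int cost_old = std::abs(pos[a - 1] - pos[b - 1]) +
                   std::abs(pos[c - 1] - pos[d - 1]);
    int cost_new = std::abs(pos[a - 1] - pos[d - 1]) +
                   std::abs(pos[c - 1] - pos[b - 1]);
    if (cost_new > cost_old) continue;
    adj[(size_t)(a - 1) * n + (b - 1)] = adj[(size_t)(b - 1) * n + (a - 1)] = false;
    adj[(size_t)(c - 1) * n + (d - 1)] = adj[(size_t)(d - 1) * n + (c - 1)] = false;
    adj[(size_t)(a - 1) * n + (d - 1)] = adj[(size_t)(d - 1) * n + (a - 1)] = true;
    adj[(size_t)(c - 1) * n + (b - 1)] = adj[(size_t)(b - 1) * n + (c - 1)] = true;
    out(e1, 0) = a; out(e1, 1) = d;
    out(e2, 0) = c; out(e2, 1) = b;
    accepted++;
  }
  return out;
}
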