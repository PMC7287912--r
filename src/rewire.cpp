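#include <Rcpp.h>
using namespace Rcpp;

// Maslov-Sneppen degree-preserving randomization: `attempts` double-edge
// swaps are proposed on the edge list; a swap is accepted only if it keeps
// the graph simple (no self-loops, no multi-edges). Uses R's RNG so results
// are reproducible under set.seed().
//
// edges: m x 2 integer matrix, 1-based node indices.
// [[Rcpp::export]]
IntegerMatrix rewire_edgelist_cpp(IntegerMatrix edges, int n_nodes,
                                  double attempts) {
  int m = edges.nrow();
  std::vector<int> from(m), to(m);
  std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    from[e] = a;
    to[e] = b;
    adj[(size_t)a * n_nodes + b] = 1;
    adj[(size_t)b * n_nodes + a] = 1;
  }
  long long n_try = (long long)attempts;
  for (long long it = 0; it < n_try; ++it) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int a = from[e1], b = to[e1];
    int c = from[e2], d = to[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a,d) and (c,b)
    if (a == c || a == d || b == c || b == d) continue;
    if (adj[(size_t)a * n_nodes + d] || adj[(size_t)c * n_nodes + b]) continue;
    adj[(size_t)a * n_nodes + b] = 0;
    adj[(size_t)b * n_nodes + a] = 0;
    adj[(size_t)c * n_nodes + d] = 0;
    adj[(size_t)d * n_nodes + c] = 0;
    adj[(size_t)a * n_nodes + d] = 1;
    adj[(size_t)d * n_nodes + a] = 1;
    adj[(size_t)c * n_nodes + b] = 1;
    adj[(size_t)b * n_nodes + c] = 1;
    to[e1] = d;
    to[e2] = b;
    from[e2] = c;
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = from[e] + 1;
    out(e, 1) = to[e] + 1;
  }
  return out;
}
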