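#include <Rcpp.h>
using namespace Rcpp;

// Weighted double-edge swap: edges (a,b),(c,d) -> (a,d),(c,b), each weight
// travelling with its original edge row. Rejects self-loops and
// multi-edges, so the degree sequence and the edge-weight multiset are
// preserved exactly. Draws from R's RNG so results are governed by
// set.seed() on the R side.
// [[Rcpp::export]]
List rewire_edge_list(IntegerMatrix edges, int n_nodes, int n_success,
                      int max_attempts) {
  int E = edges.nrow();
  IntegerMatrix out = clone(edges);
  std::vector<unsigned char> adj((size_t)n_nodes * n_nodes, 0);
  for (int e = 0; e < E; e++) {
    int a = out(e, 0) - 1, b = out(e, 1) - 1;
    adj[(size_t)a * n_nodes + b] = adj[(size_t)b * n_nodes + a] = 1;
  }
  int done = 0, att = 0;
  while (done < n_success && att < max_attempts) {
    att++;
    int e1 = (int)(unif_rand() * E);
    int e2 = (int)(unif_rand() * E);
    if (e1 >= E) e1 = E - 1;
    if (e2 >= E) e2 = E - 1;
    if (e1 == e2) continue;
    int a = out(e1, 0) - 1, b = out(e1, 1) - 1;
    int c = out(e2, 0) - 1, d = out(e2, 1) - 1;
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == c || a == d || b == c || b == d) continue;
    if (adj[(size_t)a * n_nodes + d] || adj[(size_t)c * n_nodes + b]) continue;
    adj[(size_t)a * n_nodes + b] = adj[(size_t)b * n_nodes + a] = 0;
    adj[(size_t)c * n_nodes + d] = adj[(size_t)d * n_nodes + c] = 0;
    adj[(size_t)a * n_nodes + d] = adj[(size_t)d * n_nodes + a] = 1;
    adj[(size_t)c * n_nodes + b] = adj[(size_t)b * n_nodes + c] = 1;
    out(e1, 0) = a + 1; out(e1, 1) = d + 1;
    out(e2, 0) = c + 1; out(e2, 1) = b + 1;
    done++;
  }
  return List::create(_["edges"] = out, _["swaps"] = done,
                      _["attempts"] = att);
}
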