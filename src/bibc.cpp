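#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Brandes-style betweenness accumulation restricted to source set A and
// target set B on an unweighted undirected simple graph. For disjoint A and
// B every unordered pair (s in A, t in B) is counted exactly once; the
// endpoints of a pair receive no credit for that pair. Disconnected pairs
// contribute nothing.
//
// edges: m x 2 integer matrix, 0-based vertex ids.
// sources / is_target: 0-based ids of A, logical mask of B (length n).
// [[Rcpp::export]]
NumericVector bibc_accumulate(int n, IntegerMatrix edges,
                              IntegerVector sources, LogicalVector is_target) {
  // CSR adjacency
  std::vector<int> deg(n, 0);
  int m = edges.nrow();
  for (int e = 0; e < m; ++e) { deg[edges(e, 0)]++; deg[edges(e, 1)]++; }
  std::vector<int> start(n + 1, 0);
  for (int v = 0; v < n; ++v) start[v + 1] = start[v] + deg[v];
  std::vector<int> adj(2 * m);
  std::vector<int> fill(start.begin(), start.end() - 1);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    adj[fill[a]++] = b;
    adj[fill[b]++] = a;
  }

  NumericVector bc(n);
  std::vector<int> dist(n), order_stack;
  std::vector<double> sigma(n), delta(n);
  order_stack.reserve(n);

  for (int si = 0; si < sources.size(); ++si) {
    int s = sources[si];
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    order_stack.clear();

    std::queue<int> q;
    dist[s] = 0; sigma[s] = 1.0; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order_stack.push_back(v);
      for (int k = start[v]; k < start[v + 1]; ++k) {
        int w = adj[k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) sigma[w] += sigma[v];
      }
    }
    // reverse-BFS dependency accumulation toward the source
    for (int i = (int)order_stack.size() - 1; i >= 0; --i) {
      int w = order_stack[i];
      double coeff = (is_target[w] && w != s ? 1.0 : 0.0) + delta[w];
      for (int k = start[w]; k < start[w + 1]; ++k) {
        int v = adj[k];
        if (dist[v] == dist[w] - 1)
          delta[v] += sigma[v] / sigma[w] * coeff;
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  return bc;
}
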