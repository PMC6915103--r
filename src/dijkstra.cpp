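#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Dijkstra shortest path on a CSR graph with deterministic tie-breaking:
// among equal-distance relaxations the smaller predecessor id wins, so the
// returned path is independent of traversal order.
// ptr: 1-based CSR row pointers (length n+1), idx: column indices (1-based),
// w: edge weights. src/dst 1-based.
// [[Rcpp::export(name = ".dijkstra_cpp")]]
List dijkstra_cpp(IntegerVector ptr, IntegerVector idx, NumericVector w,
                  int n, int src, int dst) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n + 1, INF);
  std::vector<int> pred(n + 1, 0);
  std::vector<char> done(n + 1, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[src] = 0.0;
  pq.push(QE(0.0, src));
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (u == dst) break;
    double du = top.first;
    for (int e = ptr[u - 1]; e < ptr[u]; ++e) {  // ptr already 1-based offsets
      int v = idx[e - 1];
      double nd = du + w[e - 1];
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u;
        pq.push(QE(nd, v));
      } else if (nd == dist[v] && !done[v] && pred[v] != 0 && u < pred[v]) {
        pred[v] = u;
      }
    }
  }
  if (dist[dst] == INF) {
    return List::create(_["found"] = false);
  }
  std::vector<int> path;
  for (int v = dst; v != 0; v = pred[v]) {
    path.push_back(v);
    if (v == src) break;
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["found"] = true,
                      _["path"] = wrap(path),
                      _["length"] = dist[dst]);
}
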