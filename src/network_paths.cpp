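#include <Rcpp.h>
using namespace Rcpp;

// Floyd-Warshall all-pairs shortest distances with shortest-path counts.
// w: symmetric weight matrix, R_PosInf for non-edges, any diagonal ignored.
// Path-length ties are resolved within `tol`; co-optimal paths accumulate.
// Counting is exact because every shortest path is credited exactly once,
// at the iteration of its highest-indexed intermediate vertex.
// [[Rcpp::export]]
List cpp_floyd_warshall(NumericMatrix w, double tol = 1e-9) {
  int n = w.nrow();
  NumericMatrix d(clone(w));
  NumericMatrix g(n, n);
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < n; j++)
      g(i, j) = (i != j && R_finite(d(i, j))) ? 1.0 : 0.0;
    d(i, i) = 0.0;
  }
  for (int k = 0; k < n; k++) {
    for (int i = 0; i < n; i++) {
      if (i == k || !R_finite(d(i, k))) continue;
      double dik = d(i, k);
      for (int j = 0; j < n; j++) {
        if (j == k || j == i || !R_finite(d(k, j))) continue;
        double alt = dik + d(k, j);
        if (alt < d(i, j) - tol) {
          d(i, j) = alt;
          g(i, j) = g(i, k) * g(k, j);
        } else if (alt <= d(i, j) + tol) {
          g(i, j) += g(i, k) * g(k, j);
        }
      }
    }
  }
  return List::create(_["dist"] = d, _["counts"] = g);
}

static inline double path_count(const NumericMatrix &g, int a, int b) {
  return (a == b) ? 1.0 : g(a, b);
}

// Betweenness of every node: sum over unordered pairs j<k (excluding the
// node itself) of the fraction of shortest j-k paths passing through it.
// Pairs in other components contribute nothing (infinite distance).
// [[Rcpp::export]]
NumericVector cpp_node_betweenness(NumericMatrix d, NumericMatrix g,
                                   double tol = 1e-9) {
  int n = d.nrow();
  NumericVector cb(n);
  for (int i = 0; i < n; i++) {
    double s = 0.0;
    for (int j = 0; j < n; j++) {
      if (j == i || !R_finite(d(j, i))) continue;
      for (int k = j + 1; k < n; k++) {
        if (k == i || !R_finite(d(j, k)) || g(j, k) <= 0.0) continue;
        if (std::abs(d(j, i) + d(i, k) - d(j, k)) <= tol)
          s += g(j, i) * g(i, k) / g(j, k);
      }
    }
    cb[i] = s;
  }
  return cb;
}

// Betweenness of every edge (fraction of shortest paths traversing it,
// either orientation). edges: 1-based (u, v) index pairs; w: edge weights.
// [[Rcpp::export]]
NumericVector cpp_edge_betweenness(NumericMatrix d, NumericMatrix g,
                                   IntegerMatrix edges, NumericVector w,
                                   double tol = 1e-9) {
  int n = d.nrow(), ne = edges.nrow();
  NumericVector eb(ne);
  for (int e = 0; e < ne; e++) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    double we = w[e], s = 0.0;
    for (int j = 0; j < n; j++) {
      for (int k = j + 1; k < n; k++) {
        if (!R_finite(d(j, k)) || g(j, k) <= 0.0) continue;
        double cnt = 0.0;
        if (R_finite(d(j, u)) && R_finite(d(v, k)) &&
            std::abs(d(j, u) + we + d(v, k) - d(j, k)) <= tol)
          cnt += path_count(g, j, u) * path_count(g, v, k);
        if (R_finite(d(j, v)) && R_finite(d(u, k)) &&
            std::abs(d(j, v) + we + d(u, k) - d(j, k)) <= tol)
          cnt += path_count(g, j, v) * path_count(g, u, k);
        s += cnt / g(j, k);
      }
    }
    eb[e] = s;
  }
  return eb;
}
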