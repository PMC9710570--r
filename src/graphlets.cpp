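// Graphlet orbit counting for all connected 2-4-node graphlets (15 orbits,
// standard numbering: 0 edge; 1-2 path ends/middle; 3 triangle; 4-5 4-path
// ends/middle; 6-7 claw leaves/center; 8 4-cycle; 9-11 paw leaf/rim/hub;
// 12-13 diamond rim/hub; 14 4-clique). Connected induced subgraphs are
// enumerated exactly once with the ESU algorithm; each occurrence is
// classified by (size, edge count, max within-subgraph degree) and every
// member node's orbit is determined by its within-subgraph degree.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
using namespace Rcpp;

static inline bool hasEdge(const std::vector<std::vector<int>> &adj,
                           int a, int b) {
  const std::vector<int> &v = adj[a];
  return std::binary_search(v.begin(), v.end(), b);
}

// [[Rcpp::export(name = ".countOrbitsCpp")]]
NumericMatrix countOrbitsCpp(int n, IntegerMatrix edges) {
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  for (int i = 0; i < n; ++i) std::sort(adj[i].begin(), adj[i].end());

  NumericMatrix orb(n, 15);
  for (int i = 0; i < n; ++i) orb(i, 0) = (double)adj[i].size();

  std::vector<int> markCnt(n, 0);
  std::vector<int> sub;
  int K = 3;

  std::function<void(const std::vector<int> &)> process =
      [&](const std::vector<int> &s) {
        int k = (int)s.size();
        int deg[4] = {0, 0, 0, 0};
        int nEdge = 0;
        for (int i = 0; i < k; ++i)
          for (int j = i + 1; j < k; ++j)
            if (hasEdge(adj, s[i], s[j])) {
              ++nEdge;
              ++deg[i];
              ++deg[j];
            }
        int maxDeg = *std::max_element(deg, deg + k);
        for (int i = 0; i < k; ++i) {
          int o = -1;
          if (k == 3) {
            o = (nEdge == 3) ? 3 : (deg[i] == 1 ? 1 : 2);
          } else {
            switch (nEdge) {
            case 3:
              o = (maxDeg == 3) ? (deg[i] == 1 ? 6 : 7)
                                : (deg[i] == 1 ? 4 : 5);
              break;
            case 4:
              o = (maxDeg == 3)
                      ? (deg[i] == 1 ? 9 : (deg[i] == 2 ? 10 : 11))
                      : 8;
              break;
            case 5:
              o = (deg[i] == 2) ? 12 : 13;
              break;
            default:
              o = 14;
            }
          }
          orb(s[i], o) += 1.0;
        }
      };

  std::function<void(std::vector<int>, int)> extend =
      [&](std::vector<int> ext, int root) {
        if ((int)sub.size() == K) {
          process(sub);
          return;
        }
        while (!ext.empty()) {
          int w = ext.back();
          ext.pop_back();
          std::vector<int> newExt = ext;
          for (int u : adj[w])
            if (u > root && markCnt[u] == 0) newExt.push_back(u);
          sub.push_back(w);
          for (int u : adj[w]) ++markCnt[u];
          ++markCnt[w];
          extend(newExt, root);
          for (int u : adj[w]) --markCnt[u];
          --markCnt[w];
          sub.pop_back();
        }
      };

  for (K = 3; K <= 4; ++K) {
    for (int v = 0; v < n; ++v) {
      sub.assign(1, v);
      ++markCnt[v];
      std::vector<int> ext;
      for (int u : adj[v]) {
        ++markCnt[u];
        if (u > v) ext.push_back(u);
      }
      extend(ext, v);
      --markCnt[v];
      for (int u : adj[v]) --markCnt[u];
    }
  }
  return orb;
}
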