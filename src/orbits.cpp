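#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Per-node counts of the 15 graphlet automorphism orbits (graphlets on 2-4
// nodes, induced semantics, canonical numbering: edge 0; 3-path ends 1,
// middle 2; triangle 3; 4-path ends 4, middles 5; 3-star leaves 6, centre 7;
// 4-cycle 8; tailed triangle tail 9, triangle-degree-2 10, attachment 11;
// diamond degree-2 12, degree-3 13; K4 14).
//
// Strategy: degree/triangle bookkeeping gives orbits 0-3 directly. Dense
// 4-node graphlets (diamond, K4) are enumerated per edge over pairs of common
// neighbours; the tailed triangle per triangle with inclusion-exclusion on
// tail candidates. The remaining sparse orbits (4-path, 3-star, 4-cycle,
// tail-end) follow from non-induced walk counts by subtracting the denser
// graphlets' contributions. No all-fours enumeration is ever performed.

static inline bool has_edge(const std::vector<std::vector<int>>& adj, int u, int w) {
  const std::vector<int>& a = adj[u];
  return std::binary_search(a.begin(), a.end(), w);
}

// [[Rcpp::export(name = ".count_orbits_cpp")]]
IntegerMatrix count_orbits_cpp(int n, IntegerMatrix edges) {
  const int m = edges.nrow();
  std::vector<std::vector<int>> adj(n);
  std::vector<int> eu(m), ev(m);
  for (int e = 0; e < m; ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    if (u == v) stop("self-loop in edge list");
    if (u > v) std::swap(u, v);
    eu[e] = u; ev[e] = v;
    adj[u].push_back(v);
    adj[v].push_back(u);
  }
  for (int i = 0; i < n; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    if (std::adjacent_find(adj[i].begin(), adj[i].end()) != adj[i].end())
      stop("duplicate edge in edge list");
  }

  typedef long long ll;
  std::vector<ll> deg(n), S(n, 0), Tacc(n, 0);
  std::vector<ll> o(15 * (size_t)n, 0); // column-major [orbit*n + v]
  for (int v = 0; v < n; ++v) deg[v] = (ll)adj[v].size();
  for (int v = 0; v < n; ++v)
    for (int u : adj[v]) S[v] += deg[u];

  // pass 1: common-neighbour count per edge
  std::vector<int> ce(m, 0);
  std::vector<int> cn; cn.reserve(256);
  for (int e = 0; e < m; ++e) {
    const std::vector<int>& a = adj[eu[e]];
    const std::vector<int>& b = adj[ev[e]];
    int c = 0;
    size_t i = 0, j = 0;
    while (i < a.size() && j < b.size()) {
      if (a[i] < b[j]) ++i;
      else if (a[i] > b[j]) ++j;
      else { ++c; ++i; ++j; }
    }
    ce[e] = c;
    Tacc[eu[e]] += c;
    Tacc[ev[e]] += c;
  }
  std::vector<ll> T(n);
  for (int v = 0; v < n; ++v) T[v] = Tacc[v] / 2;

  // edge-id lookup: parallel structure to adj
  std::vector<std::vector<int>> adj_eid(n);
  for (int i = 0; i < n; ++i) adj_eid[i].resize(adj[i].size());
  for (int e = 0; e < m; ++e) {
    int u = eu[e], v = ev[e];
    size_t pu = std::lower_bound(adj[u].begin(), adj[u].end(), v) - adj[u].begin();
    size_t pv = std::lower_bound(adj[v].begin(), adj[v].end(), u) - adj[v].begin();
    adj_eid[u][pu] = e;
    adj_eid[v][pv] = e;
  }
  auto edge_id = [&](int u, int v) -> int {
    const std::vector<int>& a = adj[u];
    size_t p = std::lower_bound(a.begin(), a.end(), v) - a.begin();
    return adj_eid[u][p];
  };

  ll* o9  = &o[9 * (size_t)n];  ll* o10 = &o[10 * (size_t)n];
  ll* o11 = &o[11 * (size_t)n]; ll* o12 = &o[12 * (size_t)n];
  ll* o13 = &o[13 * (size_t)n];
  std::vector<ll> ev14(n, 0);

  // pass 2: per-edge common-neighbour list -> triangles, diamonds, K4s
  std::vector<int> tcap; tcap.reserve(256);
  for (int e = 0; e < m; ++e) {
    const int u = eu[e], v = ev[e];
    const std::vector<int>& a = adj[u];
    const std::vector<int>& b = adj[v];
    cn.clear();
    size_t i = 0, j = 0;
    while (i < a.size() && j < b.size()) {
      if (a[i] < b[j]) ++i;
      else if (a[i] > b[j]) ++j;
      else { cn.push_back(a[i]); ++i; ++j; }
    }
    const int c = (int)cn.size();
    // triangles (u < v < w): tailed-triangle bookkeeping
    for (int k = 0; k < c; ++k) {
      const int w = cn[k];
      if (w <= v) continue;
      // t3 = |N(u) & N(v) & N(w)| = |cn & N(w)|
      int t3 = 0;
      const std::vector<int>& aw = adj[w];
      size_t p = 0, q = 0;
      while (p < cn.size() && q < aw.size()) {
        if (cn[p] < aw[q]) ++p;
        else if (cn[p] > aw[q]) ++q;
        else { ++t3; ++p; ++q; }
      }
      const int cuv = ce[e];
      const int cuw = ce[edge_id(u, w)];
      const int cvw = ce[edge_id(v, w)];
      const ll tau_u = (deg[u] - 2) - (cuv - 1) - (cuw - 1) + t3;
      const ll tau_v = (deg[v] - 2) - (cuv - 1) - (cvw - 1) + t3;
      const ll tau_w = (deg[w] - 2) - (cuw - 1) - (cvw - 1) + t3;
      o11[u] += tau_u; o10[v] += tau_u; o10[w] += tau_u;
      o11[v] += tau_v; o10[u] += tau_v; o10[w] += tau_v;
      o11[w] += tau_w; o10[u] += tau_w; o10[v] += tau_w;
    }
    // pairs of common neighbours: diamond (hub edge u-v) or K4
    for (int k = 0; k < c; ++k) {
      const int w = cn[k];
      for (int l = k + 1; l < c; ++l) {
        const int x = cn[l];
        if (has_edge(adj, w, x)) {
          ev14[u]++; ev14[v]++; ev14[w]++; ev14[x]++;
        } else {
          o13[u]++; o13[v]++; o12[w]++; o12[x]++;
        }
      }
    }
  }

  // pass 3: non-induced 4-cycles through v via opposite-corner counts
  std::vector<ll> NC4(n, 0);
  {
    std::vector<int> cnt(n, 0);
    std::vector<int> touched; touched.reserve(4096);
    for (int v = 0; v < n; ++v) {
      touched.clear();
      for (int u : adj[v]) {
        for (int w : adj[u]) {
          if (w == v) continue;
          if (cnt[w] == 0) touched.push_back(w);
          cnt[w]++;
        }
      }
      ll acc = 0;
      for (int w : touched) {
        const ll mm = cnt[w];
        acc += mm * (mm - 1) / 2;
        cnt[w] = 0;
      }
      NC4[v] = acc;
    }
  }

  // assemble
  std::vector<ll> sumTneigh(n, 0), sumC2(n, 0), sumSd(n, 0);
  for (int v = 0; v < n; ++v) {
    for (int u : adj[v]) {
      sumTneigh[v] += T[u];
      sumC2[v] += (deg[u] - 1) * (deg[u] - 2) / 2;
      sumSd[v] += S[u] - deg[u];
    }
  }
  IntegerMatrix out(n, 15);
  for (int v = 0; v < n; ++v) {
    const ll d = deg[v], t = T[v];
    const ll v9  = sumTneigh[v] - 2 * t - 2 * o12[v] - 3 * ev14[v] / 6;
    const ll v14 = ev14[v] / 6;
    const ll v8  = NC4[v] - o12[v] - o13[v] - 3 * v14;
    const ll v7  = d * (d - 1) * (d - 2) / 6 - o11[v] - o13[v] - v14;
    const ll v6  = sumC2[v] - v9 - o10[v] - 2 * o12[v] - o13[v] - 3 * v14;
    const ll npend = sumSd[v] - d * (d - 1) - 2 * t;
    const ll v4  = npend - 2 * v8 - 2 * v9 - o10[v] - 4 * o12[v] - 2 * o13[v] - 6 * v14;
    const ll npmid = (d - 1) * (S[v] - d) - 2 * t;
    const ll v5  = npmid - 2 * v8 - o10[v] - 2 * o11[v] - 2 * o12[v] - 4 * o13[v] - 6 * v14;
    const ll row[15] = {
      d,                       // 0
      S[v] - d - 2 * t,        // 1
      d * (d - 1) / 2 - t,     // 2
      t,                       // 3
      v4, v5, v6, v7, v8, v9,
      o10[v], o11[v], o12[v], o13[v], v14
    };
    for (int k = 0; k < 15; ++k) {
      if (row[k] < 0 || row[k] > INT32_MAX) stop("orbit count out of integer range");
      out(v, k) = (int)row[k];
    }
  }
  return out;
}
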