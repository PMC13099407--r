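#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Cell-list neighbour search: peak memory scales with the number of atoms
// plus the number of contacts, never with the full N x N distance matrix.

struct Grid {
  double ox, oy, oz, h;
  int64_t ny, nz;
  std::unordered_map<int64_t, std::vector<int>> cells;

  Grid(const NumericMatrix& xyz, double h_) : h(h_) {
    const int n = xyz.nrow();
    ox = oy = oz = 0.0;
    if (n > 0) {
      ox = xyz(0, 0); oy = xyz(0, 1); oz = xyz(0, 2);
      for (int i = 1; i < n; ++i) {
        ox = std::min(ox, xyz(i, 0));
        oy = std::min(oy, xyz(i, 1));
        oz = std::min(oz, xyz(i, 2));
      }
    }
    double my = 0, mz = 0;
    for (int i = 0; i < n; ++i) {
      my = std::max(my, xyz(i, 1) - oy);
      mz = std::max(mz, xyz(i, 2) - oz);
    }
    ny = (int64_t)(my / h) + 3;
    nz = (int64_t)(mz / h) + 3;
    cells.reserve((size_t)n * 2);
    for (int i = 0; i < n; ++i)
      cells[key(cx(xyz(i, 0)), cy(xyz(i, 1)), cz(xyz(i, 2)))].push_back(i);
  }
  int64_t cx(double x) const { return (int64_t)std::floor((x - ox) / h); }
  int64_t cy(double y) const { return (int64_t)std::floor((y - oy) / h); }
  int64_t cz(double z) const { return (int64_t)std::floor((z - oz) / h); }
  int64_t key(int64_t a, int64_t b, int64_t c) const { return (a * (ny + 2) + b) * (nz + 2) + c; }
};

// [[Rcpp::export(name = ".neighbor_pairs_cpp")]]
IntegerMatrix neighbor_pairs_cpp(NumericMatrix xyz, double cutoff) {
  const int n = xyz.nrow();
  const double c2 = cutoff * cutoff;
  Grid g(xyz, cutoff);
  std::vector<int> ri, rj;
  ri.reserve((size_t)n * 8);
  rj.reserve((size_t)n * 8);
  for (int i = 0; i < n; ++i) {
    const double x = xyz(i, 0), y = xyz(i, 1), z = xyz(i, 2);
    const int64_t a = g.cx(x), b = g.cy(y), c = g.cz(z);
    for (int64_t da = -1; da <= 1; ++da)
      for (int64_t db = -1; db <= 1; ++db)
        for (int64_t dc = -1; dc <= 1; ++dc) {
          auto it = g.cells.find(g.key(a + da, b + db, c + dc));
          if (it == g.cells.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            const double dx = x - xyz(j, 0), dy = y - xyz(j, 1), dz = z - xyz(j, 2);
            if (dx * dx + dy * dy + dz * dz < c2) { // strict <
              ri.push_back(i + 1);
              rj.push_back(j + 1);
            }
          }
        }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t k = 0; k < ri.size(); ++k) {
    out(k, 0) = ri[k];
    out(k, 1) = rj[k];
  }
  return out;
}

// For each row of `query`, TRUE iff some row of `ref` lies within `radius`
// (inclusive). Used to collect the spatial environment of a partition core.
// [[Rcpp::export(name = ".any_within_cpp")]]
LogicalVector any_within_cpp(NumericMatrix query, NumericMatrix ref, double radius) {
  const int nq = query.nrow();
  const double r2 = radius * radius;
  LogicalVector out(nq);
  if (ref.nrow() == 0) return out;
  Grid g(ref, radius);
  for (int i = 0; i < nq; ++i) {
    const double x = query(i, 0), y = query(i, 1), z = query(i, 2);
    const int64_t a = g.cx(x), b = g.cy(y), c = g.cz(z);
    bool hit = false;
    for (int64_t da = -1; da <= 1 && !hit; ++da)
      for (int64_t db = -1; db <= 1 && !hit; ++db)
        for (int64_t dc = -1; dc <= 1 && !hit; ++dc) {
          auto it = g.cells.find(g.key(a + da, b + db, c + dc));
          if (it == g.cells.end()) continue;
          for (int j : it->second) {
            const double dx = x - ref(j, 0), dy = y - ref(j, 1), dz = z - ref(j, 2);
            if (dx * dx + dy * dy + dz * dz <= r2) { hit = true; break; }
          }
        }
    out[i] = hit;
  }
  return out;
}
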