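// Marker-controlled watershed by priority flooding, and connected
// components, on dense height matrices.

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {
struct Cell {
  double h;          // height (flood from high to low)
  long long order;   // FIFO tie-break for determinism
  int idx;
};
struct CellCmp {
  bool operator()(const Cell& a, const Cell& b) const {
    if (a.h != b.h) return a.h < b.h;   // lower priority = lower height
    return a.order > b.order;           // earlier insertion first
  }
};
}

// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(NumericMatrix height, IntegerMatrix markers) {
  const int nr = height.nrow(), nc = height.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("marker matrix dimensions must match the height matrix");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<Cell, std::vector<Cell>, CellCmp> pq;
  long long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0) {
        lab(r, c) = markers(r, c);
        pq.push({height(r, c), order++, c * nr + r});
      }
  if (pq.empty()) stop("no markers supplied to watershed");
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Cell cur = pq.top(); pq.pop();
    int r = cur.idx % nr, c = cur.idx / nr;
    int l = lab(r, c);
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (lab(r2, c2) == 0) {
        lab(r2, c2) = l;
        pq.push({height(r2, c2), order++, c2 * nr + r2});
      }
    }
  }
  return lab;
}

// 4-connected component of `mask` containing (row0, col0); 1-based seed.
// [[Rcpp::export(name = ".connected_component")]]
LogicalMatrix connected_component(LogicalMatrix mask, int row0, int col0) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  if (row0 < 1 || row0 > nr || col0 < 1 || col0 > nc || !mask(row0 - 1, col0 - 1))
    return out;
  std::vector<int> stack;
  stack.push_back((col0 - 1) * nr + (row0 - 1));
  out(row0 - 1, col0 - 1) = true;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) && !out(r2, c2)) {
        out(r2, c2) = true;
        stack.push_back(c2 * nr + r2);
      }
    }
  }
  return out;
}
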