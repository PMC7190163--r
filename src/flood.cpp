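#include <Rcpp.h>
#include <deque>
#include <algorithm>
using namespace Rcpp;

// Descending priority-flood watershed on a 2D surface restricted to a mask.
//
// Basins grow from regional maxima downwards (bright-object orientation, as
// for a nuclei stain).  8-connectivity.  Deterministic: pixels are processed
// level by level in decreasing surface value; within a level, pixels touching
// an already-labelled strictly-higher pixel take the smallest such label and
// seed a FIFO that floods the rest of the plateau in breadth-first order;
// any remaining plateau is a new regional maximum and receives a fresh label.
// Every masked pixel ends up labelled (no watershed-line pixels), which is
// what the basin-graph merging step downstream expects.
// [[Rcpp::export]]
IntegerMatrix flood_watershed_cpp(NumericMatrix surf, LogicalMatrix mask) {
  int nr = surf.nrow(), nc = surf.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> idx;
  idx.reserve((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j)) idx.push_back(j * nr + i);
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    double va = surf[a], vb = surf[b];
    if (va != vb) return va > vb;
    return a < b;
  });
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next_label = 0;
  size_t p = 0, n = idx.size();
  while (p < n) {
    size_t q = p;
    double lev = surf[idx[p]];
    while (q < n && surf[idx[q]] == lev) ++q;
    std::deque<int> fifo;
    for (size_t k = p; k < q; ++k) {
      int id = idx[k], i = id % nr, j = id / nr, best = 0;
      double best_v = 0;
      // steepest ascent: take the label of the highest strictly-higher
      // labelled neighbour (ties to the smaller label)
      for (int d = 0; d < 8; ++d) {
        int ii = i + di[d], jj = j + dj[d];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int l = lab(ii, jj);
        if (l <= 0 || surf(ii, jj) <= lev) continue;
        double v = surf(ii, jj);
        if (best == 0 || v > best_v || (v == best_v && l < best)) {
          best = l;
          best_v = v;
        }
      }
      if (best > 0) { lab[id] = best; fifo.push_back(id); }
    }
    while (!fifo.empty()) {
      int id = fifo.front(); fifo.pop_front();
      int i = id % nr, j = id / nr, l0 = lab[id];
      for (int d = 0; d < 8; ++d) {
        int ii = i + di[d], jj = j + dj[d];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int nid = jj * nr + ii;
        if (!mask(ii, jj) || lab[nid] > 0) continue;
        if (surf[nid] == lev) { lab[nid] = l0; fifo.push_back(nid); }
      }
    }
    for (size_t k = p; k < q; ++k) {
      int id = idx[k];
      if (lab[id] > 0) continue;
      lab[id] = ++next_label;
      std::deque<int> comp(1, id);
      while (!comp.empty()) {
        int cid = comp.front(); comp.pop_front();
        int i = cid % nr, j = cid / nr;
        for (int d = 0; d < 8; ++d) {
          int ii = i + di[d], jj = j + dj[d];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          int nid = jj * nr + ii;
          if (!mask(ii, jj) || lab[nid] > 0) continue;
          if (surf[nid] == lev) { lab[nid] = lab[id]; comp.push_back(nid); }
        }
      }
    }
    p = q;
  }
  return lab;
}
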