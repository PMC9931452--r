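#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Meyer-style flooding from labelled markers over an elevation surface.
// markers: 0 = unknown, 1 = background, >= 2 = seed components.
// Returns the completed label grid; pixels where two basins meet get -1.
// Ties in elevation are broken FIFO (insertion order), so the result is
// deterministic for a given (elevation, markers) pair.

struct QEntry {
  double elev;
  long order;
  int idx;
};

struct QCompare {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;                      // FIFO on ties
  }
};

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export]]
IntegerMatrix ws_flood(NumericMatrix elev, IntegerMatrix markers) {
  const int H = elev.nrow(), W = elev.ncol();
  if (markers.nrow() != H || markers.ncol() != W)
    stop("elevation and marker grids have different shapes");
  IntegerMatrix lab(H, W);
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  std::vector<bool> queued((size_t)H * W, false);
  long order = 0;

  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      lab(r, c) = markers(r, c);

  // seed the queue with unknown pixels adjacent to any labelled pixel
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (lab(r, c) != 0) continue;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR8[k], cc = c + DC8[k];
        if (rr >= 0 && rr < H && cc >= 0 && cc < W && lab(rr, cc) > 0) {
          pq.push({elev(r, c), order++, c * H + r});
          queued[(size_t)c * H + r] = true;
          break;
        }
      }
    }
  }

  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    int r = e.idx % H, c = e.idx / H;
    if (lab(r, c) != 0) continue;
    int found = 0;
    bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      int l = lab(rr, cc);
      if (l > 0) {
        if (found == 0) found = l;
        else if (l != found) conflict = true;
      }
    }
    lab(r, c) = conflict ? -1 : found;  // found > 0 by queue construction
    if (conflict) continue;  // boundary pixels do not propagate
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      size_t i2 = (size_t)cc * H + rr;
      if (lab(rr, cc) == 0 && !queued[i2]) {
        pq.push({elev(rr, cc), order++, cc * H + rr});
        queued[i2] = true;
      }
    }
  }

  // unknown pixels fully walled in by watershed lines belong to the lines
  bool any_pos = false;
  for (int c = 0; c < W && !any_pos; ++c)
    for (int r = 0; r < H; ++r)
      if (markers(r, c) > 0) { any_pos = true; break; }
  if (any_pos)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        if (lab(r, c) == 0) lab(r, c) = -1;
  return lab;
}

// 8-connected component labelling of a 0/1 mask; labels 1..k in raster
// order of first encounter.

// [[Rcpp::export]]
IntegerMatrix cc_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(c * H + r);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr0 = idx % H, cc0 = idx / H;
        for (int k = 0; k < 8; ++k) {
          int rr = rr0 + DR8[k], cc = cc0 + DC8[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(cc * H + rr);
          }
        }
      }
    }
  }
  return lab;
}
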