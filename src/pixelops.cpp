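#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Row-major scan order and fixed neighbour order keep both algorithms
// fully deterministic for a given input.

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {0, -1, 1, 0};

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int *DR = (connectivity == 8) ? DR8 : DR4;
  const int *DC = (connectivity == 8) ? DC8 : DC4;
  int nnb = connectivity;
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r * W + c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p / W, pc = p % W;
        for (int k = 0; k < nnb; ++k) {
          int nr = pr + DR[k], nc = pc + DC[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nr * W + nc);
          }
        }
      }
    }
  }
  return lab;
}

struct QNode {
  double value;    // distance-map height; flood high values first
  long long order; // insertion counter; earlier wins on equal height
  int r, c, label;
};

struct QCmp {
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.value != b.value) return a.value < b.value; // max-heap on value
    return a.order > b.order;                         // FIFO on ties
  }
};

// Marker-controlled watershed by priority flooding of the (negated)
// distance map: pixels are claimed in decreasing height order starting
// from the seed markers, restricted to the foreground mask. Equal-height
// contested pixels go to whichever front reached the queue first, which
// for symmetric inputs means the lower-indexed seed.
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(NumericMatrix dmap, IntegerMatrix markers,
                              LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int H = dmap.nrow(), W = dmap.ncol();
  if (markers.nrow() != H || markers.ncol() != W ||
      mask.nrow() != H || mask.ncol() != W)
    stop("dmap, markers and mask must share their shape");
  const int *DR = (connectivity == 8) ? DR8 : DR4;
  const int *DC = (connectivity == 8) ? DC8 : DC4;
  int nnb = connectivity;
  IntegerMatrix lab(H, W);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  long long counter = 0;
  // seeds enter the queue in increasing label order
  int maxlab = 0;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      if (markers(r, c) > maxlab) maxlab = markers(r, c);
  for (int l = 1; l <= maxlab; ++l) {
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        if (markers(r, c) == l) {
          if (!mask(r, c)) stop("marker pixel outside the foreground mask");
          if (lab(r, c) == 0) {
            lab(r, c) = l;
            pq.push({dmap(r, c), counter++, r, c, l});
          }
        }
      }
    }
  }
  while (!pq.empty()) {
    QNode nd = pq.top();
    pq.pop();
    for (int k = 0; k < nnb; ++k) {
      int nr = nd.r + DR[k], nc = nd.c + DC[k];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (!mask(nr, nc) || lab(nr, nc) != 0) continue;
      lab(nr, nc) = nd.label;
      pq.push({dmap(nr, nc), counter++, nr, nc, nd.label});
    }
  }
  return lab;
}
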