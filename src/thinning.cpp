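#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-neighbourhood in the order p2..p9 of the thinning literature:
// N, NE, E, SE, S, SW, W, NW (row grows downward, col to the right).
static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static inline void neighbours(const std::vector<unsigned char> &img, int h, int w,
                              int r, int c, int p[8]) {
  for (int k = 0; k < 8; ++k) {
    int rr = r + DR[k], cc = c + DC[k];
    p[k] = (rr >= 0 && rr < h && cc >= 0 && cc < w)
               ? img[(size_t)cc * h + rr]
               : 0;
  }
}

static inline int transitions(const int p[8]) {
  int a = 0;
  for (int k = 0; k < 8; ++k) a += (p[k] == 0 && p[(k + 1) % 8] == 1);
  return a;
}

// Zhang-Suen morphological thinning to a 1-pixel-wide skeleton, followed by a
// staircase cleanup pass that sequentially removes redundant corner pixels
// (exactly two neighbours that are themselves 8-adjacent). Topology is
// preserved: only simple points (crossing number 1) are ever deleted, and
// end points (one neighbour) are never touched.
// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  std::vector<unsigned char> img((size_t)h * w, 0);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      img[(size_t)c * h + r] = mask(r, c) ? 1 : 0;

  // Candidates for each directional subpass are selected from a snapshot
  // (the textbook parallel update, which gives well-centred skeletons), but
  // each deletion is re-validated on the current image: with a purely
  // parallel update a 2x2 component satisfies the deletion test at all four
  // pixels simultaneously and vanishes, breaking topology preservation.
  std::vector<unsigned char> snap;
  std::vector<size_t> cand;
  bool changed = true;
  int p[8];
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      snap = img;
      cand.clear();
      for (int c = 0; c < w; ++c) {
        for (int r = 0; r < h; ++r) {
          if (!snap[(size_t)c * h + r]) continue;
          neighbours(snap, h, w, r, c, p);
          int b = 0;
          for (int k = 0; k < 8; ++k) b += p[k];
          if (b < 2 || b > 6) continue;
          if (transitions(p) != 1) continue;
          if (step == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // N*E*S
            if (p[2] * p[4] * p[6] != 0) continue;  // E*S*W
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // N*E*W
            if (p[0] * p[4] * p[6] != 0) continue;  // N*S*W
          }
          cand.push_back((size_t)c * h + r);
        }
      }
      for (size_t i = 0; i < cand.size(); ++i) {
        size_t idx = cand[i];
        int r = (int)(idx % h), c = (int)(idx / h);
        neighbours(img, h, w, r, c, p);
        int b = 0;
        for (int k = 0; k < 8; ++k) b += p[k];
        if (b < 2 || b > 6) continue;       // became an end point: keep
        if (transitions(p) != 1) continue;  // no longer simple: keep
        img[idx] = 0;
        changed = true;
      }
    }
  }

  // redundancy pruning: a non-endpoint pixel whose foreground neighbours
  // all sit in a single mutually 8-connected group carries no path
  // information (staircase corners, thick diagonal knots, junction cores);
  // deleting it preserves connectivity because every route through the
  // pixel can be rerouted within its own neighbourhood. Such pixels distort
  // branch-point detection and pixel-count length estimates. Sequential
  // deletion with recomputation keeps each individual step safe.
  bool again = true;
  while (again) {
    again = false;
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        if (!img[(size_t)c * h + r]) continue;
        neighbours(img, h, w, r, c, p);
        int ks[8], b = 0;
        for (int k = 0; k < 8; ++k)
          if (p[k]) ks[b++] = k;
        if (b < 2) continue;  // end points and isolated pixels stay
        // union-find over the occupied neighbour positions, joined when the
        // corresponding pixels are themselves 8-adjacent
        int parent[8];
        for (int i = 0; i < b; ++i) parent[i] = i;
        for (int i = 0; i < b; ++i) {
          for (int j = i + 1; j < b; ++j) {
            int ddr = DR[ks[i]] - DR[ks[j]], ddc = DC[ks[i]] - DC[ks[j]];
            if (ddr >= -1 && ddr <= 1 && ddc >= -1 && ddc <= 1) {
              int ri = i; while (parent[ri] != ri) ri = parent[ri];
              int rj = j; while (parent[rj] != rj) rj = parent[rj];
              if (ri != rj) parent[rj] = ri;
            }
          }
        }
        int ncomp = 0;
        for (int i = 0; i < b; ++i) if (parent[i] == i) ++ncomp;
        if (ncomp != 1) continue;
        img[(size_t)c * h + r] = 0;
        again = true;
      }
    }
  }

  LogicalMatrix out(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      out(r, c) = img[(size_t)c * h + r] != 0;
  return out;
}
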