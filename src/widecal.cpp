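#include <Rcpp.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

// Return freed heap pages to the OS. Long frame-by-frame loops allocate and
// free many MB-sized temporaries; glibc keeps that space in the arena, which
// can double the resident size of a session. No-op off glibc.
// [[Rcpp::export(name = ".memTrim")]]
void memTrim() {
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}

// Union-find with path halving.
static int ufFind(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Two-pass connected-component labeling of a binary mask.
// connectivity: 4 or 8. Labels are 1..n in raster (column-major) order of
// each component's first pixel.
// [[Rcpp::export(name = ".ccLabel")]]
IntegerMatrix ccLabel(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  int next = 0;
  // column-major scan; neighbors already visited: (r-1,c), (r,c-1) and for
  // 8-connectivity (r-1,c-1), (r+1,c-1)
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int cand[4];
      int ncand = 0;
      if (r > 0 && mask(r - 1, c)) cand[ncand++] = lab(r - 1, c);
      if (c > 0 && mask(r, c - 1)) cand[ncand++] = lab(r, c - 1);
      if (connectivity == 8 && c > 0) {
        if (r > 0 && mask(r - 1, c - 1)) cand[ncand++] = lab(r - 1, c - 1);
        if (r + 1 < H && mask(r + 1, c - 1)) cand[ncand++] = lab(r + 1, c - 1);
      }
      for (int k = 0; k < ncand; ++k) {
        int root = ufFind(parent, cand[k]);
        if (best == 0 || root < best) best = root;
      }
      if (best == 0) {
        ++next;
        parent.push_back(next);
        lab(r, c) = next;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < ncand; ++k) {
          int root = ufFind(parent, cand[k]);
          if (root != best) parent[root] = best;
        }
      }
    }
  }
  // relabel to consecutive ids in first-pixel raster order
  std::vector<int> newId(parent.size(), 0);
  int n = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c)) {
        int root = ufFind(parent, lab(r, c));
        if (newId[root] == 0) newId[root] = ++n;
        lab(r, c) = newId[root];
      }
  return lab;
}

// Translate frame content by (dx, dy) pixels (dx = columns/right, dy =
// rows/down) with bilinear interpolation and replicated edges:
// out(r, c) = in(r - dy, c - dx).
// [[Rcpp::export(name = ".bilinearShift")]]
NumericMatrix bilinearShift(const NumericMatrix& x, double dx, double dy) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    double sc = c - dx;
    int c0 = (int)std::floor(sc);
    double wc = sc - c0;
    int c0c = std::min(std::max(c0, 0), W - 1);
    int c1c = std::min(std::max(c0 + 1, 0), W - 1);
    for (int r = 0; r < H; ++r) {
      double sr = r - dy;
      int r0 = (int)std::floor(sr);
      double wr = sr - r0;
      int r0c = std::min(std::max(r0, 0), H - 1);
      int r1c = std::min(std::max(r0 + 1, 0), H - 1);
      out(r, c) = (1 - wr) * ((1 - wc) * x(r0c, c0c) + wc * x(r0c, c1c)) +
                  wr * ((1 - wc) * x(r1c, c0c) + wc * x(r1c, c1c));
    }
  }
  return out;
}
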