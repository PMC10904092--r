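#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// reflect an out-of-range index into [0, n) (symmetric, edge included:
// -1 -> 0, -2 -> 1, n -> n-1)
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Sliding-window median of a 16-bit quantized image with reflected borders.
// Huang-style: per output row, build a two-level histogram (256 coarse x 256
// fine bins) of the first window, then slide across columns removing/adding
// one window-column at a time. Median search walks the coarse histogram and
// then one fine block, O(512) worst case per pixel.
// [[Rcpp::export(name = ".cpp_window_median")]]
IntegerMatrix cpp_window_median(IntegerMatrix img, int window) {
  const int nr = img.nrow(), nc = img.ncol();
  const int half = window / 2;
  if (window % 2 == 0 || window < 3) stop("window must be odd and >= 3");
  if (window > nr || window > nc) stop("window larger than image");
  IntegerMatrix out(nr, nc);
  const int target = (window * window) / 2 + 1;  // rank of the median
  std::vector<int> coarse(256), fine(65536);

  // precomputed reflected row indices for each output row are cheap enough
  std::vector<int> ridx(window), cidx(window);
  for (int i = 0; i < nr; ++i) {
    std::fill(coarse.begin(), coarse.end(), 0);
    std::fill(fine.begin(), fine.end(), 0);
    for (int wr = 0; wr < window; ++wr) ridx[wr] = reflect(i - half + wr, nr);
    // initial window centered on column 0
    for (int wc = 0; wc < window; ++wc) {
      int c = reflect(0 - half + wc, nc);
      for (int wr = 0; wr < window; ++wr) {
        int v = img(ridx[wr], c);
        ++coarse[v >> 8];
        ++fine[v];
      }
    }
    for (int j = 0; j < nc; ++j) {
      if (j > 0) {
        int c_out = reflect(j - 1 - half, nc);
        int c_in = reflect(j + half, nc);
        for (int wr = 0; wr < window; ++wr) {
          int vo = img(ridx[wr], c_out);
          --coarse[vo >> 8];
          --fine[vo];
          int vi = img(ridx[wr], c_in);
          ++coarse[vi >> 8];
          ++fine[vi];
        }
      }
      // median search
      int cnt = 0, cb = 0;
      while (cnt + coarse[cb] < target) cnt += coarse[cb++];
      int v = cb << 8;
      while (cnt + fine[v] < target) cnt += fine[v++];
      out(i, j) = v;
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask (BFS flood fill).
// Returns an integer matrix of labels (0 = background).
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int r = q.front().first, c = q.front().second;
        q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}
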