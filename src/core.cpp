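#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a logical mask.
// Labels are assigned in raster-scan order starting at 1; 0 = background.
// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline int fg(const IntegerMatrix &m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen thinning to a 1-px-wide, 8-connected, topology-preserving
// skeleton. Input/output as logical matrix.
// [[Rcpp::export(name = ".thin_zs")]]
LogicalMatrix thin_zs(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) img(i, j) = mask(i, j) ? 1 : 0;

  std::vector<int> kill;
  kill.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img(i, j)) continue;
          const int p2 = fg(img, i - 1, j),     p3 = fg(img, i - 1, j + 1);
          const int p4 = fg(img, i, j + 1),     p5 = fg(img, i + 1, j + 1);
          const int p6 = fg(img, i + 1, j),     p7 = fg(img, i + 1, j - 1);
          const int p8 = fg(img, i, j - 1),     p9 = fg(img, i - 1, j - 1);
          const int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int k = 0; k < 8; ++k)
            if (seq[k] == 0 && seq[k + 1] == 1) ++a;
          if (a != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        img(kill[k] % nr, kill[k] / nr) = 0;
    }
  }
  // Completion pass: Zhang-Suen leaves corner fillers on staircase
  // diagonals and small junction blocks. Sequentially delete non-tip
  // pixels that are 8-simple (foreground neighbours stay 8-connected
  // without the pixel, and some 4-neighbour is background), which
  // preserves topology and tips and yields a minimal skeleton.
  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!img(i, j)) continue;
        int nb[8], b = 0;
        for (int k = 0; k < 8; ++k) {
          nb[k] = fg(img, i + di8[k], j + dj8[k]);
          b += nb[k];
        }
        if (b < 2) continue;                       // keep tips
        const int bg4 = !fg(img, i - 1, j) || !fg(img, i + 1, j) ||
                        !fg(img, i, j - 1) || !fg(img, i, j + 1);
        if (!bg4) continue;                        // interior pixel
        // count 8-components of the foreground neighbours
        int comp = 0, seen[8] = {0, 0, 0, 0, 0, 0, 0, 0};
        for (int k = 0; k < 8; ++k) {
          if (!nb[k] || seen[k]) continue;
          ++comp;
          int stack[8], top = 0;
          stack[top++] = k;
          seen[k] = 1;
          while (top) {
            const int c = stack[--top];
            for (int m = 0; m < 8; ++m) {
              if (!nb[m] || seen[m]) continue;
              if (std::abs(di8[c] - di8[m]) <= 1 &&
                  std::abs(dj8[c] - dj8[m]) <= 1) {
                seen[m] = 1;
                stack[top++] = m;
              }
            }
          }
        }
        if (comp == 1) {
          img(i, j) = 0;
          changed = true;
        }
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = img(i, j) != 0;
  return out;
}

// Count of 8-neighbours that are foreground, for every foreground pixel
// (0 elsewhere). Used for skeleton tip/junction classification.
// [[Rcpp::export(name = ".neighbor_count8")]]
IntegerMatrix neighbor_count8(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int n = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj) continue;
          const int ni = i + di, nj = j + dj;
          if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
          if (mask(ni, nj)) ++n;
        }
      out(i, j) = n;
    }
  }
  return out;
}
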