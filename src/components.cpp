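#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling (BFS), labels 1..k in first-seen
// (column-major) order; 0 = background.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > queue;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      queue.clear();
      queue.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!queue.empty()) {
        std::pair<int, int> p = queue.back();
        queue.pop_back();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int r = p.first + di, c = p.second + dj;
            if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
            if (mask(r, c) && !lab(r, c)) {
              lab(r, c) = next;
              queue.push_back(std::make_pair(r, c));
            }
          }
      }
    }
  }
  return lab;
}
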