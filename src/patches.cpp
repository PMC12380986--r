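#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of cells equal to `cls` within a categorical
// window, with per-patch cell counts and perimeters. Perimeter counts
// 4-neighbour cell sides exposed to a different class, to invalid (nodata)
// cells, or to the window boundary, so a window is a self-contained landscape.
//
// [[Rcpp::export(name = ".label_patches_cpp")]]
List label_patches_cpp(IntegerMatrix window, int cls, LogicalMatrix valid) {
  const int nr = window.nrow(), nc = window.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> sizes, perims;
  std::vector<int> stack;
  stack.reserve(64);
  int next = 0;

  auto is_cls = [&](int r, int c) {
    return r >= 0 && r < nr && c >= 0 && c < nc &&
           valid(r, c) && window(r, c) == cls;
  };

  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!is_cls(r0, c0) || labels(r0, c0) != 0) continue;
      ++next;
      int n = 0, p = 0;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      labels(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % nr, c = idx / nr;
        ++n;
        // 4-neighbour side exposures
        if (!is_cls(r - 1, c)) ++p;
        if (!is_cls(r + 1, c)) ++p;
        if (!is_cls(r, c - 1)) ++p;
        if (!is_cls(r, c + 1)) ++p;
        // 8-neighbour growth
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = r + dr, cc = c + dc;
            if (is_cls(rr, cc) && labels(rr, cc) == 0) {
              labels(rr, cc) = next;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
      sizes.push_back(n);
      perims.push_back(p);
    }
  }
  return List::create(_["labels"] = labels,
                      _["cells"] = wrap(sizes),
                      _["perimeter"] = wrap(perims));
}
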