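#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labeling of a 0/1 matrix by iterative flood fill.
// Labels are assigned in column-major scan order (R storage order), so the
// labeling is deterministic for a given mask. connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cc_label(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);

  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;

  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          const int r2 = cr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
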