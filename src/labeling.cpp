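#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling of a domain-coded matrix.
// domain: 0 = background; pixels are connected only when they carry the
// same nonzero domain code (used to keep front/back body views separate).
// connectivity: 4 (edge neighbours) or 8 (edge + diagonal neighbours).
// Returns raw labels in discovery order; size ordering is done in R.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix domain, int connectivity) {
  const int nr = domain.nrow(), nc = domain.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (domain(r, c) == 0 || lab(r, c) != 0) continue;
      const int dom = domain(r, c);
      lab(r, c) = ++next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          const int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (domain(r2, c2) != dom || lab(r2, c2) != 0) continue;
          lab(r2, c2) = next;
          stack.push_back(r2 + c2 * nr);
        }
      }
    }
  }
  return lab;
}
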