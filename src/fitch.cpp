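#include <Rcpp.h>
using namespace Rcpp;

// Fitch (unordered, unit-cost) step counts on a rooted binary tree.
//
// tip_masks: nTips x nChar integer matrix of state bitmasks (bit k set means
//   state k is in the cell's state set; missing cells carry the full mask).
// child1, child2: children of each internal node, listed in postorder.
//   Node ids 1..nTips are tips; nTips+v is the v-th internal node of the
//   postorder, so every child id is strictly smaller than its parent's id.
//
// [[Rcpp::export]]
IntegerVector fitch_counts(IntegerMatrix tip_masks, IntegerVector child1,
                           IntegerVector child2) {
  const int nTips = tip_masks.nrow();
  const int nChar = tip_masks.ncol();
  const int nInt = child1.size();
  IntegerVector steps(nChar);
  std::vector<int> mask(nTips + nInt);
  for (int c = 0; c < nChar; ++c) {
    int s = 0;
    for (int i = 0; i < nTips; ++i) mask[i] = tip_masks(i, c);
    for (int v = 0; v < nInt; ++v) {
      const int a = mask[child1[v] - 1];
      const int b = mask[child2[v] - 1];
      const int inter = a & b;
      if (inter) {
        mask[nTips + v] = inter;
      } else {
        mask[nTips + v] = a | b;
        ++s;
      }
    }
    steps[c] = s;
  }
  return steps;
}

// Weighted total tree length; w holds column weights (duplicate-column
// compression), so the result is sum over characters of w_c * steps_c.
// [[Rcpp::export]]
double fitch_total(IntegerMatrix tip_masks, IntegerVector child1,
                   IntegerVector child2, NumericVector w) {
  const int nTips = tip_masks.nrow();
  const int nChar = tip_masks.ncol();
  const int nInt = child1.size();
  double total = 0.0;
  std::vector<int> mask(nTips + nInt);
  for (int c = 0; c < nChar; ++c) {
    int s = 0;
    for (int i = 0; i < nTips; ++i) mask[i] = tip_masks(i, c);
    for (int v = 0; v < nInt; ++v) {
      const int a = mask[child1[v] - 1];
      const int b = mask[child2[v] - 1];
      const int inter = a & b;
      if (inter) {
        mask[nTips + v] = inter;
      } else {
        mask[nTips + v] = a | b;
        ++s;
      }
    }
    total += w[c] * s;
  }
  return total;
}
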