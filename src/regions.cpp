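// Connected-domain labeling and binary disk morphology for the
// shape-feature post-filtering step (HALCON-style select_shape/count_obj
// semantics, re-implemented generically).
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(H, W);
  const int di4[4] = {-1, 1, 0, 0}, dj4[4] = {0, 0, -1, 1};
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1},
            dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* di = (connectivity == 4) ? di4 : di8;
  const int* dj = (connectivity == 4) ? dj4 : dj8;
  const int nn = connectivity;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int v = mask(i, j);
      if (v != 0 && v != 1) stop("mask must be binary (0/1)");
      if (v == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * H);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int t = 0; t < nn; ++t) {
          const int qi = pi + di[t], qj = pj + dj[t];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) == 1 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * H);
          }
        }
      }
    }
  }
  lab.attr("n_regions") = next;
  return lab;
}

// dilation (dilate = true) or erosion (dilate = false) with a disk
// structuring element of the given radius; pixels outside the image are
// treated as background.
// [[Rcpp::export]]
IntegerMatrix binary_morph_cpp(IntegerMatrix mask, int radius, bool dilate) {
  const int H = mask.nrow(), W = mask.ncol();
  if (radius < 0) stop("radius must be >= 0");
  std::vector<int> oi, oj;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { oi.push_back(a); oj.push_back(b); }
  IntegerMatrix out(H, W);
  const int n = oi.size();
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int hit = dilate ? 0 : 1;
      for (int t = 0; t < n; ++t) {
        const int qi = i + oi[t], qj = j + oj[t];
        const int v = (qi < 0 || qi >= H || qj < 0 || qj >= W)
                          ? 0 : mask(qi, qj);
        if (dilate) {
          if (v == 1) { hit = 1; break; }
        } else {
          if (v == 0) { hit = 0; break; }
        }
      }
      out(i, j) = hit;
    }
  }
  return out;
}
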