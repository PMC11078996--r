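#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// 3x3 median filter with edge replication; denoising step of the
// baseline segmenter (edge-preserving, unlike linear smoothing).
// [[Rcpp::export]]
NumericMatrix median3x3Cpp(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double w[9];
  for (int j = 0; j < nc; ++j) {
    const int j0 = std::max(j - 1, 0), j1 = std::min(j + 1, nc - 1);
    for (int i = 0; i < nr; ++i) {
      const int i0 = std::max(i - 1, 0), i1 = std::min(i + 1, nr - 1);
      int k = 0;
      // replicate edge pixels so the window always has 9 entries
      const int ii[3] = {i0, i, i1};
      const int jj[3] = {j0, j, j1};
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          w[k++] = img(ii[a], jj[b]);
      std::nth_element(w, w + 4, w + 9);
      out(i, j) = w[4];
    }
  }
  return out;
}
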