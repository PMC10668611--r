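#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// reflect index into [0, n-1]
static inline int reflect(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(const NumericMatrix& img, int window) {
  const int nr = img.nrow(), nc = img.ncol();
  const int h = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)window * window);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      buf.clear();
      for (int dc = -h; dc <= h; ++dc) {
        const int cc = reflect(c + dc, nc);
        for (int dr = -h; dr <= h; ++dr) {
          buf.push_back(img(reflect(r + dr, nr), cc));
        }
      }
      const size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
        med = 0.5 * (med + buf[m - 1]);
      }
      out(r, c) = med;
    }
  }
  return out;
}

// Remove 8-connected components smaller than min_size from a logical mask.
// [[Rcpp::export(name = ".filter_components_cpp")]]
LogicalMatrix filter_components_cpp(const LogicalMatrix& mask, int min_size) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<int> label((size_t)nr * nc, 0);
  int next_label = 0;
  std::vector<int> comp_size;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const size_t idx = (size_t)c * nr + r;
      if (!mask(r, c) || label[idx]) continue;
      ++next_label;
      int sz = 0;
      stack.clear();
      stack.push_back((int)idx);
      label[idx] = next_label;
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        ++sz;
        const int cr = cur % nr, ccol = cur / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            const int r2 = cr + dr, c2 = ccol + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            const size_t i2 = (size_t)c2 * nr + r2;
            if (mask(r2, c2) && !label[i2]) {
              label[i2] = next_label;
              stack.push_back((int)i2);
            }
          }
        }
      }
      comp_size.push_back(sz);
    }
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      const int lb = label[(size_t)c * nr + r];
      out(r, c) = lb > 0 && comp_size[lb - 1] >= min_size;
    }
  return out;
}
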