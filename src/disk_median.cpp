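#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflect an out-of-range index back into [0, n) (half-sample symmetric,
// i.e. -1 -> 0, n -> n-1), matching reflect padding.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static inline double median_of(std::vector<double> &buf) {
  size_t m = buf.size();
  size_t h = m / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double hi = buf[h];
  if (m % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + h);
  return 0.5 * (lo + hi);
}

// Median filter with a disk-shaped footprint of the given pixel radius and
// reflect border padding. With stride > 1 the median is evaluated on a
// strided grid (always including the last row/column) and bilinearly
// interpolated back to full resolution; intended only for slowly varying
// surfaces such as illumination profiles.
// [[Rcpp::export(name = ".disk_median_cpp")]]
NumericMatrix disk_median_cpp(NumericMatrix img, int radius, int stride = 1) {
  const int nr = img.nrow(), nc = img.ncol();
  if (radius < 1) stop("radius must be >= 1");
  if (stride < 1) stop("stride must be >= 1");

  std::vector<int> dr, dc;
  const int r2 = radius * radius;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= r2) { dr.push_back(a); dc.push_back(b); }
  const size_t m = dr.size();

  std::vector<int> gr, gc;
  for (int i = 0; i < nr; i += stride) gr.push_back(i);
  if (gr.back() != nr - 1) gr.push_back(nr - 1);
  for (int j = 0; j < nc; j += stride) gc.push_back(j);
  if (gc.back() != nc - 1) gc.push_back(nc - 1);
  const int ngr = (int)gr.size(), ngc = (int)gc.size();

  NumericMatrix grid(ngr, ngc);
  std::vector<double> buf(m);
  for (int gi = 0; gi < ngr; ++gi) {
    const int i = gr[gi];
    for (int gj = 0; gj < ngc; ++gj) {
      const int j = gc[gj];
      for (size_t k = 0; k < m; ++k) {
        const int ri = reflect_idx(i + dr[k], nr);
        const int cj = reflect_idx(j + dc[k], nc);
        buf[k] = img(ri, cj);
      }
      grid(gi, gj) = median_of(buf);
    }
  }
  if (stride == 1) return grid;

  // bilinear interpolation from the strided grid back to full resolution
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    int gi = std::min(i / stride, ngr - 2);
    while (gr[gi + 1] < i) ++gi;  // handles the appended last row
    const double fi = (gr[gi + 1] == gr[gi])
      ? 0.0 : (double)(i - gr[gi]) / (gr[gi + 1] - gr[gi]);
    for (int j = 0; j < nc; ++j) {
      int gj = std::min(j / stride, ngc - 2);
      while (gc[gj + 1] < j) ++gj;
      const double fj = (gc[gj + 1] == gc[gj])
        ? 0.0 : (double)(j - gc[gj]) / (gc[gj + 1] - gc[gj]);
      out(i, j) =
        (1 - fi) * (1 - fj) * grid(gi, gj) +
        (1 - fi) * fj       * grid(gi, gj + 1) +
        fi       * (1 - fj) * grid(gi + 1, gj) +
        fi       * fj       * grid(gi + 1, gj + 1);
    }
  }
  return out;
}
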