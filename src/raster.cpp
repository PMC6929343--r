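#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Even-odd scanline fill of a closed polygon on a size x size canvas with
// ss x ss supersampling followed by box down-sampling.  Row-major output
// (row = y, column = x), foreground/background intensities in [0, 255].
// [[Rcpp::export(name = ".fill_polygon_raster")]]
IntegerVector fill_polygon_raster(NumericVector px, NumericVector py,
                                  int size, int ss, int fg, int bg) {
  const int n = px.size();
  const int sub = size * ss;
  std::vector<int> cov((size_t)size * size, 0);
  std::vector<double> xs;
  xs.reserve(16);
  for (int r = 0; r < sub; ++r) {
    const double y = (r + 0.5) / ss;
    xs.clear();
    for (int e = 0; e < n; ++e) {
      const int e2 = (e + 1 == n) ? 0 : e + 1;
      const double y1 = py[e], y2 = py[e2];
      if ((y1 > y) != (y2 > y)) {
        xs.push_back(px[e] + (y - y1) * (px[e2] - px[e]) / (y2 - y1));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    const int row = r / ss;
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c0 = (int)std::ceil(xs[k] * ss - 0.5);
      int c1 = (int)std::floor(xs[k + 1] * ss - 0.5);
      if (c0 < 0) c0 = 0;
      if (c1 > sub - 1) c1 = sub - 1;
      for (int c = c0; c <= c1; ++c) cov[(size_t)row * size + c / ss] += 1;
    }
  }
  IntegerVector out((R_xlen_t)size * size);
  const double denom = (double)ss * ss;
  for (size_t i = 0; i < cov.size(); ++i) {
    out[i] = (int)std::lround(bg + (fg - bg) * (cov[i] / denom));
  }
  return out;
}
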