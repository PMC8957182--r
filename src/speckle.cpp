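#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Render a speckle frame from point scatterers convolved with an isotropic
// Gaussian point-spread function. Coordinates are 0-based image coordinates:
// x = column, y = row. Truncation at 3 sigma keeps the splat local.
// [[Rcpp::export]]
NumericMatrix cpp_render_speckle(NumericVector x, NumericVector y,
                                 NumericVector amp, int height, int width,
                                 double sigma) {
  NumericMatrix img(height, width);
  const int n = x.size();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const int rad = (int) std::ceil(3.0 * sigma);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], ai = amp[i];
    const int c0 = std::max(0, (int) std::floor(xi) - rad);
    const int c1 = std::min(width - 1, (int) std::ceil(xi) + rad);
    const int r0 = std::max(0, (int) std::floor(yi) - rad);
    const int r1 = std::min(height - 1, (int) std::ceil(yi) + rad);
    for (int c = c0; c <= c1; ++c) {
      const double dx = c - xi;
      for (int r = r0; r <= r1; ++r) {
        const double dy = r - yi;
        img(r, c) += ai * std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
  }
  return img;
}
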