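#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Normalised cross-correlation of a (2*bh+1)^2 block of `a` centred at
// (ar, ac) against the same-sized block of `b` centred at (br, bc).
// Assumes both blocks lie inside their images. Returns 0 on zero variance.
static double ncc_block(const NumericMatrix &a, const NumericMatrix &b,
                        int ar, int ac, int br, int bc, int bh) {
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  const int n = (2 * bh + 1) * (2 * bh + 1);
  const int ha = a.nrow(), hb = b.nrow();
  const double *pa = a.begin(), *pb = b.begin();
  for (int dc = -bh; dc <= bh; ++dc) {
    const double *ca = pa + (ac + dc) * ha + ar - bh;
    const double *cb = pb + (bc + dc) * hb + br - bh;
    for (int k = 0; k < 2 * bh + 1; ++k) {
      const double va = ca[k], vb = cb[k];
      sa += va; sb += vb;
      saa += va * va; sbb += vb * vb; sab += va * vb;
    }
  }
  const double cov = sab - sa * sb / n;
  const double vara = saa - sa * sa / n;
  const double varb = sbb - sb * sb / n;
  if (vara <= 0 || varb <= 0) return 0.0;
  return cov / std::sqrt(vara * varb);
}

// Sub-pixel peak offset from three correlation samples. The correlation
// peak of speckle under a Gaussian PSF is close to Gaussian, so the fit is
// done on log-correlations when all three samples are positive (a Gaussian
// peak is exactly parabolic in the log domain, which suppresses
// pixel-locking bias); otherwise a plain parabola is used.
static double parabolic_offset(double cm, double c0, double cp) {
  if (cm > 0 && c0 > 0 && cp > 0 && c0 >= cm && c0 >= cp) {
    cm = std::log(cm); c0 = std::log(c0); cp = std::log(cp);
  }
  const double denom = cm - 2.0 * c0 + cp;
  if (std::fabs(denom) < 1e-12) return 0.0;
  double d = 0.5 * (cm - cp) / denom;
  if (d > 0.5) d = 0.5;
  if (d < -0.5) d = -0.5;
  return d;
}

// Block matching between consecutive frames for a set of tracked points.
// px, py: 0-based point coordinates (x = column, y = row) in `prev`.
// For each point the integer displacement maximising NCC within the search
// window is found by exhaustive evaluation, then refined to sub-pixel by a
// separable parabolic fit of the correlation peak.
// Returns an n x 6 matrix: dx, dy (sub-pixel), peak correlation,
// in_bounds flag (0 = block left the image, match not attempted),
// integer dx, integer dy.
// [[Rcpp::export]]
NumericMatrix cpp_block_match(NumericMatrix prev, NumericMatrix nxt,
                              NumericVector px, NumericVector py,
                              int block_half, int search) {
  const int n = px.size();
  const int h = prev.nrow(), w = prev.ncol();
  NumericMatrix out(n, 6);
  const int span = 2 * search + 1;
  std::vector<double> corr(span * span);

  for (int i = 0; i < n; ++i) {
    const int ac = (int) std::lround(px[i]);
    const int ar = (int) std::lround(py[i]);
    // reference block must lie fully inside the previous frame
    if (ac - block_half < 0 || ac + block_half >= w ||
        ar - block_half < 0 || ar + block_half >= h) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
      out(i, 3) = 0; out(i, 4) = NA_REAL; out(i, 5) = NA_REAL;
      continue;
    }
    double best = -2.0;
    int bdx = 0, bdy = 0;
    bool any = false;
    for (int dy = -search; dy <= search; ++dy) {
      for (int dx = -search; dx <= search; ++dx) {
        const int bc = ac + dx, br = ar + dy;
        double c;
        if (bc - block_half < 0 || bc + block_half >= w ||
            br - block_half < 0 || br + block_half >= h) {
          c = -2.0; // candidate block outside the next frame
        } else {
          c = ncc_block(prev, nxt, ar, ac, br, bc, block_half);
          any = true;
        }
        corr[(dy + search) * span + (dx + search)] = c;
        if (c > best) { best = c; bdx = dx; bdy = dy; }
      }
    }
    if (!any) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
      out(i, 3) = 0; out(i, 4) = NA_REAL; out(i, 5) = NA_REAL;
      continue;
    }
    // separable parabolic refinement, skipped on the window border or next
    // to an unevaluated candidate
    double sx = 0, sy = 0;
    if (bdx > -search && bdx < search) {
      const double cm = corr[(bdy + search) * span + (bdx - 1 + search)];
      const double cp = corr[(bdy + search) * span + (bdx + 1 + search)];
      const double c0 = best;
      if (cm > -2.0 && cp > -2.0) sx = parabolic_offset(cm, c0, cp);
    }
    if (bdy > -search && bdy < search) {
      const double cm = corr[(bdy - 1 + search) * span + (bdx + search)];
      const double cp = corr[(bdy + 1 + search) * span + (bdx + search)];
      const double c0 = best;
      if (cm > -2.0 && cp > -2.0) sy = parabolic_offset(cm, c0, cp);
    }
    out(i, 0) = bdx + sx;
    out(i, 1) = bdy + sy;
    out(i, 2) = best;
    out(i, 3) = 1;
    out(i, 4) = bdx;
    out(i, 5) = bdy;
  }
  return out;
}
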