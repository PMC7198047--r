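#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dense disparity by normalized cross-correlation along rectified rows.
// left/right: grayscale matrices (rows y, cols x). For each left pixel the
// correlation is evaluated for integer disparities in [dmin, dmax]
// (right column = left column - d), the peak is refined by a 3-point
// parabola fit, and pixels whose peak NCC falls below `thresh` (or whose
// window has no texture) are marked invalid (NaN).
// [[Rcpp::export]]
NumericMatrix ncc_disparity_cpp(NumericMatrix left, NumericMatrix right,
                                int win, int dmin, int dmax, double thresh) {
  const int H = left.nrow(), W = left.ncol();
  const int hw = win / 2;
  NumericMatrix disp(H, W);
  std::fill(disp.begin(), disp.end(), NA_REAL);
  const int nd = dmax - dmin + 1;
  std::vector<double> score(nd);
  for (int y = hw; y < H - hw; ++y) {
    for (int x = hw; x < W - hw; ++x) {
      // left window stats
      double sl = 0, sll = 0;
      for (int j = -hw; j <= hw; ++j)
        for (int i = -hw; i <= hw; ++i) {
          double v = left(y + i, x + j);
          sl += v; sll += v * v;
        }
      const int npix = win * win;
      double ml = sl / npix;
      double varl = sll - npix * ml * ml;
      if (varl < 1e-10) continue; // textureless
      int bestd = -1; double best = -2.0;
      for (int d = dmin; d <= dmax; ++d) {
        int xr = x - d;
        if (xr - hw < 0 || xr + hw >= W) { score[d - dmin] = -2.0; continue; }
        double sr = 0, srr = 0, slr = 0;
        for (int j = -hw; j <= hw; ++j)
          for (int i = -hw; i <= hw; ++i) {
            double a = left(y + i, x + j);
            double b = right(y + i, xr + j);
            sr += b; srr += b * b; slr += a * b;
          }
        double mr = sr / npix;
        double varr = srr - npix * mr * mr;
        double ncc;
        if (varr < 1e-10) ncc = -2.0;
        else ncc = (slr - npix * ml * mr) / std::sqrt(varl * varr);
        score[d - dmin] = ncc;
        if (ncc > best) { best = ncc; bestd = d; }
      }
      if (bestd < 0 || best < thresh) continue;
      double d = bestd;
      int k = bestd - dmin;
      if (k > 0 && k < nd - 1 && score[k - 1] > -1.5 && score[k + 1] > -1.5) {
        double denom = score[k - 1] - 2.0 * score[k] + score[k + 1];
        if (std::fabs(denom) > 1e-12) {
          double off = 0.5 * (score[k - 1] - score[k + 1]) / denom;
          if (off > -1.0 && off < 1.0) d += off;
        }
      }
      disp(y, x) = d;
    }
    if ((y & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return disp;
}
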