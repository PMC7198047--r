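#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Morphological implementation of the two-phase Chan-Vese active contour
// (active contours without edges): the region competition term flips
// boundary pixels by the sign of lambda1 (I-c1)^2 - lambda2 (I-c2)^2 and
// the curvature term is realized by alternating sup-inf / inf-sup
// morphological smoothing with four line elements of length 3.
// u: binary {0,1} matrix, 1 inside. Returns evolved u and iterations run.

namespace {

// inf over the 4 line structuring elements of sup over the element (IS),
// or the dual (SI)
void morphOp(const IntegerMatrix &u, IntegerMatrix &out, bool supInf) {
  const int H = u.nrow(), W = u.ncol();
  static const int off[4][2][2] = {
    {{-1, 0}, {1, 0}}, {{0, -1}, {0, 1}}, {{-1, -1}, {1, 1}}, {{-1, 1}, {1, -1}}
  };
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int agg = supInf ? 0 : 1; // sup of infs : start 0; inf of sups : start 1
      for (int e = 0; e < 4; ++e) {
        int v = u(i, j);
        for (int k = 0; k < 2 && ((supInf && v == 1) || (!supInf && v == 0)); ++k) {
          int ii = i + off[e][k][0], jj = j + off[e][k][1];
          int val = (ii < 0 || ii >= H || jj < 0 || jj >= W) ? u(i, j)
                                                             : u(ii, jj);
          if (supInf) { if (val < v) v = val; }
          else        { if (val > v) v = val; }
        }
        if (supInf) { if (v > agg) agg = v; }
        else        { if (v < agg) agg = v; }
      }
      out(i, j) = agg;
    }
}

} // namespace

// img: H x W x K array flattened column-major (K = channels); the region
// force is the vector-valued extension (sum of squared channel
// deviations from the region mean colour).
// [[Rcpp::export]]
List chanvese_cpp(NumericVector img, int H, int W, int K,
                  IntegerMatrix init, double lambda1, double lambda2,
                  int smoothing, int maxIter, double tol) {
  IntegerMatrix u = clone(init);
  IntegerMatrix tmp(H, W), tmp2(H, W);
  const double *I = img.begin();
  const long HW = (long)H * W;
  std::vector<double> c1(K), c2(K);
  int iter = 0;
  int stable = 0;
  for (iter = 1; iter <= maxIter; ++iter) {
    // region mean colours
    long a1 = 0, a2 = 0;
    std::fill(c1.begin(), c1.end(), 0.0);
    std::fill(c2.begin(), c2.end(), 0.0);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        long p = i + (long)j * H;
        if (u(i, j)) { ++a1; for (int k = 0; k < K; ++k) c1[k] += I[p + k * HW]; }
        else         { ++a2; for (int k = 0; k < K; ++k) c2[k] += I[p + k * HW]; }
      }
    if (a1 == 0 || a2 == 0) break;
    for (int k = 0; k < K; ++k) { c1[k] /= a1; c2[k] /= a2; }
    // data term on the (morphological) boundary
    long changed = 0;
    IntegerMatrix un = clone(u);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        int ip = std::min(i + 1, H - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, W - 1), jm = std::max(j - 1, 0);
        double gx = 0.5 * (u(i, jp) - u(i, jm));
        double gy = 0.5 * (u(ip, j) - u(im, j));
        if (gx == 0 && gy == 0) continue;
        long p = i + (long)j * H;
        double d1 = 0, d2 = 0;
        for (int k = 0; k < K; ++k) {
          double v = I[p + k * HW];
          d1 += (v - c1[k]) * (v - c1[k]);
          d2 += (v - c2[k]) * (v - c2[k]);
        }
        double aux = lambda1 * d1 - lambda2 * d2;
        int v = aux < 0 ? 1 : (aux > 0 ? 0 : u(i, j));
        if (v != u(i, j)) { un(i, j) = v; ++changed; }
      }
    u = un;
    // curvature smoothing, alternating the operator order
    for (int s = 0; s < smoothing; ++s) {
      if ((iter + s) % 2 == 0) {
        morphOp(u, tmp, true); morphOp(tmp, tmp2, false);
      } else {
        morphOp(u, tmp, false); morphOp(tmp, tmp2, true);
      }
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          if (tmp2(i, j) != u(i, j)) ++changed;
          u(i, j) = tmp2(i, j);
        }
    }
    if ((double)changed / (H * W) < tol) { if (++stable >= 3) break; }
    else stable = 0;
    if ((iter & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["u"] = u, _["iterations"] = std::min(iter, maxIter));
}
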