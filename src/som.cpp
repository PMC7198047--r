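#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Online Kohonen training of an r x c grid of 3-D nodes on a point cloud.
// pts: N x 3, init: (nr*nc) x 3 (node (i,j) at row i + j*nr, 0-based,
// matching R column-major order). order: step-wise sample indices
// (1-based, length epochs*N) drawn in R so determinism follows R's RNG.
// Learning rate and neighbourhood sigma decay exponentially from *0 to *1
// over all steps. Neighbourhood is Gaussian in grid coordinates, truncated
// at 3 sigma. Returns trained nodes and (optionally) the mean point-to-node
// distance after each epoch.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix pts, NumericMatrix init, int nr, int nc,
                   int epochs, double lr0, double lr1, double sig0,
                   double sig1, IntegerVector order, bool record) {
  const int N = pts.nrow(), M = nr * nc;
  NumericMatrix W = clone(init);
  const double T = (double)epochs * N;
  NumericVector epochErr(record ? epochs : 0);
  double *w = W.begin();
  const double *p = pts.begin();

  long step = 0;
  for (int e = 0; e < epochs; ++e) {
    for (int s = 0; s < N; ++s, ++step) {
      int idx = order[step] - 1;
      double x0 = p[idx], x1 = p[idx + N], x2 = p[idx + 2 * N];
      // best matching unit
      int bmu = 0;
      double best = R_PosInf;
      for (int m = 0; m < M; ++m) {
        double d0 = w[m] - x0, d1 = w[m + M] - x1, d2 = w[m + 2 * M] - x2;
        double d = d0 * d0 + d1 * d1 + d2 * d2;
        if (d < best) { best = d; bmu = m; }
      }
      double frac = step / T;
      double lr = lr0 * std::pow(lr1 / lr0, frac);
      double sig = sig0 * std::pow(sig1 / sig0, frac);
      int bi = bmu % nr, bj = bmu / nr;
      int rad = (int)std::ceil(3.0 * sig);
      int i0 = std::max(0, bi - rad), i1 = std::min(nr - 1, bi + rad);
      int j0 = std::max(0, bj - rad), j1 = std::min(nc - 1, bj + rad);
      double inv2s2 = 1.0 / (2.0 * sig * sig);
      for (int j = j0; j <= j1; ++j) {
        int dj = j - bj;
        for (int i = i0; i <= i1; ++i) {
          int di = i - bi;
          double h = std::exp(-(di * di + dj * dj) * inv2s2) * lr;
          if (h < 1e-6) continue;
          int m = i + j * nr;
          w[m]         += h * (x0 - w[m]);
          w[m + M]     += h * (x1 - w[m + M]);
          w[m + 2 * M] += h * (x2 - w[m + 2 * M]);
        }
      }
    }
    if (record) {
      double tot = 0.0;
      for (int s = 0; s < N; ++s) {
        double x0 = p[s], x1 = p[s + N], x2 = p[s + 2 * N];
        double best = R_PosInf;
        for (int m = 0; m < M; ++m) {
          double d0 = w[m] - x0, d1 = w[m + M] - x1, d2 = w[m + 2 * M] - x2;
          double d = d0 * d0 + d1 * d1 + d2 * d2;
          if (d < best) best = d;
        }
        tot += std::sqrt(best);
      }
      epochErr[e] = tot / N;
    }
  }
  return List::create(_["nodes"] = W, _["epochError"] = epochErr);
}

// Mean distance from each point to its nearest node (used by tests).
// [[Rcpp::export]]
double mean_nn_dist_cpp(NumericMatrix pts, NumericMatrix nodes) {
  const int N = pts.nrow(), M = nodes.nrow();
  const double *p = pts.begin(), *w = nodes.begin();
  double tot = 0.0;
  for (int s = 0; s < N; ++s) {
    double x0 = p[s], x1 = p[s + N], x2 = p[s + 2 * N];
    double best = R_PosInf;
    for (int m = 0; m < M; ++m) {
      double d0 = w[m] - x0, d1 = w[m + M] - x1, d2 = w[m + 2 * M] - x2;
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    tot += std::sqrt(best);
  }
  return tot / N;
}
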