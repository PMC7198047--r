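#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// SLIC superpixels restricted to a mask. Locality-constrained k-means in
// (L, a, b, x, y): each cluster searches a 2S x 2S window; distance
// D = d_lab + (m/S) * d_xy. centers0: k x 2 matrix of (row, col) seeds
// (1-based). Returns label matrix (0 outside mask, 1..k inside).
// [[Rcpp::export]]
IntegerMatrix slic_cpp(NumericMatrix L, NumericMatrix A, NumericMatrix B,
                       LogicalMatrix mask, NumericMatrix centers0,
                       double S, double m, int iters) {
  const int H = L.nrow(), W = L.ncol();
  const int k = centers0.nrow();
  std::vector<double> cl(k), ca(k), cb(k), cr(k), cc(k);
  for (int q = 0; q < k; ++q) {
    int r = (int)centers0(q, 0) - 1, c = (int)centers0(q, 1) - 1;
    cr[q] = r; cc[q] = c; cl[q] = L(r, c); ca[q] = A(r, c); cb[q] = B(r, c);
  }
  IntegerMatrix lab(H, W);
  NumericMatrix dist(H, W);
  const double invS = m / S;
  for (int it = 0; it < iters; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(lab.begin(), lab.end(), 0);
    for (int q = 0; q < k; ++q) {
      int r0 = std::max(0, (int)cr[q] - (int)(2 * S));
      int r1 = std::min(H - 1, (int)cr[q] + (int)(2 * S));
      int c0 = std::max(0, (int)cc[q] - (int)(2 * S));
      int c1 = std::min(W - 1, (int)cc[q] + (int)(2 * S));
      for (int c = c0; c <= c1; ++c)
        for (int r = r0; r <= r1; ++r) {
          if (!mask(r, c)) continue;
          double dl = L(r, c) - cl[q], da = A(r, c) - ca[q],
                 db = B(r, c) - cb[q];
          double dx = (r - cr[q]) * invS, dy = (c - cc[q]) * invS;
          double d = std::sqrt(dl * dl + da * da + db * db) +
                     std::sqrt(dx * dx + dy * dy);
          if (d < dist(r, c)) { dist(r, c) = d; lab(r, c) = q + 1; }
        }
    }
    // any masked pixel missed by all windows -> nearest centre (rare)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        if (!mask(r, c) || lab(r, c) > 0) continue;
        double best = R_PosInf; int bq = 1;
        for (int q = 0; q < k; ++q) {
          double dx = r - cr[q], dy = c - cc[q];
          double d = dx * dx + dy * dy;
          if (d < best) { best = d; bq = q + 1; }
        }
        lab(r, c) = bq;
      }
    // update centres
    std::vector<double> sl(k, 0), sa(k, 0), sb(k, 0), sr(k, 0), sc(k, 0);
    std::vector<int> cnt(k, 0);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        int q = lab(r, c) - 1;
        if (q < 0) continue;
        sl[q] += L(r, c); sa[q] += A(r, c); sb[q] += B(r, c);
        sr[q] += r; sc[q] += c; ++cnt[q];
      }
    for (int q = 0; q < k; ++q)
      if (cnt[q] > 0) {
        cl[q] = sl[q] / cnt[q]; ca[q] = sa[q] / cnt[q];
        cb[q] = sb[q] / cnt[q];
        cr[q] = sr[q] / cnt[q]; cc[q] = sc[q] / cnt[q];
      }
  }
  return lab;
}

// Enforce connectivity: relabel connected components; components that are
// not the largest for their label get merged into an adjacent label.
// [[Rcpp::export]]
IntegerMatrix slic_connectivity_cpp(IntegerMatrix lab) {
  const int H = lab.nrow(), W = lab.ncol();
  IntegerMatrix comp(H, W);
  std::fill(comp.begin(), comp.end(), 0);
  int ncomp = 0;
  std::vector<int> compLab, compSize, compAdj; // adjacent label for merge
  const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (lab(r0, c0) == 0 || comp(r0, c0) != 0) continue;
      ++ncomp;
      int lb = lab(r0, c0), size = 0, adj = 0;
      std::queue<std::pair<int,int> > q;
      q.push(std::make_pair(r0, c0)); comp(r0, c0) = ncomp;
      while (!q.empty()) {
        int r = q.front().first, c = q.front().second; q.pop();
        ++size;
        for (int d = 0; d < 4; ++d) {
          int rr = r + dr[d], cc2 = c + dc[d];
          if (rr < 0 || rr >= H || cc2 < 0 || cc2 >= W) continue;
          int l2 = lab(rr, cc2);
          if (l2 == lb && comp(rr, cc2) == 0) {
            comp(rr, cc2) = ncomp; q.push(std::make_pair(rr, cc2));
          } else if (l2 != 0 && l2 != lb) {
            adj = l2;
          }
        }
      }
      compLab.push_back(lb); compSize.push_back(size); compAdj.push_back(adj);
    }
  // keep largest component per label, merge the rest into neighbours
  std::vector<int> bestComp; // per label (1-based labels)
  int maxLab = 0;
  for (size_t i = 0; i < compLab.size(); ++i)
    maxLab = std::max(maxLab, compLab[i]);
  bestComp.assign(maxLab + 1, -1);
  for (size_t i = 0; i < compLab.size(); ++i) {
    int l = compLab[i];
    if (bestComp[l] < 0 || compSize[i] > compSize[bestComp[l]])
      bestComp[l] = (int)i;
  }
  IntegerMatrix out = clone(lab);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int cp = comp(r, c);
      if (cp == 0) continue;
      int i = cp - 1;
      if (bestComp[compLab[i]] != i && compAdj[i] != 0)
        out(r, c) = compAdj[i];
    }
  return out;
}
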