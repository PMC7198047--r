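#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Incremental Bowyer-Watson 2-D Delaunay triangulation with walking point
// location. Caller is expected to centre/scale coordinates to O(1) and to
// break exact co-circularity (regular grids) with a tiny deterministic
// jitter; done in the R wrapper.

namespace {

struct Tri {
  int v[3];   // vertex indices, CCW
  int n[3];   // neighbour opposite v[k], -1 = hull
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

inline bool incircle(double ax, double ay, double bx, double by,
                     double cx, double cy, double px, double py) {
  double adx = ax - px, ady = ay - py;
  double bdx = bx - px, bdy = by - py;
  double cdx = cx - px, cdy = cy - py;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  double det = adx * (bdy * cd - bd * cdy)
             - ady * (bdx * cd - bd * cdx)
             + ad  * (bdx * cdy - bdy * cdx);
  return det > 0.0;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) { px[i] = x[i]; py[i] = y[i]; }
  double xmin = *std::min_element(px.begin(), px.begin() + n);
  double xmax = *std::max_element(px.begin(), px.begin() + n);
  double ymin = *std::min_element(py.begin(), py.begin() + n);
  double ymax = *std::max_element(py.begin(), py.begin() + n);
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) span = 1.0;
  double R = 50.0 * span;
  // super-triangle (CCW)
  px[n] = cx - 2.0 * R; py[n] = cy - R;
  px[n + 1] = cx + 2.0 * R; py[n + 1] = cy - R;
  px[n + 2] = cx; py[n + 2] = cy + 2.0 * R;

  std::vector<Tri> tris;
  tris.reserve(2 * n + 10);
  Tri t0; t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2;
  t0.n[0] = t0.n[1] = t0.n[2] = -1; t0.alive = true;
  tris.push_back(t0);
  int last = 0;

  std::vector<int> cavity, stack;
  std::vector<char> inCav;
  // cavity boundary edges: (a, b, outsideTri, outsideSlot)
  std::vector<std::array<int,4> > bedges;

  for (int ip = 0; ip < n; ++ip) {
    double qx = px[ip], qy = py[ip];
    // --- locate by walking ---
    int t = last;
    if (!tris[t].alive) {
      for (int k = (int)tris.size() - 1; k >= 0; --k)
        if (tris[k].alive) { t = k; break; }
    }
    int guard = 0, maxguard = 4 * (int)tris.size() + 100;
    bool located = false;
    while (true) {
      if (++guard > maxguard) break;
      const Tri &tr = tris[t];
      int moved = -1;
      for (int k = 0; k < 3 && moved < 0; ++k) {
        int a = tr.v[(k + 1) % 3], b = tr.v[(k + 2) % 3];
        if (orient2d(px[a], py[a], px[b], py[b], qx, qy) < 0.0) {
          if (tr.n[k] < 0) { moved = -2; break; }
          moved = tr.n[k];
        }
      }
      if (moved == -2) break;
      if (moved < 0) { located = true; break; }
      t = moved;
    }
    if (!located) {
      // walk failed (cycling on a near-degenerate configuration or left
      // the hull): linear scan with a tolerant containment test
      double bestScore = -R_PosInf;
      int bestT = -1;
      for (int k2 = 0; k2 < (int)tris.size(); ++k2) {
        if (!tris[k2].alive) continue;
        const Tri &tr = tris[k2];
        double mn = R_PosInf;
        for (int k = 0; k < 3; ++k) {
          int a = tr.v[(k + 1) % 3], b = tr.v[(k + 2) % 3];
          double o = orient2d(px[a], py[a], px[b], py[b], qx, qy);
          if (o < mn) mn = o;
        }
        if (mn > bestScore) { bestScore = mn; bestT = k2; }
      }
      if (bestT < 0) stop("point location failed");
      t = bestT;
    }
    // --- grow cavity ---
    cavity.clear(); stack.clear(); bedges.clear();
    inCav.assign(tris.size(), 0);
    stack.push_back(t); inCav[t] = 1;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      cavity.push_back(c);
      const Tri &tr = tris[c];
      for (int k = 0; k < 3; ++k) {
        int nb = tr.n[k];
        int a = tr.v[(k + 1) % 3], b = tr.v[(k + 2) % 3];
        bool nbIn = false;
        if (nb >= 0 && !inCav[nb] && tris[nb].alive) {
          const Tri &tn = tris[nb];
          if (incircle(px[tn.v[0]], py[tn.v[0]], px[tn.v[1]], py[tn.v[1]],
                       px[tn.v[2]], py[tn.v[2]], qx, qy)) {
            inCav[nb] = 1; stack.push_back(nb); nbIn = true;
          }
        } else if (nb >= 0 && inCav[nb]) {
          nbIn = true;
        }
        if (!nbIn) {
          int slot = -1;
          if (nb >= 0) { // which neighbour slot of nb points back to c
            for (int s = 0; s < 3; ++s) if (tris[nb].n[s] == c) slot = s;
          }
          bedges.push_back({a, b, nb, slot});
        }
      }
    }
    for (size_t k = 0; k < cavity.size(); ++k) tris[cavity[k]].alive = false;
    // --- retriangulate fan: edge (a,b) + point, CCW preserved ---
    int base = (int)tris.size();
    std::vector<std::pair<int,int> > firstVert; // (vertex a, tri index)
    firstVert.reserve(bedges.size());
    for (size_t k = 0; k < bedges.size(); ++k) {
      Tri nt;
      nt.v[0] = bedges[k][0]; nt.v[1] = bedges[k][1]; nt.v[2] = ip;
      nt.n[0] = -2; nt.n[1] = -2; nt.n[2] = bedges[k][2];
      nt.alive = true;
      int id = (int)tris.size();
      if (bedges[k][2] >= 0 && bedges[k][3] >= 0)
        tris[bedges[k][2]].n[bedges[k][3]] = id;
      tris.push_back(nt);
      firstVert.push_back(std::make_pair(bedges[k][0], id));
    }
    // link fan neighbours: tri with edge (a,b): neighbour opposite a shares
    // edge (b, p) -> the fan triangle whose first vertex is b; neighbour
    // opposite b shares edge (p, a) -> fan triangle whose second vertex is a.
    for (int id = base; id < (int)tris.size(); ++id) {
      int a = tris[id].v[0], b = tris[id].v[1];
      for (size_t k = 0; k < firstVert.size(); ++k) {
        if (firstVert[k].first == b) tris[id].n[0] = firstVert[k].second;
        int other = firstVert[k].second;
        if (tris[other].v[1] == a) tris[id].n[1] = other;
      }
    }
    last = base;
    if ((ip & 255) == 0) Rcpp::checkUserInterrupt();
  }

  int cnt = 0;
  for (size_t k = 0; k < tris.size(); ++k)
    if (tris[k].alive && tris[k].v[0] < n && tris[k].v[1] < n &&
        tris[k].v[2] < n) ++cnt;
  IntegerMatrix out(cnt, 3);
  int r = 0;
  for (size_t k = 0; k < tris.size(); ++k) {
    const Tri &tr = tris[k];
    if (tr.alive && tr.v[0] < n && tr.v[1] < n && tr.v[2] < n) {
      out(r, 0) = tr.v[0] + 1; out(r, 1) = tr.v[1] + 1;
      out(r, 2) = tr.v[2] + 1; ++r;
    }
  }
  return out;
}
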