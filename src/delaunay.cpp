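// Incremental Bowyer-Watson Delaunay triangulation of a 2-D point set.
// Used by the unstructured mesh generator; points are expected to be
// pre-jittered by the caller so that exactly cocircular configurations do
// not arise.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Tri {
  int v[3];    // vertex indices (CCW)
  int adj[3];  // neighbour opposite vertex i (-1 = none)
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff p strictly inside circumcircle of CCW triangle (a,b,c)
inline double incircle(double ax, double ay, double bx, double by,
                       double cx, double cy, double px, double py) {
  double adx = ax - px, ady = ay - py;
  double bdx = bx - px, bdy = by - py;
  double cdx = cx - px, cdy = cy - py;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

inline std::uint64_t ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<std::uint64_t>(a) << 32) | static_cast<std::uint32_t>(b);
}

} // namespace

// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> x(n + 3), y(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0); y[i] = pts(i, 1);
    if (!R_finite(x[i]) || !R_finite(y[i])) stop("non-finite point coordinates");
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  double dx = xmax - xmin, dy = ymax - ymin;
  double dmax = std::max(dx, dy) * 20.0 + 1.0;
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  // super-triangle vertices at indices n..n+2
  x[n]     = cx - dmax;   y[n]     = cy - dmax;
  x[n + 1] = cx + dmax;   y[n + 1] = cy - dmax;
  x[n + 2] = cx;          y[n + 2] = cy + dmax;

  std::vector<Tri> tris;
  tris.reserve(2 * n + 16);
  {
    Tri t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2;
    t0.adj[0] = t0.adj[1] = t0.adj[2] = -1;
    t0.alive = true;
    tris.push_back(t0);
  }

  // deterministic insertion order (LCG shuffle) for walk efficiency
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::uint64_t s = 88172645463325252ULL;
  for (int i = n - 1; i > 0; --i) {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    int j = static_cast<int>(s % static_cast<std::uint64_t>(i + 1));
    std::swap(order[i], order[j]);
  }

  std::vector<int> bad, stack;
  std::vector<char> inbad;
  std::unordered_map<std::uint64_t, std::pair<int, int>> edgemap;
  edgemap.reserve(64);
  int last = 0;

  for (int k = 0; k < n; ++k) {
    const int p = order[k];
    const double px = x[p], py = y[p];

    // --- locate: remembering walk from `last`
    int t = last, steps = 0, tmax = static_cast<int>(tris.size()) * 4 + 64;
    while (!tris[t].alive) ++t; // ensure alive start
    for (;;) {
      if (++steps > tmax) { // fallback: linear scan
        t = -1;
        for (int i = static_cast<int>(tris.size()) - 1; i >= 0; --i) {
          if (!tris[i].alive) continue;
          const Tri &tr = tris[i];
          bool in = true;
          for (int e = 0; e < 3 && in; ++e) {
            int a = tr.v[(e + 1) % 3], b = tr.v[(e + 2) % 3];
            if (orient2d(x[a], y[a], x[b], y[b], px, py) < 0) in = false;
          }
          if (in) { t = i; break; }
        }
        if (t < 0) stop("point location failed");
        break;
      }
      const Tri &tr = tris[t];
      int cross = -1;
      for (int e = 0; e < 3; ++e) {
        int a = tr.v[(e + 1) % 3], b = tr.v[(e + 2) % 3];
        if (orient2d(x[a], y[a], x[b], y[b], px, py) < 0) { cross = e; break; }
      }
      if (cross < 0) break;
      int nb = tr.adj[cross];
      if (nb < 0) break; // on hull of current triangulation; treat t as container
      t = nb;
    }

    // --- grow cavity of in-circumcircle triangles
    bad.clear();
    inbad.assign(tris.size(), 0);
    stack.clear();
    stack.push_back(t);
    inbad[t] = 1;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      bad.push_back(c);
      const Tri &tc = tris[c];
      for (int e = 0; e < 3; ++e) {
        int nb = tc.adj[e];
        if (nb < 0 || inbad[nb] || !tris[nb].alive) continue;
        const Tri &tn = tris[nb];
        if (incircle(x[tn.v[0]], y[tn.v[0]], x[tn.v[1]], y[tn.v[1]],
                     x[tn.v[2]], y[tn.v[2]], px, py) > 0) {
          inbad[nb] = 1;
          stack.push_back(nb);
        }
      }
    }

    // --- collect cavity boundary edges (edge, outside neighbour)
    edgemap.clear();
    std::vector<std::array<int, 3>> bedges; // a, b, outside-neighbour
    for (int c : bad) {
      const Tri &tc = tris[c];
      for (int e = 0; e < 3; ++e) {
        int nb = tc.adj[e];
        if (nb >= 0 && inbad[nb]) continue;
        // edge opposite vertex e, CCW order (v[e+1], v[e+2])
        bedges.push_back({tc.v[(e + 1) % 3], tc.v[(e + 2) % 3], nb});
      }
    }
    for (int c : bad) tris[c].alive = false;

    // --- fan of new triangles
    int first_new = static_cast<int>(tris.size());
    for (auto &be : bedges) {
      Tri tn;
      tn.v[0] = p; tn.v[1] = be[0]; tn.v[2] = be[1];
      tn.adj[0] = be[2]; // opposite p: the outside neighbour
      tn.adj[1] = tn.adj[2] = -1;
      tn.alive = true;
      int id = static_cast<int>(tris.size());
      // fix outside neighbour's back-pointer
      if (be[2] >= 0) {
        Tri &to = tris[be[2]];
        for (int e = 0; e < 3; ++e) {
          int a = to.v[(e + 1) % 3], b = to.v[(e + 2) % 3];
          if ((a == be[0] && b == be[1]) || (a == be[1] && b == be[0])) {
            to.adj[e] = id;
            break;
          }
        }
      }
      tris.push_back(tn);
    }
    // link new triangles to each other via shared edges (p, vertex)
    std::unordered_map<int, std::pair<int, int>> fanmap; // vertex -> (tri, slot)
    fanmap.reserve(bedges.size() * 2);
    for (int i = 0; i < static_cast<int>(bedges.size()); ++i) {
      int id = first_new + i;
      // the two edges through p: (p, v[1]) is opposite slot 2,
      // (p, v[2]) is opposite slot 1
      for (int pair = 0; pair < 2; ++pair) {
        int vother = tris[id].v[pair == 0 ? 1 : 2];
        int adjslot = pair == 0 ? 2 : 1;
        auto it = fanmap.find(vother);
        if (it == fanmap.end()) {
          fanmap[vother] = {id, adjslot};
        } else {
          tris[id].adj[adjslot] = it->second.first;
          tris[it->second.first].adj[it->second.second] = id;
        }
      }
    }
    last = first_new;
  }

  // --- export triangles not touching the super-triangle
  int m = 0;
  for (const Tri &t : tris) {
    if (t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n) ++m;
  }
  IntegerMatrix out(m, 3);
  int r = 0;
  for (const Tri &t : tris) {
    if (!(t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n)) continue;
    out(r, 0) = t.v[0] + 1;
    out(r, 1) = t.v[1] + 1;
    out(r, 2) = t.v[2] + 1;
    ++r;
  }
  return out;
}
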