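#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---- Bowyer-Watson Delaunay triangulation ----------------------------------
// Plain incremental algorithm with a super-triangle. Adequate for the point
// counts used here (a few thousand); no exact predicates, but the meshes are
// built from well-separated lattice + boundary points.

struct Tri {
  int a, b, c;
  double cx, cy, r2;   // circumcircle
  bool alive;
};

static inline void circumcircle(double ax, double ay, double bx, double by,
                                double cx, double cy, double &ox, double &oy,
                                double &r2) {
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-14) { ox = oy = 0.0; r2 = 1e300; return; }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  ox = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  oy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - ox, dy = ay - oy;
  r2 = dx * dx + dy * dy;
}

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(n + 3), py(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1);
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin), midx = 0.5 * (xmin + xmax),
         midy = 0.5 * (ymin + ymax);
  if (dmax <= 0) dmax = 1.0;
  // super-triangle vertices appended at indices n, n+1, n+2
  px[n] = midx - 20 * dmax; py[n] = midy - dmax;
  px[n + 1] = midx + 20 * dmax; py[n + 1] = midy - dmax;
  px[n + 2] = midx; py[n + 2] = midy + 20 * dmax;

  std::vector<Tri> tris;
  {
    Tri t; t.a = n; t.b = n + 1; t.c = n + 2; t.alive = true;
    circumcircle(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c],
                 t.cx, t.cy, t.r2);
    tris.push_back(t);
  }
  std::vector<std::pair<int,int> > edges;
  for (int ip = 0; ip < n; ++ip) {
    double x = px[ip], y = py[ip];
    edges.clear();
    for (size_t it = 0; it < tris.size(); ++it) {
      Tri &t = tris[it];
      if (!t.alive) continue;
      double dx = x - t.cx, dy = y - t.cy;
      if (dx * dx + dy * dy <= t.r2 * (1.0 + 1e-12)) {
        t.alive = false;
        edges.push_back(std::make_pair(t.a, t.b));
        edges.push_back(std::make_pair(t.b, t.c));
        edges.push_back(std::make_pair(t.c, t.a));
      }
    }
    // boundary of the cavity: edges appearing exactly once (ignoring order)
    std::vector<bool> dup(edges.size(), false);
    for (size_t i = 0; i < edges.size(); ++i)
      for (size_t j = i + 1; j < edges.size(); ++j)
        if ((edges[i].first == edges[j].second &&
             edges[i].second == edges[j].first) ||
            (edges[i].first == edges[j].first &&
             edges[i].second == edges[j].second)) {
          dup[i] = dup[j] = true;
        }
    for (size_t i = 0; i < edges.size(); ++i) {
      if (dup[i]) continue;
      Tri t; t.a = edges[i].first; t.b = edges[i].second; t.c = ip;
      t.alive = true;
      circumcircle(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c],
                   t.cx, t.cy, t.r2);
      tris.push_back(t);
    }
    // periodically compact the triangle list
    if (tris.size() > 4000u + 8u * (size_t)ip) {
      std::vector<Tri> keep;
      keep.reserve(tris.size());
      for (size_t it = 0; it < tris.size(); ++it)
        if (tris[it].alive) keep.push_back(tris[it]);
      tris.swap(keep);
    }
  }
  std::vector<int> out;
  for (size_t it = 0; it < tris.size(); ++it) {
    Tri &t = tris[it];
    if (!t.alive || t.a >= n || t.b >= n || t.c >= n) continue;
    out.push_back(t.a); out.push_back(t.b); out.push_back(t.c);
  }
  int m = (int)out.size() / 3;
  IntegerMatrix res(m, 3);
  for (int i = 0; i < m; ++i) {
    // orient counter-clockwise
    int a = out[3 * i], b = out[3 * i + 1], c = out[3 * i + 2];
    double cross = (px[b] - px[a]) * (py[c] - py[a]) -
                   (py[b] - py[a]) * (px[c] - px[a]);
    if (cross < 0) std::swap(b, c);
    res(i, 0) = a + 1; res(i, 1) = b + 1; res(i, 2) = c + 1;
  }
  return res;
}

// ---- Sutherland-Hodgman clipping of convex polygons ------------------------

static double clip_area(const std::vector<double> &sx,
                        const std::vector<double> &sy,
                        const double *cx, const double *cy, int nc) {
  std::vector<double> ox = sx, oy = sy, nx, ny;
  for (int e = 0; e < nc; ++e) {
    double x1 = cx[e], y1 = cy[e], x2 = cx[(e + 1) % nc], y2 = cy[(e + 1) % nc];
    nx.clear(); ny.clear();
    int np = (int)ox.size();
    if (np == 0) return 0.0;
    for (int i = 0; i < np; ++i) {
      double ax = ox[i], ay = oy[i];
      double bx = ox[(i + 1) % np], by = oy[(i + 1) % np];
      double da = (x2 - x1) * (ay - y1) - (y2 - y1) * (ax - x1);
      double db = (x2 - x1) * (by - y1) - (y2 - y1) * (bx - x1);
      if (da >= 0) { nx.push_back(ax); ny.push_back(ay); }
      if ((da >= 0) != (db >= 0)) {
        double t = da / (da - db);
        nx.push_back(ax + t * (bx - ax));
        ny.push_back(ay + t * (by - ay));
      }
    }
    ox = nx; oy = ny;
  }
  int np = (int)ox.size();
  if (np < 3) return 0.0;
  double A = 0.0;
  for (int i = 0; i < np; ++i) {
    int j = (i + 1) % np;
    A += ox[i] * oy[j] - ox[j] * oy[i];
  }
  return 0.5 * std::fabs(A);
}

// Overlap areas between triangles of mesh A (vertices va, triangles ta,
// counter-clockwise, 1-based) and mesh B. Returns a triplet list
// (i, j, overlap area) using a uniform-grid bbox filter on B.
// [[Rcpp::export]]
List cpp_tri_overlap(NumericMatrix va, IntegerMatrix ta, NumericMatrix vb,
                     IntegerMatrix tb) {
  int na = ta.nrow(), nb = tb.nrow();
  // bounding boxes of B triangles and global box
  std::vector<double> bxmin(nb), bxmax(nb), bymin(nb), bymax(nb);
  double gxmin = R_PosInf, gxmax = R_NegInf, gymin = R_PosInf, gymax = R_NegInf;
  for (int j = 0; j < nb; ++j) {
    double x0 = R_PosInf, x1 = R_NegInf, y0 = R_PosInf, y1 = R_NegInf;
    for (int k = 0; k < 3; ++k) {
      double x = vb(tb(j, k) - 1, 0), y = vb(tb(j, k) - 1, 1);
      x0 = std::min(x0, x); x1 = std::max(x1, x);
      y0 = std::min(y0, y); y1 = std::max(y1, y);
    }
    bxmin[j] = x0; bxmax[j] = x1; bymin[j] = y0; bymax[j] = y1;
    gxmin = std::min(gxmin, x0); gxmax = std::max(gxmax, x1);
    gymin = std::min(gymin, y0); gymax = std::max(gymax, y1);
  }
  int ng = std::max(1, (int)std::floor(std::sqrt((double)nb / 2.0)));
  double hx = (gxmax - gxmin) / ng + 1e-12, hy = (gymax - gymin) / ng + 1e-12;
  std::vector<std::vector<int> > cells(ng * ng);
  for (int j = 0; j < nb; ++j) {
    int i0 = std::max(0, std::min(ng - 1, (int)((bxmin[j] - gxmin) / hx)));
    int i1 = std::max(0, std::min(ng - 1, (int)((bxmax[j] - gxmin) / hx)));
    int j0 = std::max(0, std::min(ng - 1, (int)((bymin[j] - gymin) / hy)));
    int j1 = std::max(0, std::min(ng - 1, (int)((bymax[j] - gymin) / hy)));
    for (int ii = i0; ii <= i1; ++ii)
      for (int jj = j0; jj <= j1; ++jj) cells[ii * ng + jj].push_back(j);
  }
  std::vector<int> ri, rj; std::vector<double> rv;
  std::vector<int> seen(nb, -1);
  std::vector<double> sx(3), sy(3);
  double ccx[3], ccy[3];
  for (int i = 0; i < na; ++i) {
    double x0 = R_PosInf, x1 = R_NegInf, y0 = R_PosInf, y1 = R_NegInf;
    for (int k = 0; k < 3; ++k) {
      sx[k] = va(ta(i, k) - 1, 0); sy[k] = va(ta(i, k) - 1, 1);
      x0 = std::min(x0, sx[k]); x1 = std::max(x1, sx[k]);
      y0 = std::min(y0, sy[k]); y1 = std::max(y1, sy[k]);
    }
    int i0 = std::max(0, std::min(ng - 1, (int)((x0 - gxmin) / hx)));
    int i1 = std::max(0, std::min(ng - 1, (int)((x1 - gxmin) / hx)));
    int j0 = std::max(0, std::min(ng - 1, (int)((y0 - gymin) / hy)));
    int j1 = std::max(0, std::min(ng - 1, (int)((y1 - gymin) / hy)));
    for (int ii = i0; ii <= i1; ++ii)
      for (int jj = j0; jj <= j1; ++jj) {
        const std::vector<int> &cand = cells[ii * ng + jj];
        for (size_t q = 0; q < cand.size(); ++q) {
          int j = cand[q];
          if (seen[j] == i) continue;
          seen[j] = i;
          if (bxmin[j] > x1 || bxmax[j] < x0 || bymin[j] > y1 || bymax[j] < y0)
            continue;
          for (int k = 0; k < 3; ++k) {
            ccx[k] = vb(tb(j, k) - 1, 0); ccy[k] = vb(tb(j, k) - 1, 1);
          }
          double A = clip_area(sx, sy, ccx, ccy, 3);
          if (A > 0) { ri.push_back(i + 1); rj.push_back(j + 1); rv.push_back(A); }
        }
      }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(rj), _["area"] = wrap(rv));
}

// [[Rcpp::export]]
LogicalVector cpp_point_in_poly(NumericMatrix pts, NumericMatrix poly) {
  int n = pts.nrow(), m = poly.nrow();
  LogicalVector res(n);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1);
    bool inside = false;
    for (int i = 0, j = m - 1; i < m; j = i++) {
      double xi = poly(i, 0), yi = poly(i, 1), xj = poly(j, 0), yj = poly(j, 1);
      if (((yi > y) != (yj > y)) &&
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        inside = !inside;
    }
    res[p] = inside;
  }
  return res;
}
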