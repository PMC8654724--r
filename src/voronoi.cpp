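#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bounded 2D Voronoi tessellation of points in a rectangle by per-cell
// half-plane clipping.  Clipping against the rectangle is equivalent to
// closing unbounded regions with points mirrored across each face: the
// perpendicular bisector of a point and its mirror image is the face itself.
// Candidate neighbors come from a bucket grid and are processed inside a
// growing radius with the standard security-radius stop: a site at distance
// d from site i cannot cut i's polygon once d >= 2 * max distance from i to
// the current polygon vertices.

namespace {

struct Poly {
  std::vector<double> x, y;
  std::vector<int> lab; // lab[e]: edge from vertex e to e+1; >=0 neighbor site, <0 domain face
  size_t size() const { return x.size(); }
};

// clip polygon by half-plane (p - m) . u <= 0, new edges labelled newlab
void clip_halfplane(Poly &p, double mx, double my, double ux, double uy,
                    int newlab, Poly &out) {
  const size_t n = p.size();
  out.x.clear(); out.y.clear(); out.lab.clear();
  if (n == 0) return;
  std::vector<double> s(n);
  bool any_in = false, any_out = false;
  for (size_t k = 0; k < n; ++k) {
    s[k] = (p.x[k] - mx) * ux + (p.y[k] - my) * uy;
    if (s[k] <= 0) any_in = true; else any_out = true;
  }
  if (!any_out) { out = p; return; }
  if (!any_in) return; // emptied (cannot happen for the owning site)
  for (size_t k = 0; k < n; ++k) {
    size_t k2 = (k + 1 == n) ? 0 : k + 1;
    double sc = s[k], sn = s[k2];
    if (sc <= 0 && sn <= 0) {
      out.x.push_back(p.x[k]); out.y.push_back(p.y[k]); out.lab.push_back(p.lab[k]);
    } else if (sc <= 0 && sn > 0) {
      out.x.push_back(p.x[k]); out.y.push_back(p.y[k]); out.lab.push_back(p.lab[k]);
      double t = sc / (sc - sn);
      out.x.push_back(p.x[k] + t * (p.x[k2] - p.x[k]));
      out.y.push_back(p.y[k] + t * (p.y[k2] - p.y[k]));
      out.lab.push_back(newlab);
    } else if (sc > 0 && sn <= 0) {
      double t = sc / (sc - sn);
      out.x.push_back(p.x[k] + t * (p.x[k2] - p.x[k]));
      out.y.push_back(p.y[k] + t * (p.y[k2] - p.y[k]));
      out.lab.push_back(p.lab[k]);
    }
  }
}

struct Bucket {
  int nbx, nby;
  double x0, y0, cs;
  std::vector<int> head, nxt;
  void build(const NumericVector &px, const NumericVector &py,
             double xlo, double xhi, double ylo, double yhi, double cell) {
    cs = cell; x0 = xlo; y0 = ylo;
    nbx = std::max(1, (int)std::ceil((xhi - xlo) / cs));
    nby = std::max(1, (int)std::ceil((yhi - ylo) / cs));
    head.assign((size_t)nbx * nby, -1);
    nxt.assign(px.size(), -1);
    for (int i = 0; i < px.size(); ++i) {
      int bx = clampi((int)((px[i] - x0) / cs), nbx);
      int by = clampi((int)((py[i] - y0) / cs), nby);
      int b = by * nbx + bx;
      nxt[i] = head[b]; head[b] = i;
    }
  }
  static int clampi(int v, int n) { return v < 0 ? 0 : (v >= n ? n - 1 : v); }
};

} // namespace

// [[Rcpp::export]]
List cg_voronoi_rect(NumericVector px, NumericVector py,
                     double xlo, double xhi, double ylo, double yhi,
                     bool polygons) {
  const int n = px.size();
  const double wx = xhi - xlo, wy = yhi - ylo;
  const double scale = std::max(wx, wy);
  const double dup_tol = 1e-12 * scale;
  const double len_tol = 1e-10 * scale;

  double cs = std::sqrt(std::max(wx * wy / std::max(n, 1) * 2.0, 1e-300));
  cs = std::min(cs, scale);
  Bucket bk;
  bk.build(px, py, xlo, xhi, ylo, yhi, cs);

  NumericVector area(n), perim(n);
  LogicalVector boundary(n);
  std::vector<int> nb_i, nb_j;
  std::vector<double> nb_len;
  List polys(polygons ? n : 0), plabs(polygons ? n : 0);

  const double diam2 = wx * wx + wy * wy;
  std::vector<std::pair<double, int>> cand;
  Poly poly, tmp;

  for (int i = 0; i < n; ++i) {
    const double xi = px[i], yi = py[i];
    // start from the domain rectangle, faces labelled -1..-4
    poly.x = {xlo, xhi, xhi, xlo};
    poly.y = {ylo, ylo, yhi, yhi};
    poly.lab = {-1, -2, -3, -4};

    double maxd2 = 0;
    for (size_t k = 0; k < 4; ++k) {
      double dx = poly.x[k] - xi, dy = poly.y[k] - yi;
      maxd2 = std::max(maxd2, dx * dx + dy * dy);
    }

    double r_in = 0.0, r_out = 3.0 * cs;
    bool done = false;
    while (!done) {
      // gather candidates with distance in (r_in, r_out]
      cand.clear();
      double r_out2 = r_out * r_out, r_in2 = r_in * r_in;
      int bx0 = Bucket::clampi((int)((xi - r_out - xlo) / bk.cs), bk.nbx);
      int bx1 = Bucket::clampi((int)((xi + r_out - xlo) / bk.cs), bk.nbx);
      int by0 = Bucket::clampi((int)((yi - r_out - ylo) / bk.cs), bk.nby);
      int by1 = Bucket::clampi((int)((yi + r_out - ylo) / bk.cs), bk.nby);
      for (int by = by0; by <= by1; ++by)
        for (int bx = bx0; bx <= bx1; ++bx)
          for (int j = bk.head[by * bk.nbx + bx]; j != -1; j = bk.nxt[j]) {
            if (j == i) continue;
            double dx = px[j] - xi, dy = py[j] - yi;
            double d2 = dx * dx + dy * dy;
            if (d2 <= r_out2 && d2 > r_in2) cand.push_back({d2, j});
          }
      std::sort(cand.begin(), cand.end());
      for (auto &c : cand) {
        double d = std::sqrt(c.first);
        if (d < dup_tol)
          stop("duplicate cell centers at indices %d and %d", i + 1, c.second + 1);
        if (c.first >= 4.0 * maxd2) break; // cannot cut, nor can any farther
        int j = c.second;
        double ux = (px[j] - xi) / d, uy = (py[j] - yi) / d;
        double mx = 0.5 * (xi + px[j]), my = 0.5 * (yi + py[j]);
        clip_halfplane(poly, mx, my, ux, uy, j, tmp);
        std::swap(poly, tmp);
        maxd2 = 0;
        for (size_t k = 0; k < poly.size(); ++k) {
          double dx = poly.x[k] - xi, dy = poly.y[k] - yi;
          maxd2 = std::max(maxd2, dx * dx + dy * dy);
        }
      }
      if (r_out * r_out >= 4.0 * maxd2 || r_out * r_out >= diam2) done = true;
      else { r_in = r_out; r_out *= 1.8; }
    }

    // area (shoelace), perimeter, edges
    double A = 0, P = 0;
    bool bnd = false;
    const size_t m = poly.size();
    for (size_t k = 0; k < m; ++k) {
      size_t k2 = (k + 1 == m) ? 0 : k + 1;
      A += poly.x[k] * poly.y[k2] - poly.x[k2] * poly.y[k];
      double ex = poly.x[k2] - poly.x[k], ey = poly.y[k2] - poly.y[k];
      double el = std::sqrt(ex * ex + ey * ey);
      if (el <= len_tol) continue;
      P += el;
      if (poly.lab[k] >= 0) {
        nb_i.push_back(i + 1);
        nb_j.push_back(poly.lab[k] + 1);
        nb_len.push_back(el);
      } else {
        bnd = true;
      }
    }
    area[i] = 0.5 * A;
    perim[i] = P;
    boundary[i] = bnd;
    if (polygons) {
      NumericMatrix pm(m, 2);
      IntegerVector lv(m);
      for (size_t k = 0; k < m; ++k) {
        pm(k, 0) = poly.x[k]; pm(k, 1) = poly.y[k];
        lv[k] = poly.lab[k] >= 0 ? poly.lab[k] + 1 : poly.lab[k];
      }
      polys[i] = pm; plabs[i] = lv;
    }
  }

  List out = List::create(
      _["area"] = area, _["perim"] = perim, _["boundary"] = boundary,
      _["nbr_i"] = wrap(nb_i), _["nbr_j"] = wrap(nb_j),
      _["nbr_len"] = wrap(nb_len));
  if (polygons) { out["polys"] = polys; out["edge_labs"] = plabs; }
  return out;
}

// All unordered pairs (i < j) with distance <= rcut, via a bucket grid.
// [[Rcpp::export]]
List cg_pairs_within(NumericVector px, NumericVector py, double rcut) {
  const int n = px.size();
  double xlo = R_PosInf, xhi = R_NegInf, ylo = R_PosInf, yhi = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xlo = std::min(xlo, px[i]); xhi = std::max(xhi, px[i]);
    ylo = std::min(ylo, py[i]); yhi = std::max(yhi, py[i]);
  }
  if (!(xhi > xlo)) xhi = xlo + 1;
  if (!(yhi > ylo)) yhi = ylo + 1;
  // cap the bucket count so tiny cutoffs cannot blow up memory; buckets
  // only need to be at least rcut wide for the 3x3 neighborhood search
  double cs = std::max({rcut, (xhi - xlo) / 1024.0, (yhi - ylo) / 1024.0, 1e-12});
  Bucket bk;
  bk.build(px, py, xlo, xhi, ylo, yhi, cs);
  std::vector<int> oi, oj;
  std::vector<double> od;
  const double r2 = rcut * rcut;
  for (int i = 0; i < n; ++i) {
    int bx = Bucket::clampi((int)((px[i] - xlo) / bk.cs), bk.nbx);
    int by = Bucket::clampi((int)((py[i] - ylo) / bk.cs), bk.nby);
    for (int dy = -1; dy <= 1; ++dy) {
      int byy = by + dy;
      if (byy < 0 || byy >= bk.nby) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int bxx = bx + dx;
        if (bxx < 0 || bxx >= bk.nbx) continue;
        for (int j = bk.head[byy * bk.nbx + bxx]; j != -1; j = bk.nxt[j]) {
          if (j <= i) continue;
          double ddx = px[j] - px[i], ddy = py[j] - py[i];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 <= r2) {
            oi.push_back(i + 1); oj.push_back(j + 1);
            od.push_back(std::sqrt(d2));
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj), _["r"] = wrap(od));
}
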