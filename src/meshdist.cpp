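#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest-point distance from a point to a triangle (Ericson, Real-Time
// Collision Detection, ch. 5.1.5).
static double pt_tri_dist2(const double* p, const double* a, const double* b,
                           const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double best[3];
  if (d1 <= 0.0 && d2 <= 0.0) {
    best[0] = a[0]; best[1] = a[1]; best[2] = a[2];
  } else {
    double bp[3], cp[3];
    for (int i = 0; i < 3; ++i) { bp[i] = p[i] - b[i]; cp[i] = p[i] - c[i]; }
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      best[0] = b[0]; best[1] = b[1]; best[2] = b[2];
    } else if (d6 >= 0.0 && d5 <= d6) {
      best[0] = c[0]; best[1] = c[1]; best[2] = c[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      double vb = d5 * d2 - d1 * d6;
      double va = d3 * d6 - d5 * d4;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) best[i] = a[i] + v * ab[i];
      } else if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
        double w = d2 / (d2 - d6);
        for (int i = 0; i < 3; ++i) best[i] = a[i] + w * ac[i];
      } else if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
        double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        for (int i = 0; i < 3; ++i) best[i] = b[i] + w * (c[i] - b[i]);
      } else {
        double denom = va + vb + vc;
        double v = vb / denom, w = vc / denom;
        for (int i = 0; i < 3; ++i) best[i] = a[i] + ab[i] * v + ac[i] * w;
      }
    }
  }
  double dx = p[0] - best[0], dy = p[1] - best[1], dz = p[2] - best[2];
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V,
                                      IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  // triangle bounding spheres for a cheap reject
  std::vector<double> cx(nf), cy(nf), cz(nf), cr(nf);
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double mx = (V(ia, 0) + V(ib, 0) + V(ic, 0)) / 3.0;
    double my = (V(ia, 1) + V(ib, 1) + V(ic, 1)) / 3.0;
    double mz = (V(ia, 2) + V(ib, 2) + V(ic, 2)) / 3.0;
    double r2 = 0.0;
    int idx[3] = {ia, ib, ic};
    for (int k = 0; k < 3; ++k) {
      double dx = V(idx[k], 0) - mx, dy = V(idx[k], 1) - my,
             dz = V(idx[k], 2) - mz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    cx[f] = mx; cy[f] = my; cz[f] = mz; cr[f] = std::sqrt(r2);
  }
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = R_PosInf;
    double bestd = R_PosInf;  // sqrt of best
    for (int f = 0; f < nf; ++f) {
      double dx = p[0] - cx[f], dy = p[1] - cy[f], dz = p[2] - cz[f];
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - cr[f];
      if (dc > bestd) continue;
      int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
      double b[3] = {V(ib, 0), V(ib, 1), V(ib, 2)};
      double c[3] = {V(ic, 0), V(ic, 1), V(ic, 2)};
      double d2 = pt_tri_dist2(p, a, b, c);
      if (d2 < best) { best = d2; bestd = std::sqrt(d2); }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Ray-triangle intersection (Moller-Trumbore). Returns t or -1.
static double ray_tri(const double* o, const double* d, const double* a,
                      const double* b, const double* c, bool* degenerate) {
  const double EPS = 1e-12;
  double e1[3], e2[3];
  for (int i = 0; i < 3; ++i) { e1[i] = b[i] - a[i]; e2[i] = c[i] - a[i]; }
  double pv[3] = {d[1] * e2[2] - d[2] * e2[1], d[2] * e2[0] - d[0] * e2[2],
                  d[0] * e2[1] - d[1] * e2[0]};
  double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
  if (std::fabs(det) < EPS) return -1.0;
  double inv = 1.0 / det;
  double tv[3] = {o[0] - a[0], o[1] - a[1], o[2] - a[2]};
  double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1], tv[2] * e1[0] - tv[0] * e1[2],
                  tv[0] * e1[1] - tv[1] * e1[0]};
  double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  // flag hits suspiciously close to an edge: the caller retries another ray
  if (u < 1e-7 || v < 1e-7 || u + v > 1.0 - 1e-7) *degenerate = true;
  double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
  return t;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V,
                                 IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  // fixed, irrational-ish ray directions to dodge axis-aligned degeneracies
  LogicalVector out(np);
  double D1[3] = {0.5735764363, 0.5446390350, 0.6115456781};
  double D2[3] = {-0.3213938048, 0.8528685320, 0.4118988160};
  double D3[3] = {0.7248956066, -0.1736481777, 0.6665634487};
  double* DIRS[3] = {D1, D2, D3};
  for (int i = 0; i < np; ++i) {
    double o[3] = {P(i, 0), P(i, 1), P(i, 2)};
    bool inside = false;
    for (int attempt = 0; attempt < 3; ++attempt) {
      const double* d = DIRS[attempt];
      int crossings = 0;
      bool bad = false;
      for (int f = 0; f < nf && !bad; ++f) {
        int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
        double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
        double b[3] = {V(ib, 0), V(ib, 1), V(ib, 2)};
        double c[3] = {V(ic, 0), V(ic, 1), V(ic, 2)};
        bool degen = false;
        double t = ray_tri(o, d, a, b, c, &degen);
        if (t > 1e-9) {
          if (degen) bad = true;
          else ++crossings;
        }
      }
      if (!bad) { inside = (crossings % 2) == 1; break; }
      if (attempt == 2) inside = (crossings % 2) == 1;  // best effort
    }
    out[i] = inside;
  }
  return out;
}

// Orthographic top-down silhouette rasterization on pixel centres.
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_topdown(NumericMatrix V, IntegerMatrix F,
                                    LogicalVector keep, double x0, double y0,
                                    double px, int nx, int ny) {
  IntegerMatrix img(ny, nx);  // row = y, col = x
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    if (!keep[f]) continue;
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double ax = V(ia, 0), ay = V(ia, 1);
    double bx = V(ib, 0), by = V(ib, 1);
    double cx = V(ic, 0), cy = V(ic, 1);
    double minx = std::min(ax, std::min(bx, cx));
    double maxx = std::max(ax, std::max(bx, cx));
    double miny = std::min(ay, std::min(by, cy));
    double maxy = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::floor((minx - x0) / px - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((maxx - x0) / px - 0.5));
    int j0 = std::max(0, (int)std::floor((miny - y0) / px - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((maxy - y0) / px - 0.5));
    double d = (by - cy) * (ax - cx) + (cx - bx) * (ay - cy);
    if (std::fabs(d) < 1e-14) continue;
    for (int jj = j0; jj <= j1; ++jj) {
      double pyc = y0 + (jj + 0.5) * px;
      for (int ii = i0; ii <= i1; ++ii) {
        double pxc = x0 + (ii + 0.5) * px;
        double w1 = ((by - cy) * (pxc - cx) + (cx - bx) * (pyc - cy)) / d;
        double w2 = ((cy - ay) * (pxc - cx) + (ax - cx) * (pyc - cy)) / d;
        double w3 = 1.0 - w1 - w2;
        double tol = -1e-9;
        if (w1 >= tol && w2 >= tol && w3 >= tol) img(jj, ii) = 1;
      }
    }
  }
  return img;
}
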