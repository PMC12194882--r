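#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Local copy of the point-triangle distance (kept static in meshdist.cpp).
static double ptd2(const double* p, const double* a, const double* b,
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

struct CellKey {
  long long k;
};

static inline long long cell_key(int ix, int iy, int iz) {
  return ((long long)(ix + 1048576) << 42) |
         ((long long)(iy + 1048576) << 21) | (long long)(iz + 1048576);
}

// TRUE per query point when its distance to the mesh is below `thresh`.
// Uniform hash-grid over triangle bounding boxes; cell size = thresh.
// [[Rcpp::export]]
LogicalVector cpp_points_within_dist(NumericMatrix P, NumericMatrix V,
                                     IntegerMatrix F, double thresh) {
  int np = P.nrow(), nf = F.nrow();
  double h = thresh;
  if (h <= 0) stop("thresh must be > 0");
  std::unordered_map<long long, std::vector<int>> grid;
  grid.reserve(nf * 2);
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(V(ia, d), std::min(V(ib, d), V(ic, d)));
      hi[d] = std::max(V(ia, d), std::max(V(ib, d), V(ic, d)));
    }
    int x0 = (int)std::floor(lo[0] / h), x1 = (int)std::floor(hi[0] / h);
    int y0 = (int)std::floor(lo[1] / h), y1 = (int)std::floor(hi[1] / h);
    int z0 = (int)std::floor(lo[2] / h), z1 = (int)std::floor(hi[2] / h);
    for (int ix = x0; ix <= x1; ++ix)
      for (int iy = y0; iy <= y1; ++iy)
        for (int iz = z0; iz <= z1; ++iz)
          grid[cell_key(ix, iy, iz)].push_back(f);
  }
  double t2 = thresh * thresh;
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    int cx = (int)std::floor(p[0] / h);
    int cy = (int)std::floor(p[1] / h);
    int cz = (int)std::floor(p[2] / h);
    bool hit = false;
    for (int ix = cx - 1; ix <= cx + 1 && !hit; ++ix) {
      for (int iy = cy - 1; iy <= cy + 1 && !hit; ++iy) {
        for (int iz = cz - 1; iz <= cz + 1 && !hit; ++iz) {
          auto it = grid.find(cell_key(ix, iy, iz));
          if (it == grid.end()) continue;
          for (int f : it->second) {
            int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
            double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
            double b[3] = {V(ib, 0), V(ib, 1), V(ib, 2)};
            double c[3] = {V(ic, 0), V(ic, 1), V(ic, 2)};
            if (ptd2(p, a, b, c) < t2) { hit = true; break; }
          }
        }
      }
    }
    out[i] = hit;
  }
  return out;
}
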