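#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shortest-edge collapse decimation with manifold (link-condition) and
// normal-flip guards. Works on closed 2-manifold triangle meshes; boundary
// edges are never collapsed, so open meshes keep their boundary loops.

struct Mesh {
  std::vector<double> vx, vy, vz;
  std::vector<std::array<int, 3>> faces;  // 0-based, -1 marks dead
  std::vector<std::vector<int>> vfaces;   // incident faces per vertex
  std::vector<bool> vdead;

  int nV() const { return (int)vx.size(); }

  void neighbors(int v, std::set<int>& out) const {
    out.clear();
    for (int f : vfaces[v]) {
      if (faces[f][0] < 0) continue;
      for (int k = 0; k < 3; ++k)
        if (faces[f][k] != v) out.insert(faces[f][k]);
    }
  }

  bool face_has(int f, int v) const {
    return faces[f][0] == v || faces[f][1] == v || faces[f][2] == v;
  }

  void fnormal(int f, double* n) const {
    const std::array<int, 3>& t = faces[f];
    double ux = vx[t[1]] - vx[t[0]], uy = vy[t[1]] - vy[t[0]],
           uz = vz[t[1]] - vz[t[0]];
    double wx = vx[t[2]] - vx[t[0]], wy = vy[t[2]] - vy[t[0]],
           wz = vz[t[2]] - vz[t[0]];
    n[0] = uy * wz - uz * wy;
    n[1] = uz * wx - ux * wz;
    n[2] = ux * wy - uy * wx;
  }
};

// [[Rcpp::export]]
List cpp_decimate(NumericMatrix V, IntegerMatrix F, int target_faces,
                  int max_passes) {
  Mesh m;
  int nv = V.nrow(), nf = F.nrow();
  m.vx.resize(nv); m.vy.resize(nv); m.vz.resize(nv);
  for (int i = 0; i < nv; ++i) {
    m.vx[i] = V(i, 0); m.vy[i] = V(i, 1); m.vz[i] = V(i, 2);
  }
  m.faces.resize(nf);
  m.vfaces.resize(nv);
  m.vdead.assign(nv, false);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int v = F(f, k) - 1;
      m.faces[f][k] = v;
      m.vfaces[v].push_back(f);
    }
  }
  int alive = nf;

  for (int pass = 0; pass < max_passes && alive > target_faces; ++pass) {
    // collect live edges with lengths
    std::vector<std::pair<double, std::pair<int, int>>> edges;
    edges.reserve(alive * 3 / 2);
    {
      std::set<std::pair<int, int>> seen;
      for (int f = 0; f < nf; ++f) {
        if (m.faces[f][0] < 0) continue;
        for (int k = 0; k < 3; ++k) {
          int a = m.faces[f][k], b = m.faces[f][(k + 1) % 3];
          std::pair<int, int> key(std::min(a, b), std::max(a, b));
          if (seen.insert(key).second) {
            double dx = m.vx[a] - m.vx[b], dy = m.vy[a] - m.vy[b],
                   dz = m.vz[a] - m.vz[b];
            edges.push_back({dx * dx + dy * dy + dz * dz, key});
          }
        }
      }
    }
    std::sort(edges.begin(), edges.end());
    std::vector<bool> touched(nv, false);
    int collapsed = 0;
    std::set<int> na, nb, common;
    for (auto& e : edges) {
      if (alive <= target_faces) break;
      int a = e.second.first, b = e.second.second;
      if (m.vdead[a] || m.vdead[b] || touched[a] || touched[b]) continue;
      // faces sharing the edge
      std::vector<int> shared;
      for (int f : m.vfaces[a])
        if (m.faces[f][0] >= 0 && m.face_has(f, b)) shared.push_back(f);
      if (shared.size() != 2) continue;  // boundary or non-manifold: skip
      // link condition: common neighbors must be exactly the two apexes
      m.neighbors(a, na);
      m.neighbors(b, nb);
      common.clear();
      std::set_intersection(na.begin(), na.end(), nb.begin(), nb.end(),
                            std::inserter(common, common.begin()));
      if (common.size() != 2) continue;
      bool ok = true;
      for (int f : shared) {
        for (int k = 0; k < 3; ++k) {
          int v = m.faces[f][k];
          if (v != a && v != b && common.find(v) == common.end()) ok = false;
        }
      }
      if (!ok) continue;
      // tentative midpoint placement; reject if any surviving face flips
      double oax = m.vx[a], oay = m.vy[a], oaz = m.vz[a];
      double mx = 0.5 * (m.vx[a] + m.vx[b]), my = 0.5 * (m.vy[a] + m.vy[b]),
             mz = 0.5 * (m.vz[a] + m.vz[b]);
      std::vector<int> affected;
      for (int f : m.vfaces[a])
        if (m.faces[f][0] >= 0 && !m.face_has(f, b)) affected.push_back(f);
      for (int f : m.vfaces[b])
        if (m.faces[f][0] >= 0 && !m.face_has(f, a)) affected.push_back(f);
      std::vector<double> before(affected.size() * 3);
      for (size_t i = 0; i < affected.size(); ++i)
        m.fnormal(affected[i], &before[3 * i]);
      // apply tentative move (b faces still reference b; move both)
      double obx = m.vx[b], oby = m.vy[b], obz = m.vz[b];
      m.vx[a] = mx; m.vy[a] = my; m.vz[a] = mz;
      m.vx[b] = mx; m.vy[b] = my; m.vz[b] = mz;
      bool flip = false;
      for (size_t i = 0; i < affected.size() && !flip; ++i) {
        double n2[3];
        m.fnormal(affected[i], n2);
        double dot = before[3 * i] * n2[0] + before[3 * i + 1] * n2[1] +
                     before[3 * i + 2] * n2[2];
        if (dot <= 0.0) flip = true;
      }
      if (flip) {
        m.vx[a] = oax; m.vy[a] = oay; m.vz[a] = oaz;
        m.vx[b] = obx; m.vy[b] = oby; m.vz[b] = obz;
        continue;
      }
      // commit: kill shared faces, rewire b->a
      for (int f : shared) {
        m.faces[f][0] = -1;
        --alive;
      }
      for (int f : m.vfaces[b]) {
        if (m.faces[f][0] < 0) continue;
        for (int k = 0; k < 3; ++k)
          if (m.faces[f][k] == b) m.faces[f][k] = a;
        m.vfaces[a].push_back(f);
      }
      m.vdead[b] = true;
      touched[a] = true;
      for (int v : na) if (v < nv) touched[v] = true;
      for (int v : nb) if (v < nv) touched[v] = true;
      ++collapsed;
    }
    if (collapsed == 0) break;
  }

  // compact output
  std::vector<int> vmap(nv, -1);
  int nvo = 0;
  for (int f = 0; f < nf; ++f) {
    if (m.faces[f][0] < 0) continue;
    for (int k = 0; k < 3; ++k)
      if (vmap[m.faces[f][k]] < 0) vmap[m.faces[f][k]] = nvo++;
  }
  NumericMatrix Vo(nvo, 3);
  for (int v = 0; v < nv; ++v) {
    if (vmap[v] < 0) continue;
    Vo(vmap[v], 0) = m.vx[v];
    Vo(vmap[v], 1) = m.vy[v];
    Vo(vmap[v], 2) = m.vz[v];
  }
  IntegerMatrix Fo(alive, 3);
  int fo = 0;
  for (int f = 0; f < nf; ++f) {
    if (m.faces[f][0] < 0) continue;
    for (int k = 0; k < 3; ++k) Fo(fo, k) = vmap[m.faces[f][k]] + 1;
    ++fo;
  }
  return List::create(_["vertices"] = Vo, _["faces"] = Fo);
}
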