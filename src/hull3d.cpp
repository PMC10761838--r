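#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Exact 3-D convex hull (incremental / beneath-beyond) for functional
// richness. Point counts are small (species pools), so no conflict graph
// is needed. Degenerate inputs (< 4 affinely independent points) report
// zero volume with a flag instead of erroring.

namespace {

struct Vec3 { double x, y, z; };

Vec3 sub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Facet { int a, b, c; };

// signed distance of p above facet plane (positive = outside)
double facet_dist(const std::vector<Vec3>& P, const Facet& f, const Vec3& p) {
  Vec3 n = cross(sub(P[f.b], P[f.a]), sub(P[f.c], P[f.a]));
  double nn = norm(n);
  if (nn == 0.0) return 0.0;
  return dot(n, sub(p, P[f.a])) / nn;
}

void orient_outward(const std::vector<Vec3>& P, Facet& f, const Vec3& interior) {
  if (facet_dist(P, f, interior) > 0) std::swap(f.b, f.c);
}

} // namespace

// [[Rcpp::export]]
List hull3d_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<Vec3> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    scale = std::max(scale, std::max(std::fabs(P[i].x),
                     std::max(std::fabs(P[i].y), std::fabs(P[i].z))));
  }
  double eps = 1e-9 * std::max(scale, 1.0);

  List degenerate = List::create(_["volume"] = 0.0,
                                 _["vertices"] = IntegerVector(0),
                                 _["degenerate"] = true);
  if (n < 4) return degenerate;

  // initial simplex: mutually far points
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1;
  for (int i = 1; i < n; ++i) {
    double d = norm(sub(P[i], P[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (best < eps) return degenerate;
  best = -1;
  Vec3 dir = sub(P[i1], P[i0]);
  for (int i = 0; i < n; ++i) {
    Vec3 v = sub(P[i], P[i0]);
    double d = norm(cross(dir, v)) / norm(dir);
    if (d > best) { best = d; i2 = i; }
  }
  if (best < eps) return degenerate;
  Vec3 nrm = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(P[i], P[i0]))) / norm(nrm);
    if (d > best) { best = d; i3 = i; }
  }
  if (best < eps) return degenerate;

  Vec3 interior = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                   (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                   (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Facet> facets = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (auto& f : facets) orient_outward(P, f, interior);

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;

  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < facets.size(); ++f)
      if (facet_dist(P, facets[f], P[i]) > eps) visible.push_back((int)f);
    if (visible.empty()) continue;

    // horizon = directed edges of visible facets whose reverse is not visible
    std::map<std::pair<int, int>, int> edge_seen;
    for (int fi : visible) {
      const Facet& f = facets[fi];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (auto& ed : e) edge_seen[{ed[0], ed[1]}]++;
    }
    std::vector<std::pair<int, int>> horizon;
    for (auto& kv : edge_seen) {
      auto rev = std::make_pair(kv.first.second, kv.first.first);
      if (edge_seen.find(rev) == edge_seen.end()) horizon.push_back(kv.first);
    }

    std::vector<Facet> kept;
    std::vector<bool> vis(facets.size(), false);
    for (int fi : visible) vis[fi] = true;
    for (size_t f = 0; f < facets.size(); ++f)
      if (!vis[f]) kept.push_back(facets[f]);
    for (auto& ed : horizon) {
      Facet nf = {ed.first, ed.second, i};
      orient_outward(P, nf, interior);
      kept.push_back(nf);
    }
    facets.swap(kept);
  }

  double vol = 0.0;
  std::vector<bool> is_vertex(n, false);
  for (auto& f : facets) {
    Vec3 a = sub(P[f.a], interior), b = sub(P[f.b], interior), c = sub(P[f.c], interior);
    vol += std::fabs(dot(a, cross(b, c))) / 6.0;
    is_vertex[f.a] = is_vertex[f.b] = is_vertex[f.c] = true;
  }
  IntegerVector verts;
  for (int i = 0; i < n; ++i)
    if (is_vertex[i]) verts.push_back(i + 1);

  return List::create(_["volume"] = vol, _["vertices"] = verts,
                      _["degenerate"] = false);
}
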