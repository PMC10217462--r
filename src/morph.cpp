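// Surface mesh (marching tetrahedra on the 0.5 level set of a binary mask),
// 3D convex hull (incremental), and pairwise distance helpers for the
// morphology feature block.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

struct V3 { double x, y, z; };
static inline V3 sub(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double nrm(V3 a) { return std::sqrt(dot(a, a)); }

// cube corner offsets and its 6-tetrahedra split along the 0-7 diagonal
static const int CO[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},
                             {0,0,1},{1,0,1},{0,1,1},{1,1,1}};
static const int TETS[6][4] = {{0,5,1,7},{0,1,3,7},{0,3,2,7},
                               {0,2,6,7},{0,6,4,7},{0,4,5,7}};

// Triangulates the `iso` level set of a scalar field (a binary mask or a
// smoothed version of it), with linearly interpolated edge crossings.
// [[Rcpp::export]]
List cpp_mesh(NumericVector field, IntegerVector dim, NumericVector spacing,
              double iso = 0.5) {
  int d[3] = {dim[0], dim[1], dim[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  auto value = [&](int x, int y, int z) -> double {
    if (x < 0 || x >= d[0] || y < 0 || y >= d[1] || z < 0 || z >= d[2])
      return 0.0;
    return field[x + (long)d[0] * (y + (long)d[1] * z)];
  };
  double area = 0, vol6 = 0;
  std::vector<double> vx, vy, vz;
  std::unordered_map<long long, int> seen;
  auto addVert = [&](V3 p) {
    long long key = (long long)std::llround(p.x * 64 / sp[0]) * 400000037LL +
                    (long long)std::llround(p.y * 64 / sp[1]) * 200003LL +
                    (long long)std::llround(p.z * 64 / sp[2]);
    if (seen.find(key) == seen.end()) {
      seen[key] = 1;
      vx.push_back(p.x); vy.push_back(p.y); vz.push_back(p.z);
    }
  };
  auto emit = [&](V3 p1, V3 p2, V3 p3, V3 ref, bool refInside) {
    // orient the triangle so its normal points away from the inside region
    V3 n = cross(sub(p2, p1), sub(p3, p1));
    V3 cen = {(p1.x + p2.x + p3.x) / 3, (p1.y + p2.y + p3.y) / 3,
              (p1.z + p2.z + p3.z) / 3};
    double s = dot(n, sub(ref, cen));
    bool flip = refInside ? (s > 0) : (s < 0);
    if (flip) { V3 t = p2; p2 = p3; p3 = t; n = cross(sub(p2, p1), sub(p3, p1)); }
    area += 0.5 * nrm(n);
    vol6 += dot(p1, cross(p2, p3));
    addVert(p1); addVert(p2); addVert(p3);
  };
  for (int z = -1; z < d[2]; ++z)
    for (int y = -1; y < d[1]; ++y)
      for (int x = -1; x < d[0]; ++x) {
        double fv[8];
        int cv[8];
        int tot = 0;
        for (int k = 0; k < 8; ++k) {
          fv[k] = value(x + CO[k][0], y + CO[k][1], z + CO[k][2]);
          cv[k] = fv[k] > iso ? 1 : 0;
          tot += cv[k];
        }
        if (tot == 0 || tot == 8) continue;
        V3 cp[8];
        for (int k = 0; k < 8; ++k)
          cp[k] = {(x + CO[k][0]) * sp[0], (y + CO[k][1]) * sp[1],
                   (z + CO[k][2]) * sp[2]};
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int in[4], ni = 0;
          for (int k = 0; k < 4; ++k) { in[k] = cv[vi[k]]; ni += in[k]; }
          if (ni == 0 || ni == 4) continue;
          auto mid = [&](int a, int b) -> V3 {
            double va = fv[vi[a]], vb = fv[vi[b]];
            double t = (vb == va) ? 0.5 : (iso - va) / (vb - va);
            if (t < 0) t = 0;
            if (t > 1) t = 1;
            return {cp[vi[a]].x + t * (cp[vi[b]].x - cp[vi[a]].x),
                    cp[vi[a]].y + t * (cp[vi[b]].y - cp[vi[a]].y),
                    cp[vi[a]].z + t * (cp[vi[b]].z - cp[vi[a]].z)};
          };
          if (ni == 1 || ni == 3) {
            int lone = -1;
            for (int k = 0; k < 4; ++k)
              if ((ni == 1 && in[k]) || (ni == 3 && !in[k])) lone = k;
            int oth[3], c = 0;
            for (int k = 0; k < 4; ++k) if (k != lone) oth[c++] = k;
            V3 p1 = mid(lone, oth[0]), p2 = mid(lone, oth[1]),
               p3 = mid(lone, oth[2]);
            emit(p1, p2, p3, cp[vi[lone]], ni == 1);
          } else {
            int A[2], B[2], ca = 0, cb = 0;
            for (int k = 0; k < 4; ++k)
              if (in[k]) A[ca++] = k; else B[cb++] = k;
            V3 q1 = mid(A[0], B[0]), q2 = mid(A[0], B[1]),
               q3 = mid(A[1], B[1]), q4 = mid(A[1], B[0]);
            V3 refIn = {(cp[vi[A[0]]].x + cp[vi[A[1]]].x) / 2,
                        (cp[vi[A[0]]].y + cp[vi[A[1]]].y) / 2,
                        (cp[vi[A[0]]].z + cp[vi[A[1]]].z) / 2};
            emit(q1, q2, q3, refIn, true);
            emit(q1, q3, q4, refIn, true);
          }
        }
      }
  int nv = vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vz[i];
  }
  return List::create(_["area"] = area, _["volume"] = std::fabs(vol6) / 6.0,
                      _["vertices"] = verts);
}

// incremental 3D convex hull; returns volume, area and hull vertex indices
// [[Rcpp::export]]
List cpp_convhull(NumericMatrix P) {
  int n = P.nrow();
  std::vector<V3> p(n);
  for (int i = 0; i < n; ++i) p[i] = {P(i, 0), P(i, 1), P(i, 2)};
  if (n < 4) return List::create(_["volume"] = 0.0, _["area"] = 0.0,
                                 _["vertices"] = IntegerVector());
  // initial simplex
  int i0 = 0;
  for (int i = 1; i < n; ++i) if (p[i].x < p[i0].x) i0 = i;
  int i1 = -1; double best = -1;
  for (int i = 0; i < n; ++i) {
    double dd = nrm(sub(p[i], p[i0]));
    if (dd > best) { best = dd; i1 = i; }
  }
  int i2 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double dd = nrm(cross(sub(p[i], p[i0]), sub(p[i1], p[i0])));
    if (dd > best) { best = dd; i2 = i; }
  }
  V3 nrm0 = cross(sub(p[i1], p[i0]), sub(p[i2], p[i0]));
  int i3 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double dd = std::fabs(dot(nrm0, sub(p[i], p[i0])));
    if (dd > best) { best = dd; i3 = i; }
  }
  if (best < 1e-12)
    return List::create(_["volume"] = 0.0, _["area"] = 0.0,
                        _["vertices"] = IntegerVector());
  V3 interior = {(p[i0].x + p[i1].x + p[i2].x + p[i3].x) / 4,
                 (p[i0].y + p[i1].y + p[i2].y + p[i3].y) / 4,
                 (p[i0].z + p[i1].z + p[i2].z + p[i3].z) / 4};
  struct Face { int a, b, c; V3 n; double off; bool alive; };
  std::vector<Face> faces;
  auto addFace = [&](int a, int b, int c) {
    V3 nn = cross(sub(p[b], p[a]), sub(p[c], p[a]));
    if (dot(nn, sub(interior, p[a])) > 0) { int t = b; b = c; c = t;
      nn = cross(sub(p[b], p[a]), sub(p[c], p[a])); }
    faces.push_back({a, b, c, nn, dot(nn, p[a]), true});
  };
  addFace(i0, i1, i2); addFace(i0, i1, i3); addFace(i0, i2, i3);
  addFace(i1, i2, i3);
  double scale = 0;
  for (int i = 0; i < n; ++i)
    scale = std::max(scale, std::fabs(p[i].x) + std::fabs(p[i].y) +
                             std::fabs(p[i].z));
  // near-coplanar vertex clouds can destabilize the horizon walk; retry
  // with a coarser tolerance (and a face-count guard) until it converges
  std::vector<Face> faces0 = faces;
  bool done = false;
  for (double mult = 1e-6; mult <= 1e-2 && !done; mult *= 100) {
    faces = faces0;
    double eps = mult * (scale + 1);
    size_t cap = 60u * (size_t)n + 1000u;
    done = true;
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1 || i == i2 || i == i3) continue;
      if (faces.size() > cap) { done = false; break; }
      std::vector<int> vis;
      for (size_t f = 0; f < faces.size(); ++f)
        if (faces[f].alive &&
            dot(faces[f].n, p[i]) - faces[f].off > eps * (nrm(faces[f].n) + eps))
          vis.push_back(f);
      if (vis.empty()) continue;
      // horizon: directed edges of visible faces whose reverse is not visible
      std::unordered_map<long long, int> edges;
      auto ekey = [&](int a, int b) { return (long long)a * 1000003LL + b; };
      for (int f : vis) {
        int e[3][2] = {{faces[f].a, faces[f].b}, {faces[f].b, faces[f].c},
                       {faces[f].c, faces[f].a}};
        for (int k = 0; k < 3; ++k) edges[ekey(e[k][0], e[k][1])] = 1;
      }
      for (int f : vis) faces[f].alive = false;
      for (int f : vis) {
        int e[3][2] = {{faces[f].a, faces[f].b}, {faces[f].b, faces[f].c},
                       {faces[f].c, faces[f].a}};
        for (int k = 0; k < 3; ++k) {
          if (edges.find(ekey(e[k][1], e[k][0])) == edges.end())
            addFace(e[k][0], e[k][1], i);
        }
      }
    }
  }
  double area = 0, vol6 = 0;
  std::vector<char> used(n, 0);
  for (auto& f : faces) {
    if (!f.alive) continue;
    area += 0.5 * nrm(f.n);
    V3 a = sub(p[f.a], interior), b = sub(p[f.b], interior),
       c = sub(p[f.c], interior);
    vol6 += std::fabs(dot(a, cross(b, c)));
    used[f.a] = used[f.b] = used[f.c] = 1;
  }
  std::vector<int> hv;
  for (int i = 0; i < n; ++i) if (used[i]) hv.push_back(i + 1);
  return List::create(_["volume"] = vol6 / 6.0, _["area"] = area,
                      _["vertices"] = wrap(hv));
}

// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix P) {
  int n = P.nrow();
  double best = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = P(i, 0) - P(j, 0), dy = P(i, 1) - P(j, 1),
             dz = P(i, 2) - P(j, 2);
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd > best) best = dd;
    }
  return std::sqrt(best);
}
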