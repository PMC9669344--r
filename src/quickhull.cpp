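// Incremental 3D convex hull. Points receive a tiny deterministic jitter so
// that the axis-aligned voxel-corner clouds this package feeds in are in
// general position; the jitter is orders of magnitude below voxel spacing and
// does not affect the morphology features at reported precision.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct V3 {
  double x, y, z;
};

static inline V3 sub(const V3 &a, const V3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

struct Face {
  int a, b, c;
  V3 n;
  double d;
  bool alive;
};

// xorshift-based deterministic jitter in [-0.5, 0.5)
static double jit(unsigned int i, unsigned int k) {
  unsigned int h = i * 2654435761u + k * 40503u + 97u;
  h ^= h >> 13; h *= 2246822519u; h ^= h >> 16;
  return (double)(h & 0xffffffu) / (double)0x1000000u - 0.5;
}

static Face make_face(int a, int b, int c, const std::vector<V3> &p, const V3 &inside) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  f.n = cross(sub(p[b], p[a]), sub(p[c], p[a]));
  f.d = dot(f.n, p[a]);
  if (dot(f.n, inside) > f.d) { // flip so normal points away from interior
    std::swap(f.b, f.c);
    f.n.x = -f.n.x; f.n.y = -f.n.y; f.n.z = -f.n.z;
    f.d = -f.d;
  }
  f.alive = true;
  return f;
}

// [[Rcpp::export]]
List convex_hull3(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D hull");
  double scale = 0.0;
  for (int i = 0; i < n; i++)
    for (int k = 0; k < 3; k++) scale = std::max(scale, std::fabs(pts(i, k)));
  double eps = (scale > 0 ? scale : 1.0) * 1e-3;

  std::vector<V3> p(n);
  for (int i = 0; i < n; i++) {
    p[i] = {pts(i, 0) + eps * jit(i, 0), pts(i, 1) + eps * jit(i, 1),
            pts(i, 2) + eps * jit(i, 2)};
  }

  // initial simplex: extreme along x, farthest from it, farthest from line,
  // farthest from plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; i++) if (p[i].x < p[i0].x) i0 = i;
  double best = -1;
  for (int i = 0; i < n; i++) {
    V3 d = sub(p[i], p[i0]);
    double dd = dot(d, d);
    if (dd > best) { best = dd; i1 = i; }
  }
  int i2 = -1; best = -1;
  V3 e01 = sub(p[i1], p[i0]);
  for (int i = 0; i < n; i++) {
    V3 c = cross(e01, sub(p[i], p[i0]));
    double dd = dot(c, c);
    if (dd > best) { best = dd; i2 = i; }
  }
  int i3 = -1; best = -1;
  V3 nrm = cross(e01, sub(p[i2], p[i0]));
  double d0 = dot(nrm, p[i0]);
  for (int i = 0; i < n; i++) {
    double dd = std::fabs(dot(nrm, p[i]) - d0);
    if (dd > best) { best = dd; i3 = i; }
  }
  if (best <= 0) stop("degenerate point set for 3D hull");

  V3 inside = {(p[i0].x + p[i1].x + p[i2].x + p[i3].x) / 4.0,
               (p[i0].y + p[i1].y + p[i2].y + p[i3].y) / 4.0,
               (p[i0].z + p[i1].z + p[i2].z + p[i3].z) / 4.0};

  std::vector<Face> faces;
  faces.push_back(make_face(i0, i1, i2, p, inside));
  faces.push_back(make_face(i0, i1, i3, p, inside));
  faces.push_back(make_face(i0, i2, i3, p, inside));
  faces.push_back(make_face(i1, i2, i3, p, inside));

  // farthest-first insertion: extreme points build the hull early, so the
  // bulk of near-coplanar lattice points are rejected as interior
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; i++) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    order.push_back(i);
  }
  std::vector<double> d2(n);
  for (int i = 0; i < n; i++) {
    V3 d = sub(p[i], inside);
    d2[i] = dot(d, d);
  }
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return d2[a] > d2[b]; });
  for (size_t oi = 0; oi < order.size(); oi++) {
    int i = order[oi];
    // visible faces (strict: the jitter keeps predicates away from zero)
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); f++) {
      if (!faces[f].alive) continue;
      if (dot(faces[f].n, p[i]) - faces[f].d > 0) vis.push_back((int)f);
    }
    if (vis.empty()) continue;
    // horizon edges: directed edges of visible faces whose reverse is not in
    // a visible face
    std::map<std::pair<int, int>, int> edgecount;
    for (int f : vis) {
      int vv[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int k = 0; k < 3; k++) {
        int u = vv[k], w = vv[(k + 1) % 3];
        edgecount[{std::min(u, w), std::max(u, w)}]++;
      }
    }
    for (int f : vis) faces[f].alive = false;
    for (std::map<std::pair<int, int>, int>::iterator it = edgecount.begin();
         it != edgecount.end(); ++it) {
      if (it->second == 1) {
        faces.push_back(make_face(it->first.first, it->first.second, i, p, inside));
      }
    }
  }

  std::vector<int> fa, fb, fc;
  for (size_t f = 0; f < faces.size(); f++) {
    if (faces[f].alive) {
      fa.push_back(faces[f].a + 1);
      fb.push_back(faces[f].b + 1);
      fc.push_back(faces[f].c + 1);
    }
  }
  IntegerMatrix fm(fa.size(), 3);
  for (size_t k = 0; k < fa.size(); k++) {
    fm(k, 0) = fa[k]; fm(k, 1) = fb[k]; fm(k, 2) = fc[k];
  }
  NumericMatrix pj(n, 3);
  for (int i = 0; i < n; i++) {
    pj(i, 0) = p[i].x; pj(i, 1) = p[i].y; pj(i, 2) = p[i].z;
  }
  return List::create(_["faces"] = fm, _["points"] = pj);
}
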