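#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Incremental 3-D convex hull over a joggled copy of the input points,
// followed by an inside test for query points. Voxel-center point sets are
// maximally degenerate (co-planar lattices), so each point is perturbed by a
// deterministic pseudo-random offset far below the voxel pitch; the inside
// test uses a tolerance that absorbs the joggle.

namespace {

struct Face {
  int a, b, c;       // vertex indices
  double nx, ny, nz; // outward normal
  double off;        // plane offset: dot(n, x) = off
  bool alive;
};

inline double det3(double ax, double ay, double az,
                   double bx, double by, double bz,
                   double cx, double cy, double cz) {
  return ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
         az * (bx * cy - by * cx);
}

} // namespace

// [[Rcpp::export]]
List cpp_hull3d_inside(NumericMatrix pts, NumericMatrix query, double tol) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3-D hull");

  // scale for joggle/tolerance
  double scale = 0.0;
  for (int k = 0; k < 3; ++k) {
    double lo = pts(0, k), hi = pts(0, k);
    for (int i = 1; i < n; ++i) {
      lo = std::min(lo, pts(i, k));
      hi = std::max(hi, pts(i, k));
    }
    scale = std::max(scale, hi - lo);
  }
  if (scale <= 0) stop("degenerate point set (zero extent)");
  const double jog = 1e-7 * scale;

  // deterministic joggle via a fixed LCG
  std::vector<double> P(3 * (size_t)n);
  unsigned long long s = 88172645463325252ULL;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      s = s * 6364136223846793005ULL + 1442695040888963407ULL;
      double u = (double)((s >> 11) & 0xFFFFFFFFULL) / 4294967296.0;
      P[3 * (size_t)i + k] = pts(i, k) + jog * (2.0 * u - 1.0);
    }
  #define PX(i) P[3 * (size_t)(i)]
  #define PY(i) P[3 * (size_t)(i) + 1]
  #define PZ(i) P[3 * (size_t)(i) + 2]

  // initial tetrahedron: first point, farthest point, max-area third,
  // max-volume fourth
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = std::pow(PX(i) - PX(i0), 2) + std::pow(PY(i) - PY(i0), 2) +
               std::pow(PZ(i) - PZ(i0), 2);
    if (d > best) { best = d; i1 = i; }
  }
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double ux = PX(i1) - PX(i0), uy = PY(i1) - PY(i0), uz = PZ(i1) - PZ(i0);
    double vx = PX(i) - PX(i0), vy = PY(i) - PY(i0), vz = PZ(i) - PZ(i0);
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    double a2 = cx * cx + cy * cy + cz * cz;
    if (a2 > best) { best = a2; i2 = i; }
  }
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double v = std::fabs(det3(PX(i1) - PX(i0), PY(i1) - PY(i0), PZ(i1) - PZ(i0),
                              PX(i2) - PX(i0), PY(i2) - PY(i0), PZ(i2) - PZ(i0),
                              PX(i) - PX(i0), PY(i) - PY(i0), PZ(i) - PZ(i0)));
    if (v > best) { best = v; i3 = i; }
  }
  if (i3 < 0 || best < 1e-20 * scale * scale * scale)
    stop("degenerate point set (coplanar)");

  std::vector<Face> faces;
  double cx = (PX(i0) + PX(i1) + PX(i2) + PX(i3)) / 4.0;
  double cy = (PY(i0) + PY(i1) + PY(i2) + PY(i3)) / 4.0;
  double cz = (PZ(i0) + PZ(i1) + PZ(i2) + PZ(i3)) / 4.0;
  int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int f = 0; f < 4; ++f) {
    Face fc;
    fc.a = tet[f][0]; fc.b = tet[f][1]; fc.c = tet[f][2];
    double ux = PX(fc.b) - PX(fc.a), uy = PY(fc.b) - PY(fc.a), uz = PZ(fc.b) - PZ(fc.a);
    double vx = PX(fc.c) - PX(fc.a), vy = PY(fc.c) - PY(fc.a), vz = PZ(fc.c) - PZ(fc.a);
    fc.nx = uy * vz - uz * vy; fc.ny = uz * vx - ux * vz; fc.nz = ux * vy - uy * vx;
    fc.off = fc.nx * PX(fc.a) + fc.ny * PY(fc.a) + fc.nz * PZ(fc.a);
    if (fc.nx * cx + fc.ny * cy + fc.nz * cz > fc.off) { // flip outward
      std::swap(fc.b, fc.c);
      fc.nx = -fc.nx; fc.ny = -fc.ny; fc.nz = -fc.nz; fc.off = -fc.off;
    }
    fc.alive = true;
    faces.push_back(fc);
  }

  // incremental insertion
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double nrm = std::sqrt(faces[f].nx * faces[f].nx +
                             faces[f].ny * faces[f].ny +
                             faces[f].nz * faces[f].nz);
      double d = faces[f].nx * PX(i) + faces[f].ny * PY(i) +
                 faces[f].nz * PZ(i) - faces[f].off;
      if (d > 1e-12 * scale * nrm) visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    // horizon: edges used exactly once among visible faces
    std::vector<std::pair<int,int> > edges;
    for (size_t v = 0; v < visible.size(); ++v) {
      const Face &fc = faces[visible[v]];
      int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (int k = 0; k < 3; ++k) {
        bool dup = false;
        for (size_t t = 0; t < edges.size(); ++t)
          if ((edges[t].first == e[k][1] && edges[t].second == e[k][0]) ||
              (edges[t].first == e[k][0] && edges[t].second == e[k][1])) {
            edges.erase(edges.begin() + t);
            dup = true;
            break;
          }
        if (!dup) edges.push_back(std::make_pair(e[k][0], e[k][1]));
      }
    }
    for (size_t v = 0; v < visible.size(); ++v) faces[visible[v]].alive = false;
    for (size_t t = 0; t < edges.size(); ++t) {
      Face fc;
      fc.a = edges[t].first; fc.b = edges[t].second; fc.c = i;
      double ux = PX(fc.b) - PX(fc.a), uy = PY(fc.b) - PY(fc.a), uz = PZ(fc.b) - PZ(fc.a);
      double vx = PX(fc.c) - PX(fc.a), vy = PY(fc.c) - PY(fc.a), vz = PZ(fc.c) - PZ(fc.a);
      fc.nx = uy * vz - uz * vy; fc.ny = uz * vx - ux * vz; fc.nz = ux * vy - uy * vx;
      double nn = std::sqrt(fc.nx * fc.nx + fc.ny * fc.ny + fc.nz * fc.nz);
      if (nn < 1e-20) continue;
      fc.off = fc.nx * PX(fc.a) + fc.ny * PY(fc.a) + fc.nz * PZ(fc.a);
      if (fc.nx * cx + fc.ny * cy + fc.nz * cz > fc.off) {
        std::swap(fc.b, fc.c);
        fc.nx = -fc.nx; fc.ny = -fc.ny; fc.nz = -fc.nz; fc.off = -fc.off;
      }
      fc.alive = true;
      faces.push_back(fc);
    }
  }

  // hull volume (signed tetrahedra against interior centroid)
  double vol = 0.0;
  int nfaces = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    ++nfaces;
    const Face &fc = faces[f];
    vol += det3(PX(fc.a) - cx, PY(fc.a) - cy, PZ(fc.a) - cz,
                PX(fc.b) - cx, PY(fc.b) - cy, PZ(fc.b) - cz,
                PX(fc.c) - cx, PY(fc.c) - cy, PZ(fc.c) - cz);
  }
  vol = std::fabs(vol) / 6.0;

  // inside test for query points
  const int nq = query.nrow();
  LogicalVector inside(nq);
  const double eps = tol + 10.0 * jog;
  for (int q = 0; q < nq; ++q) {
    bool in = true;
    for (size_t f = 0; f < faces.size() && in; ++f) {
      if (!faces[f].alive) continue;
      double nrm = std::sqrt(faces[f].nx * faces[f].nx +
                             faces[f].ny * faces[f].ny +
                             faces[f].nz * faces[f].nz);
      double d = faces[f].nx * query(q, 0) + faces[f].ny * query(q, 1) +
                 faces[f].nz * query(q, 2) - faces[f].off;
      if (d > eps * nrm) in = false;
    }
    inside[q] = in;
  }
  #undef PX
  #undef PY
  #undef PZ
  return List::create(_["inside"] = inside, _["volume"] = vol,
                      _["n_faces"] = nfaces);
}
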