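// Geometry kernels: triangle-mesh proximity queries (closest point, signed
// distance via angle-weighted pseudo-normals, uniform-grid acceleration),
// the muscle-line wrapping relaxation, surface-constrained smoothing used by
// the geodesic straightener, and the quasi-static membrane relaxation with
// penalty contact used by the constraining sheet.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(const V3& a, double s) { return V3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }
static inline V3 unitv(const V3& a) {
  double n = norm(a);
  return n > 0 ? a * (1.0 / n) : V3(0, 0, 0);
}

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
// feature: 0,1,2 = vertices a,b,c; 3,4,5 = edges ab,bc,ca; 6 = interior.
static V3 closestPtTri(const V3& p, const V3& a, const V3& b, const V3& c, int& feature) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { feature = 0; return a; }
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { feature = 1; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    feature = 3;
    double t = d1 / (d1 - d3);
    return a + ab * t;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { feature = 2; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    feature = 5;
    double t = d2 / (d2 - d6);
    return a + ac * t;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    feature = 4;
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * t;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  feature = 6;
  return a + ab * v + ac * w;
}

struct MeshC {
  std::vector<V3> v;                 // vertices
  std::vector<int> f;                // faces, 3 per triangle (0-based)
  std::vector<V3> fnorm;             // face normals (unit)
  std::vector<V3> vnorm;             // angle-weighted vertex pseudo-normals
  std::vector<V3> enorm;             // edge pseudo-normals
  std::vector<int> fedge;            // per-face edge ids (ab, bc, ca)
  // uniform grid
  V3 gmin;
  double h;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;
  mutable std::vector<int> stamp;
  mutable int stampval;

  int ncell(int i, int j, int k) const { return (k * ny + j) * nx + i; }

  void build() {
    size_t nf = f.size() / 3;
    fnorm.assign(nf, V3());
    vnorm.assign(v.size(), V3());
    fedge.assign(nf * 3, -1);
    std::unordered_map<uint64_t, int> emap;
    std::vector<V3> esum;
    double elensum = 0.0;
    size_t ecount = 0;
    for (size_t t = 0; t < nf; ++t) {
      int ia = f[3 * t], ib = f[3 * t + 1], ic = f[3 * t + 2];
      V3 a = v[ia], b = v[ib], c = v[ic];
      V3 n = cross(b - a, c - a);
      double nn = norm(n);
      fnorm[t] = nn > 0 ? n * (1.0 / nn) : V3(0, 0, 1);
      // angle-weighted vertex normals
      int idx[3] = {ia, ib, ic};
      V3 pts[3] = {a, b, c};
      for (int k = 0; k < 3; ++k) {
        V3 e1 = unitv(pts[(k + 1) % 3] - pts[k]);
        V3 e2 = unitv(pts[(k + 2) % 3] - pts[k]);
        double ca = dot(e1, e2);
        ca = std::max(-1.0, std::min(1.0, ca));
        vnorm[idx[k]] = vnorm[idx[k]] + fnorm[t] * std::acos(ca);
      }
      for (int k = 0; k < 3; ++k) {
        int p = idx[k], q = idx[(k + 1) % 3];
        uint64_t key = p < q ? (uint64_t)p << 32 | (uint32_t)q : (uint64_t)q << 32 | (uint32_t)p;
        auto it = emap.find(key);
        int eid;
        if (it == emap.end()) {
          eid = (int)esum.size();
          emap[key] = eid;
          esum.push_back(V3());
          elensum += norm(pts[(k + 1) % 3] - pts[k]);
          ++ecount;
        } else eid = it->second;
        esum[eid] = esum[eid] + fnorm[t];
        fedge[3 * t + k] = eid;
      }
    }
    enorm = esum;
    for (auto& n : vnorm) n = unitv(n);
    for (auto& n : enorm) n = unitv(n);
    // grid
    V3 gmax;
    gmin = gmax = v.empty() ? V3() : v[0];
    for (const auto& p : v) {
      gmin.x = std::min(gmin.x, p.x); gmin.y = std::min(gmin.y, p.y); gmin.z = std::min(gmin.z, p.z);
      gmax.x = std::max(gmax.x, p.x); gmax.y = std::max(gmax.y, p.y); gmax.z = std::max(gmax.z, p.z);
    }
    double meanEdge = ecount ? elensum / ecount : 1.0;
    V3 ext = gmax - gmin;
    double diag = norm(ext);
    h = std::max(meanEdge * 1.5, diag / 48.0);
    if (h <= 0) h = 1.0;
    nx = std::max(1, std::min(64, (int)std::floor(ext.x / h) + 1));
    ny = std::max(1, std::min(64, (int)std::floor(ext.y / h) + 1));
    nz = std::max(1, std::min(64, (int)std::floor(ext.z / h) + 1));
    cells.assign((size_t)nx * ny * nz, {});
    for (size_t t = 0; t < nf; ++t) {
      V3 a = v[f[3 * t]], b = v[f[3 * t + 1]], c = v[f[3 * t + 2]];
      V3 lo(std::min({a.x, b.x, c.x}), std::min({a.y, b.y, c.y}), std::min({a.z, b.z, c.z}));
      V3 hi(std::max({a.x, b.x, c.x}), std::max({a.y, b.y, c.y}), std::max({a.z, b.z, c.z}));
      int i0 = clampi((lo.x - gmin.x) / h, nx), i1 = clampi((hi.x - gmin.x) / h, nx);
      int j0 = clampi((lo.y - gmin.y) / h, ny), j1 = clampi((hi.y - gmin.y) / h, ny);
      int k0 = clampi((lo.z - gmin.z) / h, nz), k1 = clampi((hi.z - gmin.z) / h, nz);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) cells[ncell(i, j, k)].push_back((int)t);
    }
    stamp.assign(nf, -1);
    stampval = 0;
  }

  static int clampi(double x, int n) {
    int i = (int)std::floor(x);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  }

  void testTri(const V3& p, int t, double& best2, int& bestFace, V3& bestCp, int& bestFeat) const {
    if (stamp[t] == stampval) return;
    stamp[t] = stampval;
    int feat;
    V3 cp = closestPtTri(p, v[f[3 * t]], v[f[3 * t + 1]], v[f[3 * t + 2]], feat);
    double d2 = dot(p - cp, p - cp);
    if (d2 < best2) { best2 = d2; bestFace = t; bestCp = cp; bestFeat = feat; }
  }

  // nearest point on the surface; returns face, closest point, feature.
  void nearest(const V3& p, int& face, V3& cp, int& feat) const {
    ++stampval;
    double best2 = std::numeric_limits<double>::infinity();
    face = -1; feat = 6;
    int ci = clampi((p.x - gmin.x) / h, nx);
    int cj = clampi((p.y - gmin.y) / h, ny);
    int ck = clampi((p.z - gmin.z) / h, nz);
    int rmax = nx + ny + nz;
    for (int r = 0; r <= rmax; ++r) {
      if (face >= 0) {
        // conservative shell bound: any cell at Chebyshev ring r is at least
        // (r-1)*h away from p
        double lb = (r - 1) * h;
        if (lb > 0 && lb * lb > best2) break;
      }
      bool any = false;
      int i0 = std::max(0, ci - r), i1 = std::min(nx - 1, ci + r);
      int j0 = std::max(0, cj - r), j1 = std::min(ny - 1, cj + r);
      int k0 = std::max(0, ck - r), k1 = std::min(nz - 1, ck + r);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            int cheb = std::max({std::abs(i - ci), std::abs(j - cj), std::abs(k - ck)});
            if (cheb != r) continue;
            any = true;
            for (int t : cells[ncell(i, j, k)]) testTri(p, t, best2, face, cp, feat);
          }
      if (!any && r > std::max({nx, ny, nz})) break;
    }
    if (face < 0) { // degenerate fallback: brute force
      for (size_t t = 0; t < f.size() / 3; ++t) testTri(p, (int)t, best2, face, cp, feat);
    }
  }

  // signed distance at p (outside positive); also returns outward normal at
  // the closest feature and the closest surface point.
  double signedDist(const V3& p, V3& cp, V3& nrm, int& face) const {
    int feat;
    nearest(p, face, cp, feat);
    V3 pn;
    switch (feat) {
      case 0: pn = vnorm[f[3 * face]]; break;
      case 1: pn = vnorm[f[3 * face + 1]]; break;
      case 2: pn = vnorm[f[3 * face + 2]]; break;
      case 3: pn = enorm[fedge[3 * face]]; break;
      case 4: pn = enorm[fedge[3 * face + 1]]; break;
      case 5: pn = enorm[fedge[3 * face + 2]]; break;
      default: pn = fnorm[face];
    }
    V3 d = p - cp;
    double dist = norm(d);
    double sgn = dot(d, pn) >= 0 ? 1.0 : -1.0;
    nrm = dist > 1e-12 ? d * (sgn / dist) : pn;
    return sgn * dist;
  }
};

struct Pose { // rigid transform world <- local
  double R[9]; // row-major rotation
  V3 t;
  bool identity;
  V3 toLocal(const V3& p) const {
    if (identity) return p;
    V3 q = p - t;
    return V3(R[0] * q.x + R[3] * q.y + R[6] * q.z,
              R[1] * q.x + R[4] * q.y + R[7] * q.z,
              R[2] * q.x + R[5] * q.y + R[8] * q.z);
  }
  V3 toWorld(const V3& p) const {
    if (identity) return p;
    return V3(R[0] * p.x + R[1] * p.y + R[2] * p.z + t.x,
              R[3] * p.x + R[4] * p.y + R[5] * p.z + t.y,
              R[6] * p.x + R[7] * p.y + R[8] * p.z + t.z);
  }
  V3 rotWorld(const V3& p) const {
    if (identity) return p;
    return V3(R[0] * p.x + R[1] * p.y + R[2] * p.z,
              R[3] * p.x + R[4] * p.y + R[5] * p.z,
              R[6] * p.x + R[7] * p.y + R[8] * p.z);
  }
};

static Pose poseFromMatrix(const NumericMatrix& T) {
  Pose P;
  P.identity = true;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      P.R[3 * i + j] = T(i, j);
      if (std::fabs(T(i, j) - (i == j ? 1.0 : 0.0)) > 1e-15) P.identity = false;
    }
  P.t = V3(T(0, 3), T(1, 3), T(2, 3));
  if (std::fabs(P.t.x) + std::fabs(P.t.y) + std::fabs(P.t.z) > 1e-15) P.identity = false;
  return P;
}

struct Obstacle {
  const MeshC* mesh;
  Pose pose;
};

static std::vector<Obstacle> unpackObstacles(List obstacles) {
  std::vector<Obstacle> out;
  for (int i = 0; i < obstacles.size(); ++i) {
    List o = obstacles[i];
    XPtr<MeshC> ptr = o["ptr"];
    Obstacle ob;
    ob.mesh = ptr.get();
    ob.pose = poseFromMatrix(as<NumericMatrix>(o["pose"]));
    out.push_back(ob);
  }
  return out;
}

// [[Rcpp::export(name = ".mw_mesh_build")]]
SEXP mw_mesh_build(NumericMatrix vertices, IntegerMatrix faces) {
  XPtr<MeshC> ptr(new MeshC(), true);
  size_t nv = vertices.nrow(), nf = faces.nrow();
  ptr->v.resize(nv);
  for (size_t i = 0; i < nv; ++i) ptr->v[i] = V3(vertices(i, 0), vertices(i, 1), vertices(i, 2));
  ptr->f.resize(nf * 3);
  for (size_t t = 0; t < nf; ++t)
    for (int k = 0; k < 3; ++k) ptr->f[3 * t + k] = faces(t, k) - 1;
  ptr->build();
  return ptr;
}

// [[Rcpp::export(name = ".mw_xptr_valid")]]
bool mw_xptr_valid(SEXP p) {
  return TYPEOF(p) == EXTPTRSXP && R_ExternalPtrAddr(p) != nullptr;
}

// Closest point / signed distance queries for a block of world-space points.
// [[Rcpp::export(name = ".mw_mesh_query")]]
List mw_mesh_query(SEXP meshPtr, NumericMatrix points, NumericMatrix pose) {
  XPtr<MeshC> m(meshPtr);
  Pose P = poseFromMatrix(pose);
  int n = points.nrow();
  NumericVector sd(n);
  NumericMatrix cp(n, 3), nrm(n, 3);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    V3 p(points(i, 0), points(i, 1), points(i, 2));
    V3 pl = P.toLocal(p), c, nn;
    int fc;
    sd[i] = m->signedDist(pl, c, nn, fc);
    V3 cw = P.toWorld(c), nw = P.rotWorld(nn);
    cp(i, 0) = cw.x; cp(i, 1) = cw.y; cp(i, 2) = cw.z;
    nrm(i, 0) = nw.x; nrm(i, 1) = nw.y; nrm(i, 2) = nw.z;
    face[i] = fc + 1;
  }
  return List::create(_["sdist"] = sd, _["closest"] = cp, _["normal"] = nrm, _["face"] = face);
}

// Closest point on surface with barycentric coordinates (unsigned; used for
// binding muscle-line nodes to the sheet).
// [[Rcpp::export(name = ".mw_mesh_project")]]
List mw_mesh_project(SEXP meshPtr, NumericMatrix points) {
  XPtr<MeshC> m(meshPtr);
  int n = points.nrow();
  NumericMatrix cp(n, 3), bary(n, 3);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    V3 p(points(i, 0), points(i, 1), points(i, 2)), c;
    int fc, feat;
    m->nearest(p, fc, c, feat);
    cp(i, 0) = c.x; cp(i, 1) = c.y; cp(i, 2) = c.z;
    face[i] = fc + 1;
    // barycentric of c in face fc
    V3 a = m->v[m->f[3 * fc]], b = m->v[m->f[3 * fc + 1]], cc = m->v[m->f[3 * fc + 2]];
    V3 v0 = b - a, v1 = cc - a, v2 = c - a;
    double d00 = dot(v0, v0), d01 = dot(v0, v1), d11 = dot(v1, v1);
    double d20 = dot(v2, v0), d21 = dot(v2, v1);
    double den = d00 * d11 - d01 * d01;
    double bv = den != 0 ? (d11 * d20 - d01 * d21) / den : 0.0;
    double bw = den != 0 ? (d00 * d21 - d01 * d20) / den : 0.0;
    bary(i, 0) = 1.0 - bv - bw; bary(i, 1) = bv; bary(i, 2) = bw;
  }
  return List::create(_["closest"] = cp, _["face"] = face, _["bary"] = bary);
}

// Muscle-line wrapping: sequential sweeps moving each interior node toward
// the average of its neighbours (optionally over-relaxed), then projecting
// back outside the obstacles. Far-from-surface nodes reuse cached signed
// distances: a node that moved d since its last query against an obstacle
// is at least (cached sd - d) away from it, so the query can be skipped
// while that bound stays clear of the contact offset.
// [[Rcpp::export(name = ".mw_wrap_solve")]]
List mw_wrap_solve(NumericMatrix nodes, List obstacles, double lineRadius,
                   int maxIter, double tol, double omega = 1.0) {
  std::vector<Obstacle> obs = unpackObstacles(obstacles);
  int n = nodes.nrow();
  size_t no = obs.size();
  std::vector<V3> p(n);
  for (int i = 0; i < n; ++i) p[i] = V3(nodes(i, 0), nodes(i, 1), nodes(i, 2));
  std::vector<V3> cachePos(n * no);
  std::vector<double> cacheSd(n * no, -1e30); // force initial queries
  const double safety = 0.5;
  auto resolve = [&](V3 q, int i) {
    for (int sub = 0; sub < 5; ++sub) {
      int worst = -1;
      double worstPen = 0.0;
      V3 worstCp, worstN;
      for (size_t o = 0; o < no; ++o) {
        size_t ci = i * no + o;
        double bound = cacheSd[ci] - norm(q - cachePos[ci]);
        if (bound > lineRadius + safety) continue;
        V3 pl = obs[o].pose.toLocal(q), c, nn;
        int fc;
        double sd = obs[o].mesh->signedDist(pl, c, nn, fc);
        cacheSd[ci] = sd;
        cachePos[ci] = q;
        double pen = lineRadius - sd;
        if (pen > worstPen + 1e-15) {
          worstPen = pen;
          worst = (int)o;
          worstCp = obs[o].pose.toWorld(c);
          worstN = obs[o].pose.rotWorld(nn);
        }
      }
      if (worst < 0 || worstPen <= 1e-12) break;
      q = worstCp + worstN * lineRadius;
      size_t ci = i * no + worst;
      cacheSd[ci] = lineRadius;
      cachePos[ci] = q;
    }
    return q;
  };
  double maxDisp = R_PosInf;
  int it = 0;
  for (it = 0; it < maxIter; ++it) {
    maxDisp = 0.0;
    for (int i = 1; i < n - 1; ++i) {
      V3 target = (p[i - 1] + p[i + 1]) * 0.5;
      if (omega != 1.0) target = p[i] + (target - p[i]) * omega;
      if (!obs.empty()) target = resolve(target, i);
      double d = norm(target - p[i]);
      if (d > maxDisp) maxDisp = d;
      p[i] = target;
    }
    if (maxDisp < tol) { ++it; break; }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = p[i].x; out(i, 1) = p[i].y; out(i, 2) = p[i].z; }
  return List::create(_["nodes"] = out, _["iterations"] = it,
                      _["converged"] = maxDisp < tol, _["max_disp"] = maxDisp);
}

// Surface-constrained smoothing for geodesic straightening: every interior
// node is moved toward the neighbour average and projected onto the surface.
// [[Rcpp::export(name = ".mw_surface_smooth")]]
NumericMatrix mw_surface_smooth(NumericMatrix nodes, SEXP meshPtr, int maxIter, double tol) {
  XPtr<MeshC> m(meshPtr);
  int n = nodes.nrow();
  std::vector<V3> p(n);
  for (int i = 0; i < n; ++i) p[i] = V3(nodes(i, 0), nodes(i, 1), nodes(i, 2));
  for (int it = 0; it < maxIter; ++it) {
    double maxDisp = 0.0;
    for (int i = 1; i < n - 1; ++i) {
      V3 target = (p[i - 1] + p[i + 1]) * 0.5;
      V3 c;
      int fc, feat;
      m->nearest(target, fc, c, feat);
      double d = norm(c - p[i]);
      if (d > maxDisp) maxDisp = d;
      p[i] = c;
    }
    if (maxDisp < tol) break;
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = p[i].x; out(i, 1) = p[i].y; out(i, 2) = p[i].z; }
  return out;
}

// Membrane energy, gradient and PSD-projected Hessian triplets: edge
// springs (structural + shear) with a quadratic penalty on penetration into
// the obstacles. The spring Hessian block is k [ d d^T + max(0, 1 - l0/l)
// (I - d d^T) ] (transverse curvature clamped to keep the system positive
// semi-definite); the contact Hessian is kContact n n^T on penetrating
// nodes. Triplets cover the full symmetric 3n x 3n matrix.
// [[Rcpp::export(name = ".mw_sheet_energy")]]
List mw_sheet_energy(NumericMatrix positions, IntegerVector si, IntegerVector sj,
                     NumericVector l0, NumericVector kspring,
                     List obstacles, double kContact, bool hessian = false) {
  std::vector<Obstacle> obs = unpackObstacles(obstacles);
  int n = positions.nrow(), ns = si.size();
  std::vector<V3> x(n);
  for (int i = 0; i < n; ++i) x[i] = V3(positions(i, 0), positions(i, 1), positions(i, 2));
  std::vector<V3> g(n);
  double E = 0.0, maxPen = 0.0;
  std::vector<int> hi, hj;
  std::vector<double> hv;
  if (hessian) { hi.reserve(ns * 36 + n * 9); hj.reserve(ns * 36 + n * 9); hv.reserve(ns * 36 + n * 9); }
  auto addBlock = [&](int a, int b, const double B[9], double sgn) {
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) {
        hi.push_back(3 * a + r + 1);
        hj.push_back(3 * b + c + 1);
        hv.push_back(sgn * B[3 * r + c]);
      }
  };
  for (int s = 0; s < ns; ++s) {
    int a = si[s] - 1, b = sj[s] - 1;
    V3 d = x[b] - x[a];
    double l = norm(d);
    double dl = l - l0[s];
    E += 0.5 * kspring[s] * dl * dl;
    if (l > 1e-12) {
      V3 u = d * (1.0 / l);
      V3 fg = u * (kspring[s] * dl);
      g[a] = g[a] - fg;
      g[b] = g[b] + fg;
      if (hessian) {
        double ct = kspring[s] * std::max(0.0, 1.0 - l0[s] / l);
        double uu[3] = {u.x, u.y, u.z};
        double B[9];
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c)
            B[3 * r + c] = kspring[s] * uu[r] * uu[c] +
              ct * ((r == c ? 1.0 : 0.0) - uu[r] * uu[c]);
        addBlock(a, a, B, 1.0);
        addBlock(b, b, B, 1.0);
        addBlock(a, b, B, -1.0);
        addBlock(b, a, B, -1.0);
      }
    }
  }
  LogicalVector active(n, false);
  if (kContact > 0 && !obs.empty()) {
    for (int i = 0; i < n; ++i) {
      for (size_t o = 0; o < obs.size(); ++o) {
        V3 pl = obs[o].pose.toLocal(x[i]), c, nn;
        int fc;
        double sd = obs[o].mesh->signedDist(pl, c, nn, fc);
        if (sd < 0) {
          double pen = -sd;
          if (pen > maxPen) maxPen = pen;
          E += 0.5 * kContact * pen * pen;
          V3 nw = obs[o].pose.rotWorld(nn);
          g[i] = g[i] - nw * (kContact * pen);
          active[i] = true;
          if (hessian) {
            double uu[3] = {nw.x, nw.y, nw.z};
            double B[9];
            for (int r = 0; r < 3; ++r)
              for (int c = 0; c < 3; ++c)
                B[3 * r + c] = kContact * uu[r] * uu[c];
            addBlock(i, i, B, 1.0);
          }
        }
      }
    }
  }
  NumericMatrix gout(n, 3);
  for (int i = 0; i < n; ++i) { gout(i, 0) = g[i].x; gout(i, 1) = g[i].y; gout(i, 2) = g[i].z; }
  List out = List::create(_["energy"] = E, _["grad"] = gout,
                          _["max_penetration"] = maxPen, _["active"] = active);
  if (hessian) {
    out["hi"] = IntegerVector(hi.begin(), hi.end());
    out["hj"] = IntegerVector(hj.begin(), hj.end());
    out["hv"] = NumericVector(hv.begin(), hv.end());
  }
  return out;
}

// Segment-triangle intersection (Moller-Trumbore), strict interior hits.
static bool segTri(const V3& p, const V3& q, const V3& a, const V3& b, const V3& c) {
  V3 d = q - p, e1 = b - a, e2 = c - a;
  V3 h = cross(d, e2);
  double det = dot(e1, h);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  V3 s = p - a;
  double u = dot(s, h) * inv;
  if (u < 1e-9 || u > 1 - 1e-9) return false;
  V3 qv = cross(s, e1);
  double v = dot(d, qv) * inv;
  if (v < 1e-9 || u + v > 1 - 1e-9) return false;
  double t = dot(e2, qv) * inv;
  return t > 1e-9 && t < 1 - 1e-9;
}

// Self-intersection flags per face: an edge of one face passes through the
// interior of another, vertex-disjoint face.
// [[Rcpp::export(name = ".mw_self_intersect")]]
LogicalVector mw_self_intersect(NumericMatrix vertices, IntegerMatrix faces) {
  int nv = vertices.nrow(), nf = faces.nrow();
  std::vector<V3> v(nv);
  for (int i = 0; i < nv; ++i) v[i] = V3(vertices(i, 0), vertices(i, 1), vertices(i, 2));
  LogicalVector flag(nf, false);
  for (int t = 0; t < nf; ++t) {
    int ta = faces(t, 0) - 1, tb = faces(t, 1) - 1, tc = faces(t, 2) - 1;
    for (int s = 0; s < nf; ++s) {
      if (s == t) continue;
      int sa = faces(s, 0) - 1, sb = faces(s, 1) - 1, sc = faces(s, 2) - 1;
      if (sa == ta || sa == tb || sa == tc || sb == ta || sb == tb || sb == tc ||
          sc == ta || sc == tb || sc == tc) continue;
      int ev[6] = {sa, sb, sb, sc, sc, sa};
      for (int e = 0; e < 3; ++e) {
        if (segTri(v[ev[2 * e]], v[ev[2 * e + 1]], v[ta], v[tb], v[tc])) {
          flag[t] = true;
          flag[s] = true;
          break;
        }
      }
      if (flag[t]) break;
    }
  }
  return flag;
}
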