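#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <limits>
using namespace Rcpp;

// Mesh geometry kernels: nearest-vertex queries on a uniform spatial hash,
// point-to-triangle projection restricted to triangles near the closest
// vertices (valid for the densely triangulated smooth shells produced by
// isosurfacing), and line-mesh intersection by Moller-Trumbore.

namespace {

struct VertexGrid {
  double cell, x0, y0, z0;
  int nx, ny, nz;
  std::vector<std::vector<int>> bins;
  const double *V; int nv;

  void build(const double *verts, int n, double cell_size) {
    V = verts; nv = n; cell = cell_size;
    double xmax = -1e300, ymax = -1e300, zmax = -1e300;
    x0 = y0 = z0 = 1e300;
    for (int i = 0; i < n; ++i) {
      x0 = std::min(x0, V[i]); xmax = std::max(xmax, V[i]);
      y0 = std::min(y0, V[i + nv]); ymax = std::max(ymax, V[i + nv]);
      z0 = std::min(z0, V[i + 2 * nv]); zmax = std::max(zmax, V[i + 2 * nv]);
    }
    nx = std::max(1, (int)((xmax - x0) / cell) + 1);
    ny = std::max(1, (int)((ymax - y0) / cell) + 1);
    nz = std::max(1, (int)((zmax - z0) / cell) + 1);
    bins.assign((size_t)nx * ny * nz, {});
    for (int i = 0; i < n; ++i) {
      int cx = (int)((V[i] - x0) / cell), cy = (int)((V[i + nv] - y0) / cell),
          cz = (int)((V[i + 2 * nv] - z0) / cell);
      bins[cx + nx * (cy + (size_t)ny * cz)].push_back(i);
    }
  }

  int nearest(double px, double py, double pz) const {
    int cx = (int)std::floor((px - x0) / cell), cy = (int)std::floor((py - y0) / cell),
        cz = (int)std::floor((pz - z0) / cell);
    int best = -1; double bestd = std::numeric_limits<double>::max();
    for (int r = 0;; ++r) {
      bool looked = false;
      for (int dz = -r; dz <= r; ++dz)
        for (int dy = -r; dy <= r; ++dy)
          for (int dx = -r; dx <= r; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r) continue;
            int gx = cx + dx, gy = cy + dy, gz = cz + dz;
            if (gx < 0 || gy < 0 || gz < 0 || gx >= nx || gy >= ny || gz >= nz) continue;
            looked = true;
            for (int i : bins[gx + nx * (gy + (size_t)ny * gz)]) {
              double ddx = V[i] - px, ddy = V[i + nv] - py, ddz = V[i + 2 * nv] - pz;
              double d = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d < bestd) { bestd = d; best = i; }
            }
          }
      // safe stop: nothing beyond ring r can beat current best
      if (best >= 0 && (double)(r)*cell >= std::sqrt(bestd)) break;
      if (!looked && r > std::max(nx, std::max(ny, nz))) break;
    }
    return best;
  }
};

// closest point on triangle abc to p (Ericson, Real-Time Collision Detection)
inline void closest_on_tri(const double *p, const double *a, const double *b,
                           const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; return; }
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i]=a[i]+v*ab[i]; return;
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i]=a[i]+w*ac[i]; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i]=b[i]+w*(c[i]-b[i]); return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i]=a[i]+ab[i]*v+ac[i]*w;
}

} // namespace

// [[Rcpp::export]]
IntegerVector nearest_vertex_cpp(NumericMatrix query, NumericMatrix verts) {
  VertexGrid g;
  std::vector<double> vflat(verts.begin(), verts.end());
  double span = 0;
  for (int d = 0; d < 3; ++d) {
    double mn = 1e300, mx = -1e300;
    for (int i = 0; i < verts.nrow(); ++i) { mn = std::min(mn, verts(i,d)); mx = std::max(mx, verts(i,d)); }
    span = std::max(span, mx - mn);
  }
  double cell = std::max(1e-6, span / std::max(4.0, std::cbrt((double)verts.nrow())));
  g.build(vflat.data(), verts.nrow(), cell);
  IntegerVector out(query.nrow());
  for (int q = 0; q < query.nrow(); ++q)
    out[q] = g.nearest(query(q,0), query(q,1), query(q,2)) + 1;
  return out;
}

// Project points onto mesh surface: nearest vertex via hash grid, then exact
// point-triangle distance over triangles incident to that vertex's two-ring.
// [[Rcpp::export]]
List project_points_cpp(NumericMatrix query, NumericMatrix verts, IntegerMatrix tris) {
  int nv = verts.nrow(), nt = tris.nrow(), nq = query.nrow();
  // vertex -> incident triangles
  std::vector<std::vector<int>> vtri(nv);
  std::vector<std::vector<int>> vadj(nv);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 3; ++c) {
      int v = tris(t,c) - 1;
      vtri[v].push_back(t);
      vadj[v].push_back(tris(t,(c+1)%3) - 1);
      vadj[v].push_back(tris(t,(c+2)%3) - 1);
    }
  VertexGrid g;
  std::vector<double> vflat(verts.begin(), verts.end());
  double span = 0;
  for (int d = 0; d < 3; ++d) {
    double mn = 1e300, mx = -1e300;
    for (int i = 0; i < nv; ++i) { mn = std::min(mn, verts(i,d)); mx = std::max(mx, verts(i,d)); }
    span = std::max(span, mx - mn);
  }
  double cell = std::max(1e-6, span / std::max(4.0, std::cbrt((double)nv)));
  g.build(vflat.data(), nv, cell);

  NumericMatrix proj(nq, 3);
  NumericVector dist(nq);
  std::vector<char> seen(nt, 0);
  std::vector<int> touched;
  for (int q = 0; q < nq; ++q) {
    double p[3] = {query(q,0), query(q,1), query(q,2)};
    int v0 = g.nearest(p[0], p[1], p[2]);
    touched.clear();
    double best = std::numeric_limits<double>::max();
    double bp[3] = {verts(v0,0), verts(v0,1), verts(v0,2)};
    // candidate triangles: incident to v0 and its one-ring neighbours
    auto consider_vertex = [&](int v) {
      for (int t : vtri[v]) {
        if (seen[t]) continue;
        seen[t] = 1; touched.push_back(t);
        int a = tris(t,0)-1, b = tris(t,1)-1, c = tris(t,2)-1;
        double pa[3] = {verts(a,0), verts(a,1), verts(a,2)};
        double pb[3] = {verts(b,0), verts(b,1), verts(b,2)};
        double pc[3] = {verts(c,0), verts(c,1), verts(c,2)};
        double cp[3];
        closest_on_tri(p, pa, pb, pc, cp);
        double d = 0; for (int i=0;i<3;++i) { double e = p[i]-cp[i]; d += e*e; }
        if (d < best) { best = d; for (int i=0;i<3;++i) bp[i]=cp[i]; }
      }
    };
    consider_vertex(v0);
    for (int v : vadj[v0]) consider_vertex(v);
    for (int t : touched) seen[t] = 0;
    for (int i = 0; i < 3; ++i) proj(q,i) = bp[i];
    dist[q] = std::sqrt(best == std::numeric_limits<double>::max() ? 0 : best);
  }
  return List::create(_["points"] = proj, _["distance"] = dist);
}

// Line-mesh intersection: for each origin/direction, the intersection point
// with smallest |t| along the (two-sided) line. Returns t = NA when the line
// misses every triangle.
// [[Rcpp::export]]
List line_mesh_intersect_cpp(NumericMatrix origins, NumericMatrix dirs,
                             NumericMatrix verts, IntegerMatrix tris) {
  int nq = origins.nrow(), nt = tris.nrow();
  NumericVector tout(nq, NA_REAL);
  NumericMatrix hit(nq, 3);
  std::fill(hit.begin(), hit.end(), NA_REAL);
  const double EPS = 1e-12;
  for (int q = 0; q < nq; ++q) {
    double o[3] = {origins(q,0), origins(q,1), origins(q,2)};
    double d[3] = {dirs(q,0), dirs(q,1), dirs(q,2)};
    double best = std::numeric_limits<double>::max(); bool found = false; double bt = 0;
    for (int t = 0; t < nt; ++t) {
      int ia = tris(t,0)-1, ib = tris(t,1)-1, ic = tris(t,2)-1;
      double e1[3], e2[3], tv[3], pv[3], qv[3];
      for (int i=0;i<3;++i) { e1[i]=verts(ib,i)-verts(ia,i); e2[i]=verts(ic,i)-verts(ia,i); }
      pv[0]=d[1]*e2[2]-d[2]*e2[1]; pv[1]=d[2]*e2[0]-d[0]*e2[2]; pv[2]=d[0]*e2[1]-d[1]*e2[0];
      double det = e1[0]*pv[0]+e1[1]*pv[1]+e1[2]*pv[2];
      if (std::abs(det) < EPS) continue;
      double inv = 1.0/det;
      for (int i=0;i<3;++i) tv[i]=o[i]-verts(ia,i);
      double u = (tv[0]*pv[0]+tv[1]*pv[1]+tv[2]*pv[2]) * inv;
      if (u < -1e-9 || u > 1+1e-9) continue;
      qv[0]=tv[1]*e1[2]-tv[2]*e1[1]; qv[1]=tv[2]*e1[0]-tv[0]*e1[2]; qv[2]=tv[0]*e1[1]-tv[1]*e1[0];
      double v = (d[0]*qv[0]+d[1]*qv[1]+d[2]*qv[2]) * inv;
      if (v < -1e-9 || u + v > 1+1e-9) continue;
      double tt = (e2[0]*qv[0]+e2[1]*qv[1]+e2[2]*qv[2]) * inv;
      if (std::abs(tt) < best) { best = std::abs(tt); bt = tt; found = true; }
    }
    if (found) {
      tout[q] = bt;
      for (int i=0;i<3;++i) hit(q,i) = o[i] + bt * d[i];
    }
  }
  return List::create(_["t"] = tout, _["point"] = hit);
}

// area-weighted vertex normals (orientation from triangle winding)
// [[Rcpp::export]]
NumericMatrix vertex_normals_cpp(NumericMatrix verts, IntegerMatrix tris) {
  int nv = verts.nrow(), nt = tris.nrow();
  NumericMatrix N(nv, 3);
  for (int t = 0; t < nt; ++t) {
    int a = tris(t,0)-1, b = tris(t,1)-1, c = tris(t,2)-1;
    double u[3], v[3], n[3];
    for (int i=0;i<3;++i) { u[i]=verts(b,i)-verts(a,i); v[i]=verts(c,i)-verts(a,i); }
    n[0]=u[1]*v[2]-u[2]*v[1]; n[1]=u[2]*v[0]-u[0]*v[2]; n[2]=u[0]*v[1]-u[1]*v[0];
    for (int i=0;i<3;++i) { N(a,i)+=n[i]; N(b,i)+=n[i]; N(c,i)+=n[i]; }
  }
  for (int p = 0; p < nv; ++p) {
    double len = std::sqrt(N(p,0)*N(p,0)+N(p,1)*N(p,1)+N(p,2)*N(p,2));
    if (len > 0) for (int i=0;i<3;++i) N(p,i) /= len;
  }
  return N;
}
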