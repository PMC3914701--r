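#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction on a regular grid by tetrahedral decomposition of
// each voxel cell (six tetrahedra sharing the main diagonal, so face
// diagonals agree between neighbouring cells and the mesh is watertight
// whenever the level set does not touch the grid boundary).

namespace {

struct MeshAcc {
  std::vector<double> pts;                  // flat xyz
  std::vector<int> tris;                    // flat 0-based
  std::map<std::pair<long long, long long>, int> edge_vertex;
};

inline long long lin(int i, int j, int k, int nx, int ny) {
  return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
}

// interpolated vertex on grid edge (a,b); coordinates in voxel index units
int edge_point(MeshAcc &m, long long ia, long long ib,
               const double *pa, const double *pb,
               double va, double vb, double iso) {
  std::pair<long long, long long> key = ia < ib ? std::make_pair(ia, ib)
                                                : std::make_pair(ib, ia);
  auto it = m.edge_vertex.find(key);
  if (it != m.edge_vertex.end()) return it->second;
  double t = (iso - va) / (vb - va);
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  int idx = (int)(m.pts.size() / 3);
  for (int d = 0; d < 3; ++d) m.pts.push_back(pa[d] + t * (pb[d] - pa[d]));
  m.edge_vertex[key] = idx;
  return idx;
}

void add_tri(MeshAcc &m, int a, int b, int c, const double *inside_ref) {
  // orient so the normal points away from the inside reference point
  const double *pa = &m.pts[3 * a], *pb = &m.pts[3 * b], *pc = &m.pts[3 * c];
  double u[3], v[3], n[3], w[3];
  for (int d = 0; d < 3; ++d) { u[d] = pb[d] - pa[d]; v[d] = pc[d] - pa[d]; }
  n[0] = u[1] * v[2] - u[2] * v[1];
  n[1] = u[2] * v[0] - u[0] * v[2];
  n[2] = u[0] * v[1] - u[1] * v[0];
  for (int d = 0; d < 3; ++d) w[d] = pa[d] - inside_ref[d];
  double dot = n[0] * w[0] + n[1] * w[1] + n[2] * w[2];
  if (dot < 0) std::swap(b, c);
  m.tris.push_back(a); m.tris.push_back(b); m.tris.push_back(c);
}

} // namespace

// [[Rcpp::export]]
List march_tetrahedra_cpp(NumericVector values, IntegerVector dims,
                          double iso, NumericVector spacing,
                          NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *val = values.begin();
  MeshAcc m;

  // cube corner offsets, main diagonal 0-6
  static const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double cv[8]; long long cid[8]; double cp[8][3];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + co[c][0], cj = j + co[c][1], ck = k + co[c][2];
          cid[c] = lin(ci, cj, ck, nx, ny);
          cv[c] = val[cid[c]];
          cp[c][0] = ci; cp[c][1] = cj; cp[c][2] = ck;
          (cv[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int vi[4]; int nin = 0;
          int ins[4], outs[4]; int no = 0;
          for (int c = 0; c < 4; ++c) {
            vi[c] = tets[t][c];
            if (cv[vi[c]] > iso) ins[nin++] = vi[c]; else outs[no++] = vi[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int A = ins[0];
            int p1 = edge_point(m, cid[A], cid[outs[0]], cp[A], cp[outs[0]], cv[A], cv[outs[0]], iso);
            int p2 = edge_point(m, cid[A], cid[outs[1]], cp[A], cp[outs[1]], cv[A], cv[outs[1]], iso);
            int p3 = edge_point(m, cid[A], cid[outs[2]], cp[A], cp[outs[2]], cv[A], cv[outs[2]], iso);
            add_tri(m, p1, p2, p3, cp[A]);
          } else if (nin == 3) {
            int D = outs[0];
            int p1 = edge_point(m, cid[ins[0]], cid[D], cp[ins[0]], cp[D], cv[ins[0]], cv[D], iso);
            int p2 = edge_point(m, cid[ins[1]], cid[D], cp[ins[1]], cp[D], cv[ins[1]], cv[D], iso);
            int p3 = edge_point(m, cid[ins[2]], cid[D], cp[ins[2]], cp[D], cv[ins[2]], cv[D], iso);
            double ref[3];
            for (int d = 0; d < 3; ++d)
              ref[d] = (cp[ins[0]][d] + cp[ins[1]][d] + cp[ins[2]][d]) / 3.0;
            add_tri(m, p1, p2, p3, ref);
          } else { // nin == 2
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int pac = edge_point(m, cid[A], cid[C], cp[A], cp[C], cv[A], cv[C], iso);
            int pad = edge_point(m, cid[A], cid[D], cp[A], cp[D], cv[A], cv[D], iso);
            int pbc = edge_point(m, cid[B], cid[C], cp[B], cp[C], cv[B], cv[C], iso);
            int pbd = edge_point(m, cid[B], cid[D], cp[B], cp[D], cv[B], cv[D], iso);
            double ref[3];
            for (int d = 0; d < 3; ++d) ref[d] = 0.5 * (cp[A][d] + cp[B][d]);
            add_tri(m, pac, pad, pbd, ref);
            add_tri(m, pac, pbd, pbc, ref);
          }
        }
      }

  int np = (int)(m.pts.size() / 3), nt = (int)(m.tris.size() / 3);
  NumericMatrix P(np, 3);
  for (int p = 0; p < np; ++p)
    for (int d = 0; d < 3; ++d)
      P(p, d) = origin[d] + m.pts[3 * p + d] * spacing[d];
  IntegerMatrix T(nt, 3);
  for (int t = 0; t < nt; ++t)
    for (int d = 0; d < 3; ++d)
      T(t, d) = m.tris[3 * t + d] + 1; // 1-based for R
  return List::create(_["points"] = P, _["triangles"] = T);
}

// Taubin lambda|mu smoothing: shrink-free alternative to plain Laplacian
// relaxation, used to damp the voxelization ripple of binary isosurfaces.
// [[Rcpp::export]]
NumericMatrix taubin_smooth_cpp(NumericMatrix points, IntegerMatrix tris,
                                int iterations, double lambda, double mu) {
  int np = points.nrow(), nt = tris.nrow();
  std::vector<std::vector<int>> adj(np);
  for (int t = 0; t < nt; ++t) {
    int a = tris(t, 0) - 1, b = tris(t, 1) - 1, c = tris(t, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int p = 0; p < np; ++p) {
    std::sort(adj[p].begin(), adj[p].end());
    adj[p].erase(std::unique(adj[p].begin(), adj[p].end()), adj[p].end());
  }
  NumericMatrix cur = clone(points);
  NumericMatrix nxt(np, 3);
  double steps[2] = {lambda, mu};
  for (int it = 0; it < iterations; ++it) {
    for (int s = 0; s < 2; ++s) {
      double step = steps[s];
      for (int p = 0; p < np; ++p) {
        if (adj[p].empty()) {
          for (int d = 0; d < 3; ++d) nxt(p, d) = cur(p, d);
          continue;
        }
        for (int d = 0; d < 3; ++d) {
          double mean = 0;
          for (int q : adj[p]) mean += cur(q, d);
          mean /= (double)adj[p].size();
          nxt(p, d) = cur(p, d) + step * (mean - cur(p, d));
        }
      }
      std::swap(cur, nxt);
    }
  }
  return cur;
}
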