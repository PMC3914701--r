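#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Patch-based multi-atlas label fusion: exhaustive windowed search.
// Atlas volumes are pre-resampled onto the target grid; for every target
// voxel, every displacement within the search window yields one candidate
// atlas patch per atlas, weighted by
//   w = exp(-SSD / (h^2 * n_overlap)) * exp(-|offset_mm|^2 / s^2).
// The n_best heaviest candidates per atlas vote for the label at the atlas
// patch centre; the fused label is the weight-argmax with ties broken toward
// the lower label code. Deterministic: candidates scanned in fixed z,y,x
// order and selected by stable sort on weight.

namespace {
struct Cand { double w; int ord; int label; };
}

// [[Rcpp::export]]
IntegerVector fuse_labels_cpp(NumericVector target, IntegerVector dims,
                              List atlas_intensity, List atlas_labels,
                              IntegerVector patch_r, IntegerVector search_r,
                              int n_best, double h2, double s2,
                              NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  int natl = atlas_intensity.size();
  std::vector<const double*> AI(natl);
  std::vector<const int*> AL(natl);
  for (int a = 0; a < natl; ++a) {
    NumericVector ai = atlas_intensity[a];
    IntegerVector al = atlas_labels[a];
    AI[a] = ai.begin(); AL[a] = al.begin();
  }
  const double *T = target.begin();
  IntegerVector out((R_xlen_t)nvox);
  int prx = patch_r[0], pry = patch_r[1], prz = patch_r[2];
  int srx = search_r[0], sry = search_r[1], srz = search_r[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  std::vector<Cand> cands;
  cands.reserve((2*srx+1)*(2*sry+1)*(2*srz+1));

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double wlab[4] = {0, 0, 0, 0};
        bool any = false;
        for (int a = 0; a < natl; ++a) {
          cands.clear();
          int ord = 0;
          for (int dz = -srz; dz <= srz; ++dz)
            for (int dy = -sry; dy <= sry; ++dy)
              for (int dx = -srx; dx <= srx; ++dx, ++ord) {
                int ci = i + dx, cj = j + dy, ck = k + dz;
                if (ci < 0 || cj < 0 || ck < 0 || ci >= nx || cj >= ny || ck >= nz)
                  continue;
                // patch SSD over voxels valid in both patches
                double ssd = 0; int n = 0;
                for (int pz = -prz; pz <= prz; ++pz) {
                  int tk = k + pz, ak = ck + pz;
                  if (tk < 0 || ak < 0 || tk >= nz || ak >= nz) continue;
                  for (int py = -pry; py <= pry; ++py) {
                    int tj = j + py, aj = cj + py;
                    if (tj < 0 || aj < 0 || tj >= ny || aj >= ny) continue;
                    for (int px = -prx; px <= prx; ++px) {
                      int ti = i + px, ai = ci + px;
                      if (ti < 0 || ai < 0 || ti >= nx || ai >= nx) continue;
                      double d = T[ti + (size_t)nx * (tj + (size_t)ny * tk)]
                               - AI[a][ai + (size_t)nx * (aj + (size_t)ny * ak)];
                      ssd += d * d; ++n;
                    }
                  }
                }
                if (n == 0) continue;
                double off2 = dx*sx*dx*sx + dy*sy*dy*sy + dz*sz*dz*sz;
                double w = std::exp(-ssd / (h2 * n)) * std::exp(-off2 / s2);
                Cand c; c.w = w; c.ord = ord;
                c.label = AL[a][ci + (size_t)nx * (cj + (size_t)ny * ck)];
                cands.push_back(c);
              }
          if (cands.empty()) continue;
          any = true;
          int keep = std::min<int>(n_best, (int)cands.size());
          std::stable_sort(cands.begin(), cands.end(),
                           [](const Cand &x, const Cand &y) { return x.w > y.w; });
          for (int c = 0; c < keep; ++c) {
            int lab = cands[c].label;
            if (lab >= 0 && lab <= 3) wlab[lab] += cands[c].w;
          }
        }
        int best = 0;
        if (any) {
          double bw = wlab[0];
          for (int l = 1; l < 4; ++l)
            if (wlab[l] > bw) { bw = wlab[l]; best = l; }
        }
        out[i + (size_t)nx * (j + (size_t)ny * k)] = best;
      }
  out.attr("dim") = dims;
  return out;
}

// trilinear / nearest-neighbour sampling of a volume at continuous voxel
// indices (0-based); outside the grid returns `fill`
// [[Rcpp::export]]
NumericVector sample_volume_cpp(NumericVector values, IntegerVector dims,
                                NumericMatrix idx, bool nearest, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *V = values.begin();
  int nq = idx.nrow();
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double x = idx(q,0), y = idx(q,1), z = idx(q,2);
    if (nearest) {
      // round half to even: a grid-ratio that lands exactly between voxels
      // (e.g. 3 mm sampling of a 2 mm grid) must not shift the mask
      auto rnd = [](double v) {
        double f = std::floor(v + 0.5);
        long long fi = (long long)f;
        if (v + 0.5 == f && (fi & 1LL)) fi -= 1LL;
        return (int)fi;
      };
      int i = rnd(x), j = rnd(y), k = rnd(z);
      out[q] = (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
                 ? fill : V[i + (size_t)nx * (j + (size_t)ny * k)];
    } else {
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      if (i0 < 0 || j0 < 0 || k0 < 0 || i0 + 1 >= nx || j0 + 1 >= ny || k0 + 1 >= nz) {
        // clamp to border when just outside by < half voxel, else fill
        if (x < -0.5 || y < -0.5 || z < -0.5 ||
            x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) { out[q] = fill; continue; }
        int i = std::min(nx - 1, std::max(0, (int)std::lround(x)));
        int j = std::min(ny - 1, std::max(0, (int)std::lround(y)));
        int k = std::min(nz - 1, std::max(0, (int)std::lround(z)));
        out[q] = V[i + (size_t)nx * (j + (size_t)ny * k)];
        continue;
      }
      double fx = x - i0, fy = y - j0, fz = z - k0;
      double acc = 0;
      for (int dk = 0; dk <= 1; ++dk)
        for (int dj = 0; dj <= 1; ++dj)
          for (int di = 0; di <= 1; ++di) {
            double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
            acc += w * V[(i0+di) + (size_t)nx * ((j0+dj) + (size_t)ny * (k0+dk))];
          }
      out[q] = acc;
    }
  }
  return out;
}
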