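#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Isosurface extraction on a regular scalar grid by tetrahedral
// decomposition: each grid cell is split into the six Kuhn tetrahedra
// sharing the cell's main diagonal. The Kuhn split tiles space
// compatibly (shared cell faces receive the same diagonal from both
// sides), so the extracted surface is free of the ambiguous-case holes
// of table-driven cube triangulation and capped meshes close up
// watertight. Iso-vertices are linearly interpolated along tetrahedron
// edges; every such edge joins two grid nodes, so vertices are deduped
// by their (node, node) key.

// Local cell-vertex bit encoding: v = x + 2y + 4z.
// Six tetrahedra = monotone vertex paths 0 -> 7, one per axis order.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

struct MeshBuilder {
  std::unordered_map<uint64_t, int> vkey;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri; // 0-based, flattened triples
};

static inline uint64_t edge_key(int64_t a, int64_t b) {
  if (a > b) std::swap(a, b);
  return (static_cast<uint64_t>(a) << 32) | static_cast<uint64_t>(b);
}

// [[Rcpp::export(name = ".cpp_isosurface")]]
List cpp_isosurface(NumericVector vol, IntegerVector dim,
                    NumericVector origin, NumericVector spacing,
                    double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = REAL(vol);

  // Shift samples exactly at the level off it so sign classification is
  // strict and interpolation parameters stay inside (0, 1).
  double vmin = R_PosInf, vmax = R_NegInf;
  const R_xlen_t n = vol.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (v[i] < vmin) vmin = v[i];
    if (v[i] > vmax) vmax = v[i];
  }
  const double scale = std::max(1.0, std::max(std::fabs(vmin), std::fabs(vmax)));
  const double eps = 1e-12 * scale;

  MeshBuilder mb;
  const int64_t sx = 1, sy = nx, sz = static_cast<int64_t>(nx) * ny;

  auto node_val = [&](int64_t lin) {
    double val = v[lin];
    if (val == level) val = level + eps;
    return val;
  };

  // Interpolated iso-vertex on the segment between grid nodes a, b.
  auto iso_vertex = [&](int64_t la, int64_t lb, double va, double vb) -> int {
    uint64_t key = edge_key(la, lb);
    auto it = mb.vkey.find(key);
    if (it != mb.vkey.end()) return it->second;
    double t = (level - va) / (vb - va);
    int ax = static_cast<int>(la % nx), ay = static_cast<int>((la / nx) % ny),
        az = static_cast<int>(la / sz);
    int bx = static_cast<int>(lb % nx), by = static_cast<int>((lb / nx) % ny),
        bz = static_cast<int>(lb / sz);
    int id = static_cast<int>(mb.vx.size());
    mb.vx.push_back(origin[0] + spacing[0] * (ax + t * (bx - ax)));
    mb.vy.push_back(origin[1] + spacing[1] * (ay + t * (by - ay)));
    mb.vz.push_back(origin[2] + spacing[2] * (az + t * (bz - az)));
    mb.vkey.emplace(key, id);
    return id;
  };

  // Emit a triangle oriented so its normal points from the below-level
  // (solid) side toward the above-level side.
  auto emit = [&](int i0, int i1, int i2,
                  double cbx, double cby, double cbz,
                  double cax, double cay, double caz) {
    if (i0 == i1 || i1 == i2 || i0 == i2) return;
    double ux = mb.vx[i1] - mb.vx[i0], uy = mb.vy[i1] - mb.vy[i0],
           uz = mb.vz[i1] - mb.vz[i0];
    double wx = mb.vx[i2] - mb.vx[i0], wy = mb.vy[i2] - mb.vy[i0],
           wz = mb.vz[i2] - mb.vz[i0];
    double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz,
           nzv = ux * wy - uy * wx;
    double dx = cax - cbx, dy = cay - cby, dz = caz - cbz;
    if (nxv * dx + nyv * dy + nzv * dz < 0) std::swap(i1, i2);
    mb.tri.push_back(i0); mb.tri.push_back(i1); mb.tri.push_back(i2);
  };

  int64_t corner[8];
  double val[8];
  double px[8], py[8], pz[8]; // node grid coordinates (index units)

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        const int64_t base = i * sx + static_cast<int64_t>(j) * sy +
                             static_cast<int64_t>(k) * sz;
        bool any_below = false, any_above = false;
        for (int c = 0; c < 8; ++c) {
          const int cx = c & 1, cy = (c >> 1) & 1, cz = (c >> 2) & 1;
          corner[c] = base + cx * sx + cy * sy + cz * sz;
          val[c] = node_val(corner[c]);
          px[c] = i + cx; py[c] = j + cy; pz[c] = k + cz;
          (val[c] < level ? any_below : any_above) = true;
        }
        if (!any_below || !any_above) continue;

        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int below[4], above[4];
          int nb = 0, na = 0;
          for (int c = 0; c < 4; ++c) {
            if (val[T[c]] < level) below[nb++] = T[c];
            else above[na++] = T[c];
          }
          if (nb == 0 || nb == 4) continue;

          // Phase centroids steer the outward orientation.
          double cbx = 0, cby = 0, cbz = 0, cax = 0, cay = 0, caz = 0;
          for (int c = 0; c < nb; ++c) {
            cbx += px[below[c]]; cby += py[below[c]]; cbz += pz[below[c]];
          }
          for (int c = 0; c < na; ++c) {
            cax += px[above[c]]; cay += py[above[c]]; caz += pz[above[c]];
          }
          cbx /= nb; cby /= nb; cbz /= nb; cax /= na; cay /= na; caz /= na;
          cbx = origin[0] + spacing[0] * cbx; cby = origin[1] + spacing[1] * cby;
          cbz = origin[2] + spacing[2] * cbz;
          cax = origin[0] + spacing[0] * cax; cay = origin[1] + spacing[1] * cay;
          caz = origin[2] + spacing[2] * caz;

          if (nb == 1 || nb == 3) {
            const int apex = (nb == 1) ? below[0] : above[0];
            const int *oth = (nb == 1) ? above : below;
            int ia = iso_vertex(corner[apex], corner[oth[0]], val[apex], val[oth[0]]);
            int ib = iso_vertex(corner[apex], corner[oth[1]], val[apex], val[oth[1]]);
            int ic = iso_vertex(corner[apex], corner[oth[2]], val[apex], val[oth[2]]);
            emit(ia, ib, ic, cbx, cby, cbz, cax, cay, caz);
          } else { // nb == 2: quad cycle AC - AD - BD - BC
            const int A = below[0], B = below[1], C = above[0], D = above[1];
            int iac = iso_vertex(corner[A], corner[C], val[A], val[C]);
            int iad = iso_vertex(corner[A], corner[D], val[A], val[D]);
            int ibd = iso_vertex(corner[B], corner[D], val[B], val[D]);
            int ibc = iso_vertex(corner[B], corner[C], val[B], val[C]);
            emit(iac, iad, ibd, cbx, cby, cbz, cax, cay, caz);
            emit(iac, ibd, ibc, cbx, cby, cbz, cax, cay, caz);
          }
        }
      }
    }
  }

  const int nv = static_cast<int>(mb.vx.size());
  const int nt = static_cast<int>(mb.tri.size() / 3);
  NumericMatrix verts(nv, 3);
  for (int a = 0; a < nv; ++a) {
    verts(a, 0) = mb.vx[a]; verts(a, 1) = mb.vy[a]; verts(a, 2) = mb.vz[a];
  }
  IntegerMatrix faces(nt, 3);
  for (int a = 0; a < nt; ++a) {
    faces(a, 0) = mb.tri[3 * a] + 1;
    faces(a, 1) = mb.tri[3 * a + 1] + 1;
    faces(a, 2) = mb.tri[3 * a + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
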