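#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Silhouette rasterization: a cell is occupied iff its center lies inside any
// projected triangle.  Closed predicate: points on an edge count as inside
// (tolerance 1e-9, scaled by the doubled triangle area) so axis-aligned
// geometry does not drop boundary cells.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalMatrix rasterize_silhouette_cpp(NumericMatrix V, IntegerMatrix F,
                                       double cell, double ou, double ov,
                                       int nu, int nv) {
  LogicalMatrix occ(nu, nv);
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const int i0 = F(f, 0), i1 = F(f, 1), i2 = F(f, 2);
    const double x0 = V(i0, 0), y0 = V(i0, 1);
    const double x1 = V(i1, 0), y1 = V(i1, 1);
    const double x2 = V(i2, 0), y2 = V(i2, 1);
    const double area2 = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (area2 == 0.0) continue;  // degenerate under projection
    const double sgn = area2 > 0 ? 1.0 : -1.0;
    const double tol = 1e-9 * std::max(1.0, std::fabs(area2));
    const double xmin = std::min({x0, x1, x2}), xmax = std::max({x0, x1, x2});
    const double ymin = std::min({y0, y1, y2}), ymax = std::max({y0, y1, y2});
    // cell centers: u_i = ou + (i + 0.5) * cell (i 0-based)
    int iu0 = (int)std::floor((xmin - ou) / cell - 0.5);
    int iu1 = (int)std::ceil((xmax - ou) / cell - 0.5);
    int iv0 = (int)std::floor((ymin - ov) / cell - 0.5);
    int iv1 = (int)std::ceil((ymax - ov) / cell - 0.5);
    iu0 = std::max(iu0, 0); iv0 = std::max(iv0, 0);
    iu1 = std::min(iu1, nu - 1); iv1 = std::min(iv1, nv - 1);
    for (int iu = iu0; iu <= iu1; ++iu) {
      const double px = ou + (iu + 0.5) * cell;
      for (int iv = iv0; iv <= iv1; ++iv) {
        if (occ(iu, iv)) continue;
        const double py = ov + (iv + 0.5) * cell;
        const double e0 = sgn * ((x1 - x0) * (py - y0) - (y1 - y0) * (px - x0));
        if (e0 < -tol) continue;
        const double e1 = sgn * ((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1));
        if (e1 < -tol) continue;
        const double e2 = sgn * ((x0 - x2) * (py - y2) - (y0 - y2) * (px - x2));
        if (e2 < -tol) continue;
        occ(iu, iv) = true;
      }
    }
  }
  return occ;
}

// ---------------------------------------------------------------------------
// Voxelization by vertical-ray parity.  For every grid column (voxel centers
// share x,y) the z-crossings with the surface are collected; a voxel center is
// inside iff an odd number of crossings lie below it.  The point-in-projected-
// triangle test uses symbolic perturbation (simulation of simplicity) so a ray
// through a shared edge or vertex is claimed by exactly the right number of
// triangles and the parity stays watertight.
// ---------------------------------------------------------------------------

static inline int perturbed_sign(double e, double ax, double ay,
                                 double bx, double by) {
  if (e != 0.0) return e > 0 ? 1 : -1;
  // E == 0: perturb sample by (+eps_x, +eps_y), eps_x >> eps_y > 0
  const double c1 = ay - by;            // coefficient of eps_x
  if (c1 != 0.0) return c1 > 0 ? 1 : -1;
  const double c2 = bx - ax;            // coefficient of eps_y
  return c2 > 0 ? 1 : -1;               // c2 == 0 impossible for non-degenerate edge
}

// [[Rcpp::export]]
LogicalVector voxelize_cpp(NumericMatrix V, IntegerMatrix F,
                           NumericVector spacing, NumericVector origin,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  std::vector< std::vector<double> > cross((size_t)nx * ny);
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const int i0 = F(f, 0), i1 = F(f, 1), i2 = F(f, 2);
    double x0 = V(i0, 0), y0 = V(i0, 1), z0 = V(i0, 2);
    double x1 = V(i1, 0), y1 = V(i1, 1), z1 = V(i1, 2);
    double x2 = V(i2, 0), y2 = V(i2, 1), z2 = V(i2, 2);
    double area2 = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (area2 == 0.0) continue;  // perpendicular to the projection: no crossing
    if (area2 < 0) {             // normalize to CCW in the x-y plane
      std::swap(x1, x2); std::swap(y1, y2); std::swap(z1, z2);
      area2 = -area2;
    }
    const double xmin = std::min({x0, x1, x2}), xmax = std::max({x0, x1, x2});
    const double ymin = std::min({y0, y1, y2}), ymax = std::max({y0, y1, y2});
    int iu0 = std::max((int)std::floor((xmin - ox) / sx - 0.5), 0);
    int iu1 = std::min((int)std::ceil((xmax - ox) / sx - 0.5), nx - 1);
    int iv0 = std::max((int)std::floor((ymin - oy) / sy - 0.5), 0);
    int iv1 = std::min((int)std::ceil((ymax - oy) / sy - 0.5), ny - 1);
    for (int iu = iu0; iu <= iu1; ++iu) {
      const double px = ox + (iu + 0.5) * sx;
      for (int iv = iv0; iv <= iv1; ++iv) {
        const double py = oy + (iv + 0.5) * sy;
        const double e0 = (x1 - x0) * (py - y0) - (y1 - y0) * (px - x0);
        const double e1 = (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1);
        const double e2 = (x0 - x2) * (py - y2) - (y0 - y2) * (px - x2);
        if (perturbed_sign(e0, x0, y0, x1, y1) < 0) continue;
        if (perturbed_sign(e1, x1, y1, x2, y2) < 0) continue;
        if (perturbed_sign(e2, x2, y2, x0, y0) < 0) continue;
        // barycentric interpolation of z (weights = opposite sub-areas)
        const double z = (e1 * z0 + e2 * z1 + e0 * z2) / area2;
        cross[(size_t)iu + (size_t)nx * iv].push_back(z);
      }
    }
  }
  LogicalVector occ((R_xlen_t)nx * ny * nz);
  for (int iv = 0; iv < ny; ++iv) {
    for (int iu = 0; iu < nx; ++iu) {
      std::vector<double>& zs = cross[(size_t)iu + (size_t)nx * iv];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      size_t p = 0;
      for (int iw = 0; iw < nz; ++iw) {
        const double zc = oz + (iw + 0.5) * sz;
        while (p < zs.size() && zs[p] < zc) ++p;
        if (p & 1) occ[(R_xlen_t)iu + (R_xlen_t)nx * (iv + (R_xlen_t)ny * iw)] = true;
      }
    }
  }
  return occ;
}

// ---------------------------------------------------------------------------
// Iso-surface extraction by marching tetrahedra on the Kuhn 6-tetrahedron
// decomposition of each grid cube.  The decomposition picks face diagonals
// consistently between neighbouring cubes, and the iso-surface of a piecewise
// linear field at a regular value is a closed manifold, so the output is
// watertight.  Vertices lie on lattice edges and are shared via a global edge
// key.  Coordinates are returned in voxel-index space (voxel (1,1,1) center
// at (1,1,1)); the caller maps to world mm.
// ---------------------------------------------------------------------------

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

// ca, cb: cube-corner codes (0..7); px/py/pz/val indexed by code; lin[] maps
// code -> global lattice index, used to share the vertex across tets/cubes.
static int edge_point(MTState& st, int ca, int cb,
                      const double* px, const double* py, const double* pz,
                      const double* val, const int* lin, double iso) {
  const int la = lin[ca], lb = lin[cb];
  uint64_t a = (uint64_t)std::min(la, lb), b = (uint64_t)std::max(la, lb);
  uint64_t key = (a << 32) | b;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  const double t = (iso - val[ca]) / (val[cb] - val[ca]);
  st.vx.push_back(px[ca] + t * (px[cb] - px[ca]));
  st.vy.push_back(py[ca] + t * (py[cb] - py[ca]));
  st.vz.push_back(pz[ca] + t * (pz[cb] - pz[ca]));
  const int id = (int)st.vx.size() - 1;
  st.edge_vertex[key] = id;
  return id;
}

static void emit_tri(MTState& st, int a, int b, int c,
                     double inx, double iny, double inz) {
  // orient so the normal points away from the inside of the solid
  const double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
  const double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
  const double wx = st.vx[c] - ax, wy = st.vy[c] - ay, wz = st.vz[c] - az;
  const double nxv = uy * wz - uz * wy;
  const double nyv = uz * wx - ux * wz;
  const double nzv = ux * wy - uy * wx;
  const double cx = (ax + st.vx[b] + st.vx[c]) / 3.0 - inx;
  const double cy = (ay + st.vy[b] + st.vy[c]) / 3.0 - iny;
  const double cz = (az + st.vz[b] + st.vz[c]) / 3.0 - inz;
  if (nxv * cx + nyv * cy + nzv * cz < 0) std::swap(b, c);
  st.f0.push_back(a); st.f1.push_back(b); st.f2.push_back(c);
}

// [[Rcpp::export]]
List marching_tets_cpp(LogicalVector occ, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  MTState st;
  // the 6 axis-order permutations defining the Kuhn split
  static const int perms[6][3] = {
    {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        // cube corner values / linear indices / coordinates
        double val[8], px[8], py[8], pz[8];
        int lin[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          const int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          const int ii = i + di, jj = j + dj, kk = k + dk;
          lin[c] = ii + nx * (jj + ny * kk);
          val[c] = occ[lin[c]] ? 1.0 : 0.0;
          px[c] = ii + 1.0; py[c] = jj + 1.0; pz[c] = kk + 1.0;
          if (val[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          // tet corners as cube-corner codes along the permutation path
          int code[4];
          code[0] = 0;
          code[1] = code[0] | (1 << perms[t][0]);
          code[2] = code[1] | (1 << perms[t][1]);
          code[3] = 7;
          int inside[4], nin = 0;
          for (int v = 0; v < 4; ++v)
            inside[v] = val[code[v]] > iso ? 1 : 0, nin += inside[v];
          if (nin == 0 || nin == 4) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) {
            if (inside[v]) ins[ni++] = code[v]; else outs[no++] = code[v];
          }
          double inx = 0, iny = 0, inz = 0;
          for (int v = 0; v < ni; ++v) {
            inx += px[ins[v]] / ni; iny += py[ins[v]] / ni; inz += pz[ins[v]] / ni;
          }
          if (nin == 1 || nin == 3) {
            const int base = (nin == 1) ? ins[0] : outs[0];
            const int oth[3] = { (nin == 1) ? outs[0] : ins[0],
                                 (nin == 1) ? outs[1] : ins[1],
                                 (nin == 1) ? outs[2] : ins[2] };
            int q[3];
            for (int v = 0; v < 3; ++v)
              q[v] = edge_point(st, base, oth[v], px, py, pz, val, lin, iso);
            emit_tri(st, q[0], q[1], q[2], inx, iny, inz);
          } else { // nin == 2: quad split into two triangles
            const int a0 = ins[0], a1 = ins[1], b0 = outs[0], b1 = outs[1];
            const int q00 = edge_point(st, a0, b0, px, py, pz, val, lin, iso);
            const int q01 = edge_point(st, a0, b1, px, py, pz, val, lin, iso);
            const int q10 = edge_point(st, a1, b0, px, py, pz, val, lin, iso);
            const int q11 = edge_point(st, a1, b1, px, py, pz, val, lin, iso);
            emit_tri(st, q00, q01, q11, inx, iny, inz);
            emit_tri(st, q00, q11, q10, inx, iny, inz);
          }
        }
      }
    }
  }
  const int nvert = (int)st.vx.size();
  NumericMatrix Vout(nvert, 3);
  for (int v = 0; v < nvert; ++v) {
    Vout(v, 0) = st.vx[v]; Vout(v, 1) = st.vy[v]; Vout(v, 2) = st.vz[v];
  }
  const int nfac = (int)st.f0.size();
  IntegerMatrix Fout(nfac, 3);
  for (int f = 0; f < nfac; ++f) {
    Fout(f, 0) = st.f0[f] + 1; Fout(f, 1) = st.f1[f] + 1; Fout(f, 2) = st.f2[f] + 1;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
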