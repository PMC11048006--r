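#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iso-surface (level 0.5) area and enclosed volume of a scalar field by
// marching tetrahedra: each 2x2x2 cell is split into 6 tetrahedra sharing
// the main diagonal; the in-region part of each tetrahedron is clipped by
// linear interpolation along cut edges. The field is implicitly padded with
// zeros so the surface closes at the grid border. Physical coordinates use
// the anisotropic voxel spacing.

struct V3 {
  double x, y, z;
};
static inline V3 vsub(const V3& a, const V3& b) {
  V3 r = {a.x - b.x, a.y - b.y, a.z - b.z};
  return r;
}
static inline V3 vcross(const V3& a, const V3& b) {
  V3 r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
  return r;
}
static inline double vdot(const V3& a, const V3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double tri_area(const V3& a, const V3& b, const V3& c) {
  V3 n = vcross(vsub(b, a), vsub(c, a));
  return 0.5 * std::sqrt(vdot(n, n));
}
static inline double tet_vol(const V3& a, const V3& b, const V3& c,
                             const V3& d) {
  return std::fabs(vdot(vsub(b, a), vcross(vsub(c, a), vsub(d, a)))) / 6.0;
}
static inline V3 lerp(const V3& a, const V3& b, double va, double vb,
                      double iso) {
  double t = (iso - va) / (vb - va);
  V3 r = {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
  return r;
}

// 6-tet decomposition of the unit cube sharing diagonal v0-v7; cube vertex
// k has offsets (k&1, (k>>1)&1, (k>>2)&1).
static const int TETS[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                               {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

// [[Rcpp::export(name = ".mesh_area_volume")]]
NumericVector mesh_area_volume(NumericVector field, IntegerVector dim,
                               NumericVector spacing, double iso = 0.5) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0, volume = 0.0;
  // padded grid of (nx+2)x(ny+2)x(nz+2) values; cells between sample points
  double vals[8];
  V3 pos[8];
  for (int z = -1; z < nz; z++)
    for (int y = -1; y < ny; y++)
      for (int x = -1; x < nx; x++) {
        bool any = false, all = true;
        for (int k = 0; k < 8; k++) {
          int cx = x + (k & 1), cy = y + ((k >> 1) & 1), cz = z + ((k >> 2) & 1);
          double v = 0.0;
          if (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz)
            v = field[(R_xlen_t)cz * nx * ny + (R_xlen_t)cy * nx + cx];
          vals[k] = v;
          pos[k].x = cx * sx;
          pos[k].y = cy * sy;
          pos[k].z = cz * sz;
          if (v >= iso) any = true; else all = false;
        }
        if (!any) continue;
        if (all) {
          volume += sx * sy * sz;
          continue;
        }
        for (int t = 0; t < 6; t++) {
          const int* T = TETS[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; k++) {
            if (vals[T[k]] >= iso) in[nin++] = T[k];
            else out[nout++] = T[k];
          }
          double vt = tet_vol(pos[T[0]], pos[T[1]], pos[T[2]], pos[T[3]]);
          if (nin == 0) continue;
          if (nin == 4) {
            volume += vt;
            continue;
          }
          if (nin == 1) {
            V3 c[3];
            double prod = 1.0;
            for (int k = 0; k < 3; k++) {
              double t0 = (iso - vals[in[0]]) / (vals[out[k]] - vals[in[0]]);
              prod *= t0;
              c[k] = lerp(pos[in[0]], pos[out[k]], vals[in[0]], vals[out[k]],
                          iso);
            }
            area += tri_area(c[0], c[1], c[2]);
            volume += vt * prod;
          } else if (nin == 3) {
            V3 c[3];
            double prod = 1.0;
            for (int k = 0; k < 3; k++) {
              double t0 = (iso - vals[out[0]]) / (vals[in[k]] - vals[out[0]]);
              prod *= t0;
              c[k] = lerp(pos[out[0]], pos[in[k]], vals[out[0]], vals[in[k]],
                          iso);
            }
            area += tri_area(c[0], c[1], c[2]);
            volume += vt * (1.0 - prod);
          } else { // nin == 2: quad section, wedge volume
            V3 m00 = lerp(pos[in[0]], pos[out[0]], vals[in[0]], vals[out[0]], iso);
            V3 m01 = lerp(pos[in[0]], pos[out[1]], vals[in[0]], vals[out[1]], iso);
            V3 m10 = lerp(pos[in[1]], pos[out[0]], vals[in[1]], vals[out[0]], iso);
            V3 m11 = lerp(pos[in[1]], pos[out[1]], vals[in[1]], vals[out[1]], iso);
            area += tri_area(m00, m01, m11) + tri_area(m00, m11, m10);
            // wedge in[0], in[1], cut quad: split into three tetrahedra
            volume += tet_vol(pos[in[0]], pos[in[1]], m10, m11) +
                      tet_vol(pos[in[0]], m10, m00, m11) +
                      tet_vol(pos[in[0]], m00, m01, m11);
          }
        }
      }
  return NumericVector::create(area, volume);
}

// Maximum pairwise physical distances of a voxel set: full 3D and within
// planes of fixed z (slice), fixed y (column) and fixed x (row). Points
// strictly between two same-line voxels cannot be convex-hull vertices, so
// only per-line extremes enter the pairwise scans (exact, much smaller).
// [[Rcpp::export(name = ".max_diameters")]]
NumericVector max_diameters(LogicalVector mask, IntegerVector dim,
                            NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // per-(y,z) x-extremes
  std::vector<int> xmin((R_xlen_t)ny * nz, -1), xmax((R_xlen_t)ny * nz, -1);
  // per-(x,z) y-extremes (for the fixed-x "row" planes)
  std::vector<int> ymin((R_xlen_t)nx * nz, -1), ymax((R_xlen_t)nx * nz, -1);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        if (!mask[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x]) continue;
        R_xlen_t l = (R_xlen_t)z * ny + y;
        if (xmin[l] < 0 || x < xmin[l]) xmin[l] = x;
        if (x > xmax[l]) xmax[l] = x;
        R_xlen_t m = (R_xlen_t)z * nx + x;
        if (ymin[m] < 0 || y < ymin[m]) ymin[m] = y;
        if (y > ymax[m]) ymax[m] = y;
      }
  // candidate points from x-extremes: (x, y, z)
  std::vector<double> cx, cy, cz;
  std::vector<int> czi, cyi;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t l = (R_xlen_t)z * ny + y;
      if (xmin[l] < 0) continue;
      cx.push_back(xmin[l] * sx); cy.push_back(y * sy); cz.push_back(z * sz);
      czi.push_back(z); cyi.push_back(y);
      if (xmax[l] != xmin[l]) {
        cx.push_back(xmax[l] * sx); cy.push_back(y * sy); cz.push_back(z * sz);
        czi.push_back(z); cyi.push_back(y);
      }
    }
  size_t n = cx.size();
  double b3 = 0, bslice = 0, bcol = 0;
  for (size_t i = 0; i < n; i++)
    for (size_t j = i + 1; j < n; j++) {
      double dx = cx[i] - cx[j], dy = cy[i] - cy[j], dz = cz[i] - cz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > b3) b3 = d2;
      if (czi[i] == czi[j] && d2 > bslice) bslice = d2;
      if (cyi[i] == cyi[j] && d2 > bcol) bcol = d2;
    }
  // fixed-x planes need y-extremes per (x,z) line
  std::vector<double> rx, ry, rz;
  std::vector<int> rxi;
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t m = (R_xlen_t)z * nx + x;
      if (ymin[m] < 0) continue;
      rx.push_back(x * sx); ry.push_back(ymin[m] * sy); rz.push_back(z * sz);
      rxi.push_back(x);
      if (ymax[m] != ymin[m]) {
        rx.push_back(x * sx); ry.push_back(ymax[m] * sy); rz.push_back(z * sz);
        rxi.push_back(x);
      }
    }
  double brow = 0;
  for (size_t i = 0; i < rx.size(); i++)
    for (size_t j = i + 1; j < rx.size(); j++) {
      if (rxi[i] != rxi[j]) continue;
      double dy = ry[i] - ry[j], dz = rz[i] - rz[j];
      double d2 = dy * dy + dz * dz;
      if (d2 > brow) brow = d2;
    }
  return NumericVector::create(std::sqrt(b3), std::sqrt(bslice),
                               std::sqrt(bcol), std::sqrt(brow));
}
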