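#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// The 13 unique 3D direction vectors at Chebyshev distance 1 (one per
// antipodal pair), ordered axis moves first, then face/edge/corner diagonals.
static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
}

// Symmetrised grey-level co-occurrence counts for the 13 unique distance-1
// offsets. levels: 1..Ng inside the region, 0 outside. Returns Ng x Ng x 13.
// [[Rcpp::export(name = ".glcm_counts")]]
NumericVector glcm_counts(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(Dimension(ng, ng, 13));
  for (int d = 0; d < 13; d++) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double* tab = &out[(R_xlen_t)d * ng * ng];
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (b == 0) continue;
          tab[(R_xlen_t)(b - 1) * ng + (a - 1)] += 1.0;
          tab[(R_xlen_t)(a - 1) * ng + (b - 1)] += 1.0;
        }
  }
  return out;
}

// Grey-level run-length counts over the 13 unique directions.
// Returns Ng x Lmax x 13 with Lmax = max grid extent.
// [[Rcpp::export(name = ".glrlm_counts")]]
NumericVector glrlm_counts(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int lmax = nx > ny ? nx : ny;
  if (nz > lmax) lmax = nz;
  NumericVector out(Dimension(ng, lmax, 13));
  for (int d = 0; d < 13; d++) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double* tab = &out[(R_xlen_t)d * ng * lmax];
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          // run start: predecessor out of grid, outside mask or other level
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              levels[idx3(xp, yp, zp, nx, ny)] == a)
            continue;
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 &&
                 zc < nz && levels[idx3(xc, yc, zc, nx, ny)] == a) {
            len++;
            xc += dx; yc += dy; zc += dz;
          }
          tab[(R_xlen_t)(len - 1) * ng + (a - 1)] += 1.0;
        }
  }
  return out;
}

// Zones of 26-connected equal-level voxels. Returns a 2-column matrix
// (level, zone size), one row per zone, in deterministic scan order.
// [[Rcpp::export(name = ".glszm_zones")]]
IntegerMatrix glszm_zones(IntegerVector levels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i0 = idx3(x, y, z, nx, ny);
        int lev = levels[i0];
        if (lev == 0 || seen[i0]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(i0);
        seen[i0] = 1;
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          size++;
          int cz = (int)(cur / ((R_xlen_t)nx * ny));
          int rem = (int)(cur % ((R_xlen_t)nx * ny));
          int cy = rem / nx, cx = rem % nx;
          for (int dz = -1; dz <= 1; dz++)
            for (int dy = -1; dy <= 1; dy++)
              for (int dx = -1; dx <= 1; dx++) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
                if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                    z2 >= nz)
                  continue;
                R_xlen_t j = idx3(x2, y2, z2, nx, ny);
                if (!seen[j] && levels[j] == lev) {
                  seen[j] = 1;
                  stack.push_back(j);
                }
              }
        }
        zl.push_back(lev);
        zs.push_back(size);
      }
  IntegerMatrix out((int)zl.size(), 2);
  for (int i = 0; i < (int)zl.size(); i++) {
    out(i, 0) = zl[i];
    out(i, 1) = zs[i];
  }
  return out;
}

// Grey-level dependence counts: for each in-region voxel, the number of
// 26-neighbours (inside the region) whose level differs by at most alpha.
// Returns Ng x 27 count matrix: column k+1 = dependence count k (0..26).
// [[Rcpp::export(name = ".gldm_counts")]]
NumericMatrix gldm_counts(IntegerVector levels, IntegerVector dim, int ng,
                          int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              int b = levels[idx3(x2, y2, z2, nx, ny)];
              if (b == 0) continue;
              int diff = a > b ? a - b : b - a;
              if (diff <= alpha) dep++;
            }
        out(a - 1, dep) += 1.0;
      }
  return out;
}

// Neighbouring grey-tone difference accumulators: per level i, the voxel
// count n_i and the summed |i - mean(26-neighbour levels)| s_i. Voxels with
// no in-region neighbour are excluded. Returns Ng x 2 (n_i, s_i).
// [[Rcpp::export(name = ".ngtdm_stats")]]
NumericMatrix ngtdm_stats(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              int b = levels[idx3(x2, y2, z2, nx, ny)];
              if (b == 0) continue;
              sum += b;
              cnt++;
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::abs((double)a - sum / cnt);
      }
  return out;
}
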