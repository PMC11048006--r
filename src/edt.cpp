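#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 1D squared distance transform (lower envelope of parabolas) with samples
// at positions i*w, arbitrary positive spacing w. f holds squared costs.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double BIG = 1e300;
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double xq = q * w;
    double s;
    while (true) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * w;
    while (z[k + 1] < xq) k++;
    double xv = v[k] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared EDT of a 3D foreground mask to the nearest background voxel centre,
// honouring anisotropic voxel spacing. Background voxels get 0. A grid with
// no background yields a large finite sentinel (> any in-grid distance).
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double ex = nx * spacing[0], ey = ny * spacing[1], ez = nz * spacing[2];
  const double CAP = ex * ex + ey * ey + ez * ez + 1.0;
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); i++)
    out[i] = mask[i] ? CAP : 0.0;
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; x++) f[x] = out[base + x];
        dt1d(f, d, nx, spacing[0]);
        for (int x = 0; x < nx; x++) out[base + x] = d[x];
      }
  }
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; z++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)y * nx];
        dt1d(f, d, ny, spacing[1]);
        for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = d[y];
      }
  }
  {
    std::vector<double> f(nz), d(nz);
    R_xlen_t slab = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; z++) f[z] = out[base + (R_xlen_t)z * slab];
        dt1d(f, d, nz, spacing[2]);
        for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * slab] = d[z];
      }
  }
  return out;
}
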