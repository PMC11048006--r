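#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Convolve a 3D array along one axis with a centred kernel.
// Boundary mode: 0 = reflect (mirror without repeating the edge sample),
// 1 = periodic. Kernel length must be odd for symmetric use; any length is
// accepted with centre at floor(len/2).
// [[Rcpp::export(name = ".conv3d_axis")]]
NumericVector conv3d_axis(NumericVector arr, IntegerVector dim,
                          NumericVector kernel, int axis, int mode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int kl = kernel.size();
  int kc = kl / 2;
  NumericVector out(arr.size());
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int na = n[axis];
  R_xlen_t sa = stride[axis];
  // iterate over all lines along `axis`
  int ob1 = (axis == 0) ? 1 : 0;
  int ob2 = (axis == 2) ? 1 : 2;
  std::vector<double> line(na), res(na);
  for (int j2 = 0; j2 < n[ob2]; j2++)
    for (int j1 = 0; j1 < n[ob1]; j1++) {
      R_xlen_t base = (R_xlen_t)j1 * stride[ob1] + (R_xlen_t)j2 * stride[ob2];
      for (int i = 0; i < na; i++) line[i] = arr[base + (R_xlen_t)i * sa];
      for (int i = 0; i < na; i++) {
        double acc = 0.0;
        for (int k = 0; k < kl; k++) {
          int p = i + k - kc;
          if (mode == 1) {
            p %= na;
            if (p < 0) p += na;
          } else {
            while (p < 0 || p >= na) {
              if (p < 0) p = -p - 1;
              if (p >= na) p = 2 * na - 1 - p;
            }
          }
          acc += line[p] * kernel[k];
        }
        res[i] = acc;
      }
      for (int i = 0; i < na; i++) out[base + (R_xlen_t)i * sa] = res[i];
    }
  return out;
}
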