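#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// symmetric (half-sample) reflection: ... b a | a b c ... | c b a ...
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 3D moving-window median with odd window sizes per axis.
// [[Rcpp::export]]
NumericVector median_filter3d_cpp(NumericVector x, IntegerVector dims,
                                  IntegerVector window) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int wx = window[0], wy = window[1], wz = window[2];
  if (wx < 1 || wy < 1 || wz < 1 || wx % 2 == 0 || wy % 2 == 0 || wz % 2 == 0)
    stop("window sizes must be odd and >= 1");
  const int rx = wx / 2, ry = wy / 2, rz = wz / 2;
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  if (x.size() != ntot) stop("volume size does not match dims");
  NumericVector out(ntot);
  std::vector<double> buf((size_t)wx * wy * wz);
  const size_t mid = buf.size() / 2;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t c = 0;
        for (int dk = -rz; dk <= rz; ++dk) {
          int kk = reflect(k + dk, nz);
          for (int dj = -ry; dj <= ry; ++dj) {
            int jj = reflect(j + dj, ny);
            R_xlen_t base = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx;
            for (int di = -rx; di <= rx; ++di)
              buf[c++] = x[base + reflect(i + di, nx)];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = buf[mid];
      }
  out.attr("dim") = dims;
  return out;
}
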