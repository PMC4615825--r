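#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connectivity component labelling by flood fill. Labels are assigned in
// column-major scan order, so the component whose first voxel has the
// smallest linear index receives label 1, and so on.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  if (mask.size() != ntot) stop("mask size does not match dims");
  IntegerVector lab(ntot, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = (int)(p % nx);
      int j = (int)((p / nx) % ny);
      int k = (int)(p / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            R_xlen_t q = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
            if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
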