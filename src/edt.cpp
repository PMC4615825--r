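#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, separable
// lower-envelope-of-parabolas) with anisotropic voxel spacing, carrying the
// nearest-site index ("feature transform") through every pass.

static const double INF = std::numeric_limits<double>::infinity();

// One 1D pass. f/fid hold squared distances and site ids sampled along a
// line with physical step h; results go to d/did.
static void dt1d(const std::vector<double>& f, const std::vector<int>& fid,
                 double h, int n,
                 std::vector<double>& d, std::vector<int>& did,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * h;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = 0.0;
    for (;;) {
      int p = v[k];
      double xp = p * h;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) {
        --k;
        if (k < 0) break;
      } else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) {  // no finite parabola on this line
    for (int q = 0; q < n; ++q) { d[q] = INF; did[q] = NA_INTEGER; }
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[j + 1] < xq) ++j;
    int p = v[j];
    double dx = xq - p * h;
    d[q] = dx * dx + f[p];
    did[q] = fid[p];
  }
}

// [[Rcpp::export]]
List edt_cpp(LogicalVector sites, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  if (sites.size() != ntot)
    stop("site volume size does not match dims");
  std::vector<double> D(ntot);
  std::vector<int> ID(ntot);
  bool any_site = false;
  for (R_xlen_t i = 0; i < ntot; ++i) {
    if (sites[i]) { D[i] = 0.0; ID[i] = (int)(i + 1); any_site = true; }
    else { D[i] = INF; ID[i] = NA_INTEGER; }
  }
  if (!any_site) stop("no site voxels: distance transform undefined");

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dline(nmax), z(nmax + 1);
  std::vector<int> fid(nmax), didline(nmax), v(nmax);

  // pass along x (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) { f[i] = D[base + i]; fid[i] = ID[base + i]; }
      dt1d(f, fid, spacing[0], nx, dline, didline, v, z);
      for (int i = 0; i < nx; ++i) { D[base + i] = dline[i]; ID[base + i] = didline[i]; }
    }
  // pass along y (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) { f[j] = D[base + (R_xlen_t)j * nx]; fid[j] = ID[base + (R_xlen_t)j * nx]; }
      dt1d(f, fid, spacing[1], ny, dline, didline, v, z);
      for (int j = 0; j < ny; ++j) { D[base + (R_xlen_t)j * nx] = dline[j]; ID[base + (R_xlen_t)j * nx] = didline[j]; }
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) { f[k] = D[base + (R_xlen_t)k * sz]; fid[k] = ID[base + (R_xlen_t)k * sz]; }
      dt1d(f, fid, spacing[2], nz, dline, didline, v, z);
      for (int k = 0; k < nz; ++k) { D[base + (R_xlen_t)k * sz] = dline[k]; ID[base + (R_xlen_t)k * sz] = didline[k]; }
    }

  NumericVector dist(ntot);
  IntegerVector nearest(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) {
    dist[i] = std::sqrt(D[i]);
    nearest[i] = ID[i];
  }
  dist.attr("dim") = dims;
  nearest.attr("dim") = dims;
  return List::create(_["dist"] = dist, _["nearest"] = nearest);
}
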