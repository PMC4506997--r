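#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D squared-distance transform of a sampled function (Felzenszwalb & Huttenlocher 2012).
// f holds squared distances (INF where no site); result overwrites d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  // build the lower envelope over finite parabolas only
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite site in this scanline
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform: for every voxel, squared distance (in voxel
// units) to the nearest zero voxel of `mask`. mask != 0 means "inside".
// [[Rcpp::export]]
NumericVector edt_squared(IntegerVector mask, IntegerVector dims) {
  int nd = dims.size();
  if (nd < 1 || nd > 3) stop("edt_squared supports 1-3 dimensional arrays");
  int nx = dims[0], ny = nd > 1 ? dims[1] : 1, nz = nd > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] != 0 ? INF : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  if (ny > 1) {
    f.resize(ny); d.resize(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
        dt1d(f, d, ny);
        for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
      }
  }
  if (nz > 1) {
    f.resize(nz); d.resize(nz);
    R_xlen_t plane = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * plane];
        dt1d(f, d, nz);
        for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * plane] = d[z];
      }
  }
  out.attr("dim") = dims;
  return out;
}
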