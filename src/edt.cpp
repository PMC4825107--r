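#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Exact squared Euclidean distance transform of one grid line (Felzenszwalb &
// Huttenlocher lower envelope of parabolas), sample positions i*h. Parabolas
// with infinite height are excluded from the hull; the caller guarantees at
// least one finite entry per line.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double h2 = h * h;
  int k = 0, first = 0;
  while (f[first] == INF) ++first;
  v[0] = first;
  z[0] = -INF;
  z[1] = INF;
  for (int q = first + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s > z[k]) break;
      --k;  // z[0] = -inf guarantees k >= 0 here
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(LogicalVector sites, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t ntot = nxy * nz;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = sites[i] ? 0.0 : INF;

  std::vector<double> f, d;
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = z * nxy + (R_xlen_t)y * nx;
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = out[base + x]; if (f[x] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = z * nxy + x;
      bool any = false;
      for (int y = 0; y < ny; ++y) { f[y] = out[base + (R_xlen_t)y * nx]; if (f[y] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      bool any = false;
      for (int z = 0; z < nz; ++z) { f[z] = out[base + z * nxy]; if (f[z] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + z * nxy] = d[z];
    }
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dim;
  return out;
}
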