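#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double BIG = 1e18;  // stands in for +inf; sqrt stays finite

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with grid step w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = w * q, xv = w * v[k];
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (k > 0 && s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = w * q;
    while (z[k + 1] < xq) ++k;
    double xv = w * v[k];
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact squared Euclidean distance (mm^2) from every voxel to the nearest
// feature voxel (mask != 0), honouring anisotropic spacing. Voxels unreachable
// (empty mask) come back as +Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> d((size_t)nx * ny * nz);
  bool any = false;
  for (size_t i = 0; i < d.size(); ++i) {
    d[i] = mask[i] ? 0.0 : BIG;
    if (mask[i]) any = true;
  }
  NumericVector out(d.size());
  if (!any) { std::fill(out.begin(), out.end(), R_PosInf); return out; }

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f, g, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) d[base + i] = g[i];
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = i + (size_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (size_t)nx * j];
      dt1d(f, g, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) d[base + (size_t)nx * j] = g[j];
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = i + (size_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = d[base + (size_t)nx * ny * k];
      dt1d(f, g, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) d[base + (size_t)nx * ny * k] = g[k];
    }
  for (size_t i = 0; i < d.size(); ++i)
    out[i] = (d[i] >= BIG * 0.5) ? R_PosInf : d[i];
  return out;
}
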