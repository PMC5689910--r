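#include <Rcpp.h>
#include <vector>
#include <cmath>

// Exact squared Euclidean distance transform, Felzenszwalb & Huttenlocher
// lower-envelope algorithm, run separably along each axis with per-axis
// sample spacing (mm). Cells with no source yet carry a large finite
// sentinel (far above any reachable squared distance) instead of infinity,
// which keeps the envelope arithmetic well defined.

static const double BIG = 1e15;

static void dt1d(std::vector<double> &f, double w) {
  const int n = (int)f.size();
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  std::vector<double> d(n);
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = +BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w * (q - p));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = +BIG;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < w * q) ++j;
    int p = v[j];
    double dq = w * (q - p);
    d[q] = dq * dq + f[p];
  }
  f.swap(d);
}

// [[Rcpp::export(name = ".edt_cpp")]]
Rcpp::NumericVector edt_cpp(Rcpp::LogicalVector mask,
                            Rcpp::IntegerVector dims,
                            Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> D((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = (mask[i] == TRUE) ? 0.0 : BIG;

  std::vector<double> line;
  // x axis
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) line[x] = D[base + x];
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; ++x) D[base + x] = line[x];
    }
  // y axis
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) line[y] = D[base + (R_xlen_t)y * nx];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) D[base + (R_xlen_t)y * nx] = line[y];
    }
  // z axis
  line.resize(nz);
  const R_xlen_t sliceN = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) line[z] = D[base + (R_xlen_t)z * sliceN];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; ++z) D[base + (R_xlen_t)z * sliceN] = line[z];
    }

  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (D[i] >= BIG * 0.5) ? R_PosInf : std::sqrt(D[i]);
  out.attr("dim") = dims;
  return out;
}
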