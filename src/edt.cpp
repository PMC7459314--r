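#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact squared Euclidean distance transform,
// one axis at a time.  `w` is the physical sample spacing along the axis,
// so anisotropic grids are handled by passing the per-axis pitch.
static const double DT_INF = 1e30;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double qq = q * w;
    double vv = v[k] * w;
    double s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) /
               (2.0 * qq - 2.0 * vv);
    while (s <= z[k]) {
      --k;
      vv = v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) /
          (2.0 * qq - 2.0 * vv);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * w;
    while (z[k + 1] < qq) ++k;
    double vv = v[k] * w;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Squared EDT of a binary mask: distance (um) from each foreground voxel to
// the nearest background voxel centre.  Array layout: dim = (n1, n2, n3)
// column-major, i.e. linear index = i1 + n1*(i2 + n2*i3).
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i)
    out[i] = mask[i] ? DT_INF : 0.0;

  long s1 = 1, s2 = n1, s3 = (long)n1 * n2;
  int n[3] = {n1, n2, n3};
  long s[3] = {s1, s2, s3};
  for (int axis = 0; axis < 3; ++axis) {
    int na = n[axis];
    long sa = s[axis];
    int b = (axis == 0) ? 1 : 0;
    int c = (axis == 2) ? 1 : 2;
    std::vector<double> f(na), d(na);
    for (int j = 0; j < n[c]; ++j) {
      for (int i = 0; i < n[b]; ++i) {
        long base = (long)i * s[b] + (long)j * s[c];
        for (int t = 0; t < na; ++t) f[t] = out[base + t * sa];
        dt1d(f, d, na, spacing[axis]);
        for (int t = 0; t < na; ++t) out[base + t * sa] = d[t];
      }
    }
  }
  for (R_xlen_t i = 0; i < ntot; ++i)
    out[i] = std::sqrt(out[i]);
  return out;
}
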