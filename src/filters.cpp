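#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  return k;
}

// reflect index into [0, n-1] (mirror boundary without repeating the edge
// sample's neighbour order issues; standard "reflect" a b c | c b a)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Separable Gaussian smoothing; sigma is in voxels per axis (order matching
// dim).  sigma[a] <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                NumericVector sigma) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> cur(vol.begin(), vol.end()), tmp(ntot);

  int n[3] = {n1, n2, n3};
  long s[3] = {1, n1, (long)n1 * n2};
  for (int axis = 0; axis < 3; ++axis) {
    if (sigma[axis] <= 0) continue;
    std::vector<double> k = gauss_kernel(sigma[axis]);
    int r = ((int)k.size() - 1) / 2;
    int na = n[axis];
    long sa = s[axis];
    int b = (axis == 0) ? 1 : 0;
    int c = (axis == 2) ? 1 : 2;
    for (int j = 0; j < n[c]; ++j) {
      for (int i = 0; i < n[b]; ++i) {
        long base = (long)i * s[b] + (long)j * s[c];
        for (int t = 0; t < na; ++t) {
          double acc = 0.0;
          for (int o = -r; o <= r; ++o) {
            int u = reflect_idx(t + o, na);
            acc += k[o + r] * cur[base + (long)u * sa];
          }
          tmp[base + (long)t * sa] = acc;
        }
      }
    }
    cur.swap(tmp);
  }
  return NumericVector(cur.begin(), cur.end());
}

// Central-difference gradient (one-sided at the borders), spacing in um per
// axis.  Returns a list of three arrays in axis order (d/daxis1, 2, 3).
// [[Rcpp::export]]
List cpp_gradient(NumericVector vol, IntegerVector dim, NumericVector spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  int n[3] = {n1, n2, n3};
  long s[3] = {1, n1, (long)n1 * n2};
  List out(3);
  for (int axis = 0; axis < 3; ++axis) {
    NumericVector g(ntot);
    int na = n[axis];
    long sa = s[axis];
    int b = (axis == 0) ? 1 : 0;
    int c = (axis == 2) ? 1 : 2;
    double w = spacing[axis];
    for (int j = 0; j < n[c]; ++j) {
      for (int i = 0; i < n[b]; ++i) {
        long base = (long)i * s[b] + (long)j * s[c];
        for (int t = 0; t < na; ++t) {
          double num;
          double den;
          if (na == 1) { num = 0.0; den = 1.0; }
          else if (t == 0) { num = vol[base + sa] - vol[base]; den = w; }
          else if (t == na - 1) {
            num = vol[base + (long)t * sa] - vol[base + (long)(t - 1) * sa];
            den = w;
          } else {
            num = vol[base + (long)(t + 1) * sa] - vol[base + (long)(t - 1) * sa];
            den = 2.0 * w;
          }
          g[base + (long)t * sa] = num / den;
        }
      }
    }
    g.attr("dim") = dim;
    out[axis] = g;
  }
  return out;
}

// Maximum over the 26-neighbourhood (plus centre), used for the
// ridge-corrected skeleton radius.
// [[Rcpp::export]]
NumericVector cpp_neighborhood_max(NumericVector vol, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(ntot);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        double m = -1e300;
        for (int dc = -1; dc <= 1; ++dc)
          for (int db = -1; db <= 1; ++db)
            for (int da = -1; da <= 1; ++da) {
              int a = i + da, b = j + db, c = k + dc;
              if (a < 0 || b < 0 || c < 0 || a >= n1 || b >= n2 || c >= n3)
                continue;
              double v = vol[a + (long)n1 * (b + (long)n2 * c)];
              if (v > m) m = v;
            }
        out[i + (long)n1 * (j + (long)n2 * k)] = m;
      }
  return out;
}
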