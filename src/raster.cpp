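#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rasterize capsules (cylinders with hemispherical caps): a voxel centre is
// foreground when it lies within `radius` of the segment p0-p1.  Coordinates
// are physical (um) in axis order matching dim; voxel centre of index i
// (0-based) sits at i * pitch.  Marks into (and returns) `mask`.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_capsules(LogicalVector mask, IntegerVector dim,
                                     double pitch, NumericMatrix p0,
                                     NumericMatrix p1, NumericVector radius) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  long s2 = n1, s3 = (long)n1 * n2;
  int nseg = p0.nrow();
  for (int sgm = 0; sgm < nseg; ++sgm) {
    double r = radius[sgm];
    double a1 = p0(sgm, 0), a2 = p0(sgm, 1), a3 = p0(sgm, 2);
    double b1 = p1(sgm, 0), b2 = p1(sgm, 1), b3 = p1(sgm, 2);
    double d1 = b1 - a1, d2 = b2 - a2, d3 = b3 - a3;
    double dd = d1 * d1 + d2 * d2 + d3 * d3;
    int lo1 = std::max(0, (int)std::floor((std::min(a1, b1) - r) / pitch));
    int lo2 = std::max(0, (int)std::floor((std::min(a2, b2) - r) / pitch));
    int lo3 = std::max(0, (int)std::floor((std::min(a3, b3) - r) / pitch));
    int hi1 = std::min(n1 - 1, (int)std::ceil((std::max(a1, b1) + r) / pitch));
    int hi2 = std::min(n2 - 1, (int)std::ceil((std::max(a2, b2) + r) / pitch));
    int hi3 = std::min(n3 - 1, (int)std::ceil((std::max(a3, b3) + r) / pitch));
    double r2 = r * r;
    for (int k = lo3; k <= hi3; ++k) {
      double z = k * pitch;
      for (int j = lo2; j <= hi2; ++j) {
        double y = j * pitch;
        for (int i = lo1; i <= hi1; ++i) {
          double x = i * pitch;
          double t = 0.0;
          if (dd > 0) {
            t = ((x - a1) * d1 + (y - a2) * d2 + (z - a3) * d3) / dd;
            if (t < 0) t = 0; else if (t > 1) t = 1;
          }
          double q1 = a1 + t * d1 - x;
          double q2 = a2 + t * d2 - y;
          double q3 = a3 + t * d3 - z;
          if (q1 * q1 + q2 * q2 + q3 * q3 <= r2)
            mask[i + j * s2 + k * s3] = true;
        }
      }
    }
  }
  return mask;
}

// Remove 26-connected components smaller than min_size voxels.
// [[Rcpp::export]]
LogicalVector cpp_filter_small(LogicalVector mask, IntegerVector dim,
                               int min_size) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  std::vector<int> label(ntot, 0);
  std::vector<long> stack;
  LogicalVector out(ntot);
  out.attr("dim") = dim;
  int cur = 0;
  for (R_xlen_t seed = 0; seed < ntot; ++seed) {
    if (!mask[seed] || label[seed]) continue;
    ++cur;
    stack.clear();
    stack.push_back(seed);
    label[seed] = cur;
    std::vector<long> members;
    while (!stack.empty()) {
      long id = stack.back();
      stack.pop_back();
      members.push_back(id);
      int i = (int)(id % n1), j = (int)((id / n1) % n2),
          k = (int)(id / ((long)n1 * n2));
      for (int dc = -1; dc <= 1; ++dc)
        for (int db = -1; db <= 1; ++db)
          for (int da = -1; da <= 1; ++da) {
            if (!da && !db && !dc) continue;
            int a = i + da, b = j + db, c = k + dc;
            if (a < 0 || b < 0 || c < 0 || a >= n1 || b >= n2 || c >= n3)
              continue;
            long nid = a + (long)n1 * (b + (long)n2 * c);
            if (mask[nid] && !label[nid]) {
              label[nid] = cur;
              stack.push_back(nid);
            }
          }
    }
    if ((int)members.size() >= min_size)
      for (size_t m = 0; m < members.size(); ++m) out[members[m]] = true;
  }
  return out;
}
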