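#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Distance-ordered homotopic thinning with directional border cycling.
//
// Voxels are processed in layers of increasing distance-transform value, so
// the skeleton settles on the medial ridge.  Inside a layer the border is
// eroded one 6-direction at a time (U/D/N/S/E/W cycling, repeated until the
// layer is stable), which erodes structures symmetrically: without this a
// sequential scan can consume an even-width tube longitudinally from one
// end.  A voxel is deleted only when it is simple (Bertrand-Malandain
// characterization: exactly one 26-component of foreground in the punctured
// 3x3x3 neighbourhood and exactly one 6-component of background in the
// 18-neighbourhood touching a face neighbour) and not a curve endpoint
// (fewer than two foreground 26-neighbours).  Deterministic: fixed layer,
// direction and index order.

namespace {

struct Vol {
  const int n1, n2, n3;
  std::vector<unsigned char> fg;
  Vol(int a, int b, int c) : n1(a), n2(b), n3(c), fg((size_t)a * b * c, 0) {}
  inline long idx(int i, int j, int k) const {
    return (long)i + (long)n1 * ((long)j + (long)n2 * k);
  }
  inline bool at(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= n1 || j >= n2 || k >= n3) return false;
    return fg[idx(i, j, k)] != 0;
  }
};

inline int lidx(int a, int b, int c) { return a + 3 * (b + 3 * c); }

int count_fg26(const Vol& v, int i, int j, int k) {
  int cnt = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da) {
        if (da == 0 && db == 0 && dc == 0) continue;
        if (v.at(i + da, j + db, k + dc)) ++cnt;
      }
  return cnt;
}

bool is_simple(const Vol& v, int i, int j, int k) {
  bool L[27];
  for (int dc = -1; dc <= 1; ++dc)
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da)
        L[lidx(da + 1, db + 1, dc + 1)] = v.at(i + da, j + db, k + dc);

  // one 26-component of foreground in N26 minus the centre
  bool seen[27] = {false};
  int ncomp = 0;
  for (int c0 = 0; c0 < 27; ++c0) {
    if (c0 == 13 || !L[c0] || seen[c0]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    int stack[27], sp = 0;
    stack[sp++] = c0;
    seen[c0] = true;
    while (sp) {
      int c = stack[--sp];
      int ca = c % 3, cb = (c / 3) % 3, cc = c / 9;
      for (int dc = -1; dc <= 1; ++dc)
        for (int db = -1; db <= 1; ++db)
          for (int da = -1; da <= 1; ++da) {
            int na = ca + da, nb = cb + db, nc = cc + dc;
            if (na < 0 || nb < 0 || nc < 0 || na > 2 || nb > 2 || nc > 2)
              continue;
            int n = lidx(na, nb, nc);
            if (n == 13 || n == c || seen[n] || !L[n]) continue;
            seen[n] = true;
            stack[sp++] = n;
          }
    }
  }
  if (ncomp != 1) return false;

  // one 6-component of background in N18 touching a face neighbour
  auto inN18 = [](int c) {
    if (c == 13) return false;
    int ca = c % 3, cb = (c / 3) % 3, cc = c / 9;
    int m = std::abs(ca - 1) + std::abs(cb - 1) + std::abs(cc - 1);
    return m >= 1 && m <= 2;
  };
  auto isFace = [](int c) {
    int ca = c % 3, cb = (c / 3) % 3, cc = c / 9;
    return std::abs(ca - 1) + std::abs(cb - 1) + std::abs(cc - 1) == 1;
  };
  bool seenB[27] = {false};
  int nbg = 0;
  for (int c0 = 0; c0 < 27; ++c0) {
    if (!inN18(c0) || L[c0] || seenB[c0] || !isFace(c0)) continue;
    ++nbg;
    if (nbg > 1) return false;
    int stack[27], sp = 0;
    stack[sp++] = c0;
    seenB[c0] = true;
    while (sp) {
      int c = stack[--sp];
      int ca = c % 3, cb = (c / 3) % 3, cc = c / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int t = 0; t < 6; ++t) {
        int na = ca + d6[t][0], nb = cb + d6[t][1], nc = cc + d6[t][2];
        if (na < 0 || nb < 0 || nc < 0 || na > 2 || nb > 2 || nc > 2) continue;
        int n = lidx(na, nb, nc);
        if (!inN18(n) || L[n] || seenB[n]) continue;
        seenB[n] = true;
        stack[sp++] = n;
      }
    }
  }
  return nbg == 1;
}

const int DIR6[6][3] = {
  {-1, 0, 0}, {1, 0, 0}, {0, -1, 0}, {0, 1, 0}, {0, 0, -1}, {0, 0, 1}};

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim,
                              NumericVector dist) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  Vol v(n1, n2, n3);
  R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  std::vector<long> fg_idx;
  for (R_xlen_t i = 0; i < ntot; ++i)
    if (mask[i]) { v.fg[i] = 1; fg_idx.push_back((long)i); }

  // ascending distance layers (values grouped at 1e-6 resolution)
  std::vector<double> vals;
  vals.reserve(fg_idx.size());
  for (size_t t = 0; t < fg_idx.size(); ++t) vals.push_back(dist[fg_idx[t]]);
  std::vector<double> layers(vals);
  std::sort(layers.begin(), layers.end());
  layers.erase(std::unique(layers.begin(), layers.end(),
                           [](double a, double b) { return std::fabs(a - b) < 1e-6; }),
               layers.end());
  // order candidate voxels by (distance layer, linear index)
  std::stable_sort(fg_idx.begin(), fg_idx.end(),
                   [&](long a, long b) {
                     if (std::fabs(dist[a] - dist[b]) >= 1e-6)
                       return dist[a] < dist[b];
                     return a < b;
                   });

  std::vector<long> active;
  size_t next = 0;
  for (size_t li = 0; li < layers.size(); ++li) {
    double lv = layers[li] + 1e-6;
    while (next < fg_idx.size() && dist[fg_idx[next]] <= lv)
      active.push_back(fg_idx[next++]);
    bool changed = true;
    while (changed) {
      changed = false;
      for (int d = 0; d < 6; ++d) {
        // 8 parity subfields: candidates within a sub-pass are pairwise
        // non-adjacent, so sequential deletion cannot cascade along a
        // structure within one sub-pass
        for (int sf = 0; sf < 8; ++sf) {
          for (size_t t = 0; t < active.size(); ++t) {
            long id = active[t];
            if (!v.fg[id]) continue;
            int i = (int)(id % n1), j = (int)((id / n1) % n2),
                k = (int)(id / ((long)n1 * n2));
            if (((i & 1) | ((j & 1) << 1) | ((k & 1) << 2)) != sf) continue;
            // must be a border voxel open towards direction d
            if (v.at(i + DIR6[d][0], j + DIR6[d][1], k + DIR6[d][2])) continue;
            if (count_fg26(v, i, j, k) < 2) continue;  // curve endpoint
            if (!is_simple(v, i, j, k)) continue;
            v.fg[id] = 0;
            changed = true;
          }
        }
      }
    }
    // compact the survivor list
    size_t w = 0;
    for (size_t t = 0; t < active.size(); ++t)
      if (v.fg[active[t]]) active[w++] = active[t];
    active.resize(w);
  }

  LogicalVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = v.fg[i] != 0;
  out.attr("dim") = dim;
  return out;
}
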