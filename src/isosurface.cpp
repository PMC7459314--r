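#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Isosurface area by marching tetrahedra.  Each grid cell is split into the
// six Kuhn tetrahedra around the main diagonal; the level surface inside a
// tetrahedron of a (tri)linearly interpolated field is planar, so the
// per-tet triangulation has no ambiguous cases.  Positions are scaled by the
// per-axis spacing (um), so the returned area is in um^2.

namespace {

struct P3 { double x, y, z; };

inline P3 lerp(const P3& a, const P3& b, double va, double vb, double level) {
  double t = (level - va) / (vb - va);
  P3 p;
  p.x = a.x + t * (b.x - a.x);
  p.y = a.y + t * (b.y - a.y);
  p.z = a.z + t * (b.z - a.z);
  return p;
}

inline double tri_area(const P3& a, const P3& b, const P3& c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// cube corner offsets (axis1, axis2, axis3)
const int CUBE[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
// Kuhn triangulation: six tetrahedra sharing the 0-6 diagonal
const int TETS[6][4] = {
  {0,1,2,6},{0,1,5,6},{0,3,2,6},{0,3,7,6},{0,4,5,6},{0,4,7,6}};

double tet_area(const P3 p[4], const double v[4], double level) {
  bool above[4];
  int na = 0;
  for (int i = 0; i < 4; ++i) { above[i] = v[i] > level; if (above[i]) ++na; }
  if (na == 0 || na == 4) return 0.0;
  int A[4], B[4], ia = 0, ib = 0;
  for (int i = 0; i < 4; ++i) (above[i] ? A[ia++] : B[ib++]) = i;
  if (na == 1 || na == 3) {
    int apex = (na == 1) ? A[0] : B[0];
    const int* oth = (na == 1) ? B : A;
    P3 e0 = lerp(p[apex], p[oth[0]], v[apex], v[oth[0]], level);
    P3 e1 = lerp(p[apex], p[oth[1]], v[apex], v[oth[1]], level);
    P3 e2 = lerp(p[apex], p[oth[2]], v[apex], v[oth[2]], level);
    return tri_area(e0, e1, e2);
  }
  // na == 2: quad across the four mixed edges, split into two triangles
  P3 e00 = lerp(p[A[0]], p[B[0]], v[A[0]], v[B[0]], level);
  P3 e01 = lerp(p[A[0]], p[B[1]], v[A[0]], v[B[1]], level);
  P3 e11 = lerp(p[A[1]], p[B[1]], v[A[1]], v[B[1]], level);
  P3 e10 = lerp(p[A[1]], p[B[0]], v[A[1]], v[B[0]], level);
  return tri_area(e00, e01, e11) + tri_area(e00, e11, e10);
}

} // namespace

// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector vol, IntegerVector dim, double level,
                           NumericVector spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  long s1 = 1, s2 = n1, s3 = (long)n1 * n2;
  double total = 0.0;
  double w1 = spacing[0], w2 = spacing[1], w3 = spacing[2];
  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        double cv[8];
        P3 cp[8];
        bool any_above = false, any_below = false;
        for (int c = 0; c < 8; ++c) {
          int a = i + CUBE[c][0], b = j + CUBE[c][1], d = k + CUBE[c][2];
          cv[c] = vol[a * s1 + b * s2 + d * s3];
          cp[c].x = a * w1; cp[c].y = b * w2; cp[c].z = d * w3;
          if (cv[c] > level) any_above = true; else any_below = true;
        }
        if (!any_above || !any_below) continue;
        for (int t = 0; t < 6; ++t) {
          P3 tp[4];
          double tv[4];
          for (int m = 0; m < 4; ++m) {
            tp[m] = cp[TETS[t][m]];
            tv[m] = cv[TETS[t][m]];
          }
          total += tet_area(tp, tv, level);
        }
      }
  return total;
}
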