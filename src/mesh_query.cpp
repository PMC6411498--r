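#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Spatial queries against triangle meshes: closest point on surface
// (uniform-grid accelerated) and barycentric point location in a planar
// triangulation (bucket grid).

namespace {

struct Vec3 { double x, y, z; };
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x+b.x, a.y+b.y, a.z+b.z}; }
inline Vec3 operator*(double s, Vec3 a) { return {s*a.x, s*a.y, s*a.z}; }
inline double dot(Vec3 a, Vec3 b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

// Ericson's closest point on triangle
Vec3 closest_on_tri(Vec3 p, Vec3 a, Vec3 b, Vec3 c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) { double v = d1 / (d1 - d3); return a + v * ab; }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) { double w = d2 / (d2 - d6); return a + w * ac; }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + v * ab + w * ac;
}

} // namespace

// For each query point, closest point on the mesh surface.
// Returns list(points = n x 3, dist = n, face = n 1-based).
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  // uniform grid over mesh bbox
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf; hi[d] = R_NegInf;
    for (int i = 0; i < V.nrow(); ++i) {
      lo[d] = std::min(lo[d], V(i,d)); hi[d] = std::max(hi[d], V(i,d));
    }
  }
  int res = std::max(1, (int)std::floor(std::cbrt((double)nf / 2.0)));
  res = std::min(res, 64);
  double cell[3];
  for (int d = 0; d < 3; ++d) {
    double ext = hi[d] - lo[d];
    cell[d] = (ext > 0 ? ext / res : 1.0);
  }
  auto cidx = [&](double v, int d) {
    int c = (int)std::floor((v - lo[d]) / cell[d]);
    return std::min(std::max(c, 0), res - 1);
  };
  std::vector<std::vector<int>> buckets((size_t)res * res * res);
  for (int f = 0; f < nf; ++f) {
    double bl[3], bh[3];
    for (int d = 0; d < 3; ++d) {
      bl[d] = std::min({V(F(f,0)-1,d), V(F(f,1)-1,d), V(F(f,2)-1,d)});
      bh[d] = std::max({V(F(f,0)-1,d), V(F(f,1)-1,d), V(F(f,2)-1,d)});
    }
    for (int k = cidx(bl[2],2); k <= cidx(bh[2],2); ++k)
      for (int j = cidx(bl[1],1); j <= cidx(bh[1],1); ++j)
        for (int i = cidx(bl[0],0); i <= cidx(bh[0],0); ++i)
          buckets[i + (size_t)res * (j + (size_t)res * k)].push_back(f);
  }
  NumericMatrix CP(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  double mincell = std::min({cell[0], cell[1], cell[2]});
  for (int q = 0; q < np; ++q) {
    Vec3 p = {P(q,0), P(q,1), P(q,2)};
    int ci = cidx(p.x,0), cj = cidx(p.y,1), ck = cidx(p.z,2);
    double best = R_PosInf; Vec3 bp = p; int bf = -1;
    for (int ring = 0; ring < 2 * res; ++ring) {
      if (bf >= 0 && best < (double)(ring - 1) * mincell * (ring - 1) * mincell)
        break;
      bool any = false;
      for (int k = std::max(0,ck-ring); k <= std::min(res-1,ck+ring); ++k)
        for (int j = std::max(0,cj-ring); j <= std::min(res-1,cj+ring); ++j)
          for (int i = std::max(0,ci-ring); i <= std::min(res-1,ci+ring); ++i) {
            if (std::max({std::abs(i-ci), std::abs(j-cj), std::abs(k-ck)}) != ring)
              continue;
            any = true;
            for (int f : buckets[i + (size_t)res * (j + (size_t)res * k)]) {
              Vec3 a = {V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2)};
              Vec3 b = {V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2)};
              Vec3 c = {V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2)};
              Vec3 cp = closest_on_tri(p, a, b, c);
              double d2 = dot(cp - p, cp - p);
              if (d2 < best) { best = d2; bp = cp; bf = f; }
            }
          }
      if (!any && ring > res) break;
    }
    CP(q,0) = bp.x; CP(q,1) = bp.y; CP(q,2) = bp.z;
    dist[q] = std::sqrt(best);
    face[q] = bf + 1;
  }
  return List::create(_["points"] = CP, _["dist"] = dist, _["face"] = face);
}

// Locate 2D points in a planar triangulation.  T is nf x 6: (x1,y1,x2,y2,x3,y3)
// per triangle.  Returns list(face 1-based or NA, bary nf x 3, fallback_face,
// fallback_dist): a point not strictly inside any triangle (beyond tol) gets
// face = NA and its nearest triangle recorded as fallback with clamped
// barycentrics.
// [[Rcpp::export]]
List cpp_locate_points2d(NumericMatrix T, NumericMatrix P, double tol) {
  const int nf = T.nrow(), np = P.nrow();
  double lo0 = R_PosInf, hi0 = R_NegInf, lo1 = R_PosInf, hi1 = R_NegInf;
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) {
      lo0 = std::min(lo0, T(f, 2*c)); hi0 = std::max(hi0, T(f, 2*c));
      lo1 = std::min(lo1, T(f, 2*c+1)); hi1 = std::max(hi1, T(f, 2*c+1));
    }
  int res = std::max(4, (int)std::floor(std::sqrt((double)nf)));
  res = std::min(res, 512);
  double cw0 = (hi0 > lo0 ? (hi0 - lo0) / res : 1.0);
  double cw1 = (hi1 > lo1 ? (hi1 - lo1) / res : 1.0);
  auto ci = [&](double v, double lo, double cw) {
    int c = (int)std::floor((v - lo) / cw);
    return std::min(std::max(c, 0), res - 1);
  };
  std::vector<std::vector<int>> buckets((size_t)res * res);
  for (int f = 0; f < nf; ++f) {
    double bl0 = std::min({T(f,0), T(f,2), T(f,4)}), bh0 = std::max({T(f,0), T(f,2), T(f,4)});
    double bl1 = std::min({T(f,1), T(f,3), T(f,5)}), bh1 = std::max({T(f,1), T(f,3), T(f,5)});
    for (int j = ci(bl1, lo1, cw1); j <= ci(bh1, lo1, cw1); ++j)
      for (int i = ci(bl0, lo0, cw0); i <= ci(bh0, lo0, cw0); ++i)
        buckets[i + (size_t)res * j].push_back(f);
  }
  IntegerVector face(np, NA_INTEGER), fb_face(np, NA_INTEGER);
  NumericMatrix bary(np, 3);
  NumericVector fb_dist(np, NA_REAL);
  for (int q = 0; q < np; ++q) {
    double px = P(q,0), py = P(q,1);
    int bi = ci(px, lo0, cw0), bj = ci(py, lo1, cw1);
    bool found = false;
    double best = R_PosInf; int bestf = -1; double bb[3] = {0,0,0};
    int maxring = res;
    for (int ring = 0; ring <= maxring && !found; ++ring) {
      for (int j = std::max(0,bj-ring); j <= std::min(res-1,bj+ring) && !found; ++j)
        for (int i = std::max(0,bi-ring); i <= std::min(res-1,bi+ring) && !found; ++i) {
          if (std::max(std::abs(i-bi), std::abs(j-bj)) != ring) continue;
          for (int f : buckets[i + (size_t)res * j]) {
            double x1 = T(f,0), y1 = T(f,1), x2 = T(f,2), y2 = T(f,3),
                   x3 = T(f,4), y3 = T(f,5);
            double det = (x2-x1)*(y3-y1) - (x3-x1)*(y2-y1);
            if (det == 0.0) continue;
            double l1 = ((y2-y3)*(px-x3) + (x3-x2)*(py-y3)) / det;
            double l2 = ((y3-y1)*(px-x3) + (x1-x3)*(py-y3)) / det;
            double l3 = 1.0 - l1 - l2;
            if (l1 >= -tol && l2 >= -tol && l3 >= -tol) {
              face[q] = f + 1;
              bary(q,0) = l1; bary(q,1) = l2; bary(q,2) = l3;
              found = true; break;
            }
            // distance proxy: most negative barycentric, scaled
            double neg = std::min({l1, l2, l3});
            double d = -neg;
            if (d < best) {
              best = d; bestf = f;
              bb[0] = std::max(l1, 0.0); bb[1] = std::max(l2, 0.0);
              bb[2] = std::max(l3, 0.0);
            }
          }
        }
      // after finishing ring 2 without a hit, accept the fallback
      if (!found && ring >= 2 && bestf >= 0) break;
    }
    if (!found && bestf >= 0) {
      double s = bb[0] + bb[1] + bb[2];
      fb_face[q] = bestf + 1;
      bary(q,0) = bb[0]/s; bary(q,1) = bb[1]/s; bary(q,2) = bb[2]/s;
      fb_dist[q] = best;
    }
  }
  return List::create(_["face"] = face, _["bary"] = bary,
                      _["fallback_face"] = fb_face, _["fallback_dist"] = fb_dist);
}
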