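#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// Isosurface of a scalar grid by marching tetrahedra (6-tet cube split along
// the main diagonal).  Watertight by construction: every interior cube face
// carries the same diagonal in adjacent cubes, and shared tet faces agree.
// Vertices are emitted on grid edges by linear interpolation and welded via
// an edge->vertex map, so the output is a closed 2-manifold whenever no
// sample equals the level exactly (guaranteed for binary data at level 0.5).

namespace {

struct EdgeKey {
  int a, b;
  EdgeKey(int x, int y) : a(std::min(x, y)), b(std::max(x, y)) {}
  bool operator<(const EdgeKey& o) const {
    return a < o.a || (a == o.a && b < o.b);
  }
};

// corner offsets of the unit cube, numbered so tets below share edge 0-6
const int CUBE[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
};

// triangle table for a positively oriented tet; mask bit i = vertex i inside
// (value >= level); entries are pairs of tet-vertex indices (edges), -1 ends.
// Orientation gives outward (inside-to-outside) CCW normals.
const int TRI[16][13] = {
  {-1},                                                    // 0000
  {0,1, 0,2, 0,3, -1},                                     // 0001 in:{0}
  {1,0, 1,3, 1,2, -1},                                     // 0010 in:{1}
  {0,2, 0,3, 1,3,  0,2, 1,3, 1,2, -1},                     // 0011 in:{0,1}
  {2,0, 2,1, 2,3, -1},                                     // 0100 in:{2}
  {0,3, 0,1, 2,1,  0,3, 2,1, 2,3, -1},                     // 0101 in:{0,2}
  {1,0, 1,3, 2,3,  1,0, 2,3, 2,0, -1},                     // 0110 in:{1,2}
  {3,0, 3,1, 3,2, -1},                                     // 0111 out:{3}
  {3,0, 3,2, 3,1, -1},                                     // 1000 in:{3}
  {0,1, 0,2, 3,2,  0,1, 3,2, 3,1, -1},                     // 1001 in:{0,3}
  {1,2, 1,0, 3,0,  1,2, 3,0, 3,2, -1},                     // 1010 in:{1,3}
  {2,0, 2,3, 2,1, -1},                                     // 1011 out:{2}
  {2,0, 2,1, 3,1,  2,0, 3,1, 3,0, -1},                     // 1100 in:{2,3}
  {1,0, 1,2, 1,3, -1},                                     // 1101 out:{1}
  {0,1, 0,3, 0,2, -1},                                     // 1110 out:{0}
  {-1}                                                     // 1111
};

} // namespace

// vol: 3D numeric array (nx x ny x nz), sampled at voxel centres.
// Returns list(vertices = n x 3 (voxel index coordinates, 0-based),
//              faces = m x 3 (1-based)).
// [[Rcpp::export]]
List cpp_isosurface(NumericVector vol, IntegerVector dim, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto val = [&](int i, int j, int k) -> double {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
    return vol[i + nx * (j + (R_xlen_t)ny * k)];
  };
  auto vid = [&](int i, int j, int k) -> int {
    // padded index space (-1 .. n) mapped to non-negative linear ids
    return (i + 1) + (nx + 2) * ((j + 1) + (ny + 2) * (k + 1));
  };

  std::map<EdgeKey, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  double cv[8];
  int cid[8];
  double cx[8], cy[8], cz[8];

  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CUBE[c][0], jj = j + CUBE[c][1], kk = k + CUBE[c][2];
          cv[c] = val(ii, jj, kk);
          cid[c] = vid(ii, jj, kk);
          cx[c] = ii; cy[c] = jj; cz[c] = kk;
          (cv[c] >= level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int m = 0;
          for (int c = 0; c < 4; ++c)
            if (cv[TETS[t][c]] >= level) m |= (1 << c);
          const int* row = TRI[m];
          for (int e = 0; row[e] != -1; e += 2) {
            int a = TETS[t][row[e]], b = TETS[t][row[e + 1]];
            EdgeKey key(cid[a], cid[b]);
            auto it = edge_vertex.find(key);
            int idx;
            if (it == edge_vertex.end()) {
              double tpar = (level - cv[a]) / (cv[b] - cv[a]);
              vx.push_back(cx[a] + tpar * (cx[b] - cx[a]));
              vy.push_back(cy[a] + tpar * (cy[b] - cy[a]));
              vz.push_back(cz[a] + tpar * (cz[b] - cz[a]));
              idx = (int)vx.size() - 1;
              edge_vertex[key] = idx;
            } else idx = it->second;
            tri.push_back(idx);
          }
        }
      }

  int nvert = (int)vx.size(), nface = (int)tri.size() / 3;
  NumericMatrix V(nvert, 3);
  for (int q = 0; q < nvert; ++q) { V(q,0)=vx[q]; V(q,1)=vy[q]; V(q,2)=vz[q]; }
  IntegerMatrix F(nface, 3);
  for (int q = 0; q < nface; ++q) {
    F(q,0) = tri[3*q] + 1; F(q,1) = tri[3*q+1] + 1; F(q,2) = tri[3*q+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// 26-connected component labelling of a logical 3D array.
// Returns integer array of labels (0 = background), labelled 1..n by
// decreasing voxel count (label 1 is always the largest component).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  std::vector<R_xlen_t> sizes_idx; std::vector<int> sizes;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!vol[s] || lab[s]) continue;
    ++next;
    int count = 0;
    stack.push_back(s); lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back(); ++count;
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t q = ii + nx * (jj + (R_xlen_t)ny * kk);
            if (vol[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
    sizes.push_back(count);
  }
  // relabel by decreasing size
  std::vector<int> order(next);
  for (int q = 0; q < next; ++q) order[q] = q;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> rank(next);
  for (int q = 0; q < next; ++q) rank[order[q]] = q + 1;
  for (R_xlen_t s = 0; s < n; ++s) if (lab[s]) lab[s] = rank[lab[s] - 1];
  lab.attr("dim") = dim;
  return lab;
}

// Voxelize the interior of a closed mesh: for every (x,y) voxel column,
// accumulate ray crossings along z by scanline triangle intersection, then
// parity-fill voxel centres.  origin = world position of voxel (0,0,0)
// centre; spacing = per-axis voxel size.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_mesh(NumericMatrix V, IntegerMatrix F,
                                 IntegerVector dim, NumericVector origin,
                                 NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // tiny irrational jitter keeps ray origins off triangle edges
  const double jx = 2.0e-7 * spacing[0], jy = 3.0e-7 * spacing[1];
  std::vector<std::vector<double>> cross((R_xlen_t)nx * ny);
  for (int f = 0; f < F.nrow(); ++f) {
    double x1 = V(F(f,0)-1,0), y1 = V(F(f,0)-1,1), z1 = V(F(f,0)-1,2);
    double x2 = V(F(f,1)-1,0), y2 = V(F(f,1)-1,1), z2 = V(F(f,1)-1,2);
    double x3 = V(F(f,2)-1,0), y3 = V(F(f,2)-1,1), z3 = V(F(f,2)-1,2);
    double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
    if (det == 0.0) continue; // projected degenerate (vertical face)
    double xmin = std::min({x1,x2,x3}), xmax = std::max({x1,x2,x3});
    double ymin = std::min({y1,y2,y3}), ymax = std::max({y1,y2,y3});
    int i0 = std::max(0, (int)std::ceil((xmin - origin[0] - jx) / spacing[0]));
    int i1 = std::min(nx-1, (int)std::floor((xmax - origin[0] - jx) / spacing[0]));
    int j0 = std::max(0, (int)std::ceil((ymin - origin[1] - jy) / spacing[1]));
    int j1 = std::min(ny-1, (int)std::floor((ymax - origin[1] - jy) / spacing[1]));
    for (int j = j0; j <= j1; ++j) {
      double py = origin[1] + j * spacing[1] + jy;
      for (int i = i0; i <= i1; ++i) {
        double px = origin[0] + i * spacing[0] + jx;
        double l1 = ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det;
        double l2 = ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det;
        double l3 = 1.0 - l1 - l2;
        if (l1 < 0 || l2 < 0 || l3 < 0) continue;
        cross[i + (R_xlen_t)nx * j].push_back(l1 * z1 + l2 * z2 + l3 * z3);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx * ny * nz, FALSE);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      auto& zs = cross[i + (R_xlen_t)nx * j];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      for (size_t q = 0; q + 1 < zs.size(); q += 2) {
        // half-open [enter, exit): a centre exactly on the exit face is out
        int k0 = std::max(0, (int)std::ceil((zs[q] - origin[2]) / spacing[2]));
        int k1 = std::min(nz - 1,
                          (int)std::ceil((zs[q+1] - origin[2]) / spacing[2]) - 1);
        for (int k = k0; k <= k1; ++k)
          out[i + nx * (j + (R_xlen_t)ny * k)] = TRUE;
      }
    }
  out.attr("dim") = dim;
  return out;
}
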