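#include <Rcpp.h>
#include <queue>
#include <set>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Quadric-error-metric edge-collapse decimation for closed manifold triangle
// meshes.  Collapses the cheapest valid edge until the target vertex count is
// reached.  Validity: link condition (manifold preservation, hence Euler
// characteristic preservation on closed meshes) and a normal-flip rejection.

namespace {

struct Quadric {
  // symmetric 4x4 stored as upper triangle (10 terms)
  double q[10] = {0,0,0,0,0,0,0,0,0,0};
  void add_plane(double a, double b, double c, double d, double w) {
    q[0]+=w*a*a; q[1]+=w*a*b; q[2]+=w*a*c; q[3]+=w*a*d;
    q[4]+=w*b*b; q[5]+=w*b*c; q[6]+=w*b*d;
    q[7]+=w*c*c; q[8]+=w*c*d; q[9]+=w*d*d;
  }
  void add(const Quadric& o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(double x, double y, double z) const {
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z + q[9];
  }
  // minimise: solve [A b; 0 1], returns false if near-singular
  bool optimal(double& x, double& y, double& z) const {
    double a11=q[0], a12=q[1], a13=q[2], a22=q[4], a23=q[5], a33=q[7];
    double b1=-q[3], b2=-q[6], b3=-q[8];
    double det = a11*(a22*a33-a23*a23) - a12*(a12*a33-a23*a13)
               + a13*(a12*a23-a22*a13);
    double scale = std::abs(a11)+std::abs(a22)+std::abs(a33);
    if (std::abs(det) < 1e-10 * scale * scale * scale || scale == 0) return false;
    x = (b1*(a22*a33-a23*a23) - a12*(b2*a33-a23*b3) + a13*(b2*a23-a22*b3)) / det;
    y = (a11*(b2*a33-a23*b3) - b1*(a12*a33-a23*a13) + a13*(a12*b3-b2*a13)) / det;
    z = (a11*(a22*b3-b2*a23) - a12*(a12*b3-b2*a13) + b1*(a12*a23-a22*a13)) / det;
    return true;
  }
};

struct HeapItem {
  double cost; int a, b; long stamp;
  bool operator<(const HeapItem& o) const { return cost > o.cost; } // min-heap
};

} // namespace

// [[Rcpp::export]]
List cpp_decimate_qem(NumericMatrix Vin, IntegerMatrix Fin, int target) {
  const int nv0 = Vin.nrow(), nf0 = Fin.nrow();
  std::vector<std::array<double,3>> V(nv0);
  for (int i = 0; i < nv0; ++i) V[i] = {Vin(i,0), Vin(i,1), Vin(i,2)};
  std::vector<std::array<int,3>> F(nf0);
  for (int f = 0; f < nf0; ++f) F[f] = {Fin(f,0)-1, Fin(f,1)-1, Fin(f,2)-1};
  std::vector<bool> vdead(nv0, false), fdead(nf0, false);
  std::vector<std::set<int>> vfaces(nv0);
  for (int f = 0; f < nf0; ++f)
    for (int c = 0; c < 3; ++c) vfaces[F[f][c]].insert(f);

  // initial quadrics
  std::vector<Quadric> Q(nv0);
  auto face_plane = [&](int f, double* abcda) {
    auto& t = F[f];
    double ux = V[t[1]][0]-V[t[0]][0], uy = V[t[1]][1]-V[t[0]][1], uz = V[t[1]][2]-V[t[0]][2];
    double wx = V[t[2]][0]-V[t[0]][0], wy = V[t[2]][1]-V[t[0]][1], wz = V[t[2]][2]-V[t[0]][2];
    double nx = uy*wz - uz*wy, ny = uz*wx - ux*wz, nz = ux*wy - uy*wx;
    double a2 = std::sqrt(nx*nx + ny*ny + nz*nz);
    abcda[4] = 0.5 * a2; // area
    if (a2 == 0) { abcda[0]=abcda[1]=abcda[2]=abcda[3]=0; return; }
    nx/=a2; ny/=a2; nz/=a2;
    abcda[0]=nx; abcda[1]=ny; abcda[2]=nz;
    abcda[3] = -(nx*V[t[0]][0] + ny*V[t[0]][1] + nz*V[t[0]][2]);
  };
  for (int f = 0; f < nf0; ++f) {
    double pl[5]; face_plane(f, pl);
    for (int c = 0; c < 3; ++c) Q[F[f][c]].add_plane(pl[0],pl[1],pl[2],pl[3],pl[4]);
  }

  std::vector<long> vstamp(nv0, 0);
  std::priority_queue<HeapItem> heap;
  auto neighbors = [&](int v) {
    std::set<int> nb;
    for (int f : vfaces[v]) for (int c = 0; c < 3; ++c)
      if (F[f][c] != v) nb.insert(F[f][c]);
    return nb;
  };
  auto edge_cost = [&](int a, int b, double* pos) {
    Quadric q = Q[a]; q.add(Q[b]);
    double x, y, z;
    if (!q.optimal(x, y, z)) {
      // best of endpoints / midpoint
      double mx = 0.5*(V[a][0]+V[b][0]), my = 0.5*(V[a][1]+V[b][1]), mz = 0.5*(V[a][2]+V[b][2]);
      double ca = q.eval(V[a][0],V[a][1],V[a][2]);
      double cb = q.eval(V[b][0],V[b][1],V[b][2]);
      double cm = q.eval(mx,my,mz);
      if (cm <= ca && cm <= cb) { x=mx; y=my; z=mz; }
      else if (ca <= cb) { x=V[a][0]; y=V[a][1]; z=V[a][2]; }
      else { x=V[b][0]; y=V[b][1]; z=V[b][2]; }
    }
    pos[0]=x; pos[1]=y; pos[2]=z;
    return q.eval(x, y, z);
  };
  auto push_edges_of = [&](int v) {
    for (int u : neighbors(v)) {
      int a = std::min(u, v), b = std::max(u, v);
      double pos[3];
      double c = edge_cost(a, b, pos);
      heap.push({c, a, b, vstamp[a] + vstamp[b]});
    }
  };
  for (int v = 0; v < nv0; ++v) {
    for (int u : neighbors(v)) if (u > v) {
      double pos[3]; double c = edge_cost(v, u, pos);
      heap.push({c, v, u, 0});
    }
  }

  int nv = nv0;
  while (nv > target && !heap.empty()) {
    HeapItem it = heap.top(); heap.pop();
    int a = it.a, b = it.b;
    if (vdead[a] || vdead[b]) continue;
    if (it.stamp != vstamp[a] + vstamp[b]) continue; // stale
    // still an edge?
    bool isedge = false;
    for (int f : vfaces[a]) {
      auto& t = F[f];
      if (t[0]==b || t[1]==b || t[2]==b) { isedge = true; break; }
    }
    if (!isedge) continue;
    // link condition: common neighbors == opposite vertices of shared faces
    std::set<int> na = neighbors(a), nb = neighbors(b), common;
    for (int u : na) if (nb.count(u)) common.insert(u);
    std::set<int> opp;
    for (int f : vfaces[a]) {
      auto& t = F[f];
      if (t[0]==b || t[1]==b || t[2]==b)
        for (int c = 0; c < 3; ++c) if (t[c]!=a && t[c]!=b) opp.insert(t[c]);
    }
    if (common != opp || opp.size() != 2) continue;
    // candidate position
    double pos[3]; edge_cost(a, b, pos);
    // normal-flip check on surviving faces around a and b
    bool flip = false;
    std::array<double,3> olda = V[a], oldb = V[b];
    for (int pass = 0; pass < 2 && !flip; ++pass) {
      int v = pass == 0 ? a : b;
      for (int f : vfaces[v]) {
        auto& t = F[f];
        if (t[0]==a||t[1]==a||t[2]==a) { if (t[0]==b||t[1]==b||t[2]==b) continue; }
        double p[3][3];
        for (int c = 0; c < 3; ++c)
          for (int d = 0; d < 3; ++d) p[c][d] = V[t[c]][d];
        double n0[3], n1[3];
        auto cross_of = [&](double pp[3][3], double* n) {
          double ux=pp[1][0]-pp[0][0], uy=pp[1][1]-pp[0][1], uz=pp[1][2]-pp[0][2];
          double wx=pp[2][0]-pp[0][0], wy=pp[2][1]-pp[0][1], wz=pp[2][2]-pp[0][2];
          n[0]=uy*wz-uz*wy; n[1]=uz*wx-ux*wz; n[2]=ux*wy-uy*wx;
        };
        cross_of(p, n0);
        for (int c = 0; c < 3; ++c)
          if (t[c] == v) { p[c][0]=pos[0]; p[c][1]=pos[1]; p[c][2]=pos[2]; }
        cross_of(p, n1);
        if (n0[0]*n1[0] + n0[1]*n1[1] + n0[2]*n1[2] <= 0) { flip = true; break; }
      }
    }
    if (flip) continue;
    // collapse b into a
    V[a] = {pos[0], pos[1], pos[2]};
    Q[a].add(Q[b]);
    std::vector<int> gone;
    for (int f : vfaces[a]) {
      auto& t = F[f];
      if (t[0]==b || t[1]==b || t[2]==b) gone.push_back(f);
    }
    for (int f : gone) {
      fdead[f] = true;
      for (int c = 0; c < 3; ++c) vfaces[F[f][c]].erase(f);
    }
    for (int f : std::vector<int>(vfaces[b].begin(), vfaces[b].end())) {
      auto& t = F[f];
      for (int c = 0; c < 3; ++c) if (t[c] == b) t[c] = a;
      vfaces[b].erase(f);
      vfaces[a].insert(f);
    }
    vdead[b] = true;
    --nv;
    ++vstamp[a];
    push_edges_of(a);
    (void)olda; (void)oldb;
  }

  // compact
  std::vector<int> vmap(nv0, -1);
  int nvout = 0;
  for (int v = 0; v < nv0; ++v) if (!vdead[v]) vmap[v] = nvout++;
  NumericMatrix Vout(nvout, 3);
  for (int v = 0; v < nv0; ++v)
    if (!vdead[v]) for (int d = 0; d < 3; ++d) Vout(vmap[v], d) = V[v][d];
  int nfout = 0;
  for (int f = 0; f < nf0; ++f) if (!fdead[f]) ++nfout;
  IntegerMatrix Fout(nfout, 3);
  int fi = 0;
  for (int f = 0; f < nf0; ++f)
    if (!fdead[f]) {
      for (int c = 0; c < 3; ++c) Fout(fi, c) = vmap[F[f][c]] + 1;
      ++fi;
    }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout,
                      _["achieved"] = nvout);
}
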