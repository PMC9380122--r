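#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Iso-surface + interior tetrahedralization of a scalar field in one pass.
//
// Each grid cube is split into the six Freudenthal tetrahedra (all sharing
// the main diagonal, so faces agree between neighbouring cubes). Every
// background tetrahedron is clipped against the iso-level: the part of it on
// the "inside" (field > level) is emitted as 1..3 tetrahedra and the cut
// polygon becomes surface triangles. Vertices are deduplicated globally
// (grid vertices by index, edge-cut vertices by the sorted grid-vertex pair),
// so the surface is watertight and the tet mesh conforms to it: the boundary
// faces of the tet mesh are exactly the surface triangles.
//
// Where the clip creates a quadrilateral on a face shared by two background
// tetrahedra, the diagonal is chosen from the inside corner with the smaller
// global id. Ordering the inside corners by decreasing global id makes the
// fixed decompositions below realize exactly that rule, so the two sides of
// every shared face are triangulated identically (conforming mesh).

struct MeshAcc {
  std::vector<double> nodes;             // xyz interleaved
  std::unordered_map<long long, int> gridNode;
  std::unordered_map<long long, int> edgeNode;
  std::vector<int> tets;                 // 4 node ids per tet (0-based)
  std::vector<int> tris;                 // 3 node ids per surface tri
  const double* field;
  int nx, ny, nz;
  double ox, oy, oz, sx, sy, sz;
  double level;

  long long gid(int i, int j, int k) const {
    return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
  }
  void gidToXyz(long long g, double* p) const {
    int i = (int)(g % nx);
    int j = (int)((g / nx) % ny);
    int k = (int)(g / ((long long)nx * ny));
    p[0] = ox + sx * i; p[1] = oy + sy * j; p[2] = oz + sz * k;
  }
  double fval(long long g) const {
    double v = field[g];
    return (v == level) ? level - 1e-9 : v;
  }
  int nodeOfGrid(long long g) {
    auto it = gridNode.find(g);
    if (it != gridNode.end()) return it->second;
    double p[3]; gidToXyz(g, p);
    int id = (int)(nodes.size() / 3);
    nodes.insert(nodes.end(), p, p + 3);
    gridNode[g] = id;
    return id;
  }
  int nodeOfCut(long long ga, long long gb) {
    long long a = std::min(ga, gb), b = std::max(ga, gb);
    long long key = a * (long long)nx * ny * nz + b;
    auto it = edgeNode.find(key);
    if (it != edgeNode.end()) return it->second;
    double fa = fval(a), fb = fval(b);
    double t = (level - fa) / (fb - fa);
    // snap away from the grid nodes: avoids sliver elements whose height
    // would vanish (the surface is later refined by vertex projection)
    if (t < 0.05) t = 0.05;
    if (t > 0.95) t = 0.95;
    double pa[3], pb[3];
    gidToXyz(a, pa); gidToXyz(b, pb);
    int id = (int)(nodes.size() / 3);
    for (int c = 0; c < 3; ++c)
      nodes.push_back(pa[c] + t * (pb[c] - pa[c]));
    edgeNode[key] = id;
    return id;
  }
  void pushTet(int a, int b, int c, int d) {
    tets.push_back(a); tets.push_back(b); tets.push_back(c); tets.push_back(d);
  }
  // surface triangle oriented so its normal points away from refPoint (inside)
  void pushTri(int a, int b, int c, const double* ref) {
    const double* pa = &nodes[3 * a];
    const double* pb = &nodes[3 * b];
    const double* pc = &nodes[3 * c];
    double u[3] = {pb[0]-pa[0], pb[1]-pa[1], pb[2]-pa[2]};
    double v[3] = {pc[0]-pa[0], pc[1]-pa[1], pc[2]-pa[2]};
    double n[3] = {u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0]};
    double cen[3] = {(pa[0]+pb[0]+pc[0])/3 - ref[0],
                     (pa[1]+pb[1]+pc[1])/3 - ref[1],
                     (pa[2]+pb[2]+pc[2])/3 - ref[2]};
    double dot = n[0]*cen[0] + n[1]*cen[1] + n[2]*cen[2];
    if (dot < 0) std::swap(b, c);
    tris.push_back(a); tris.push_back(b); tris.push_back(c);
  }

  void handleTet(long long g[4]) {
    bool in[4];
    int nin = 0;
    for (int v = 0; v < 4; ++v) { in[v] = fval(g[v]) > level; if (in[v]) ++nin; }
    if (nin == 0) return;
    // inside / outside corners, each ordered by decreasing global id
    long long ins[4], outs[4];
    int ni = 0, no = 0;
    for (int v = 0; v < 4; ++v) (in[v] ? ins[ni++] : outs[no++]) = g[v];
    std::sort(ins, ins + ni, std::greater<long long>());
    std::sort(outs, outs + no, std::greater<long long>());

    if (nin == 4) {
      pushTet(nodeOfGrid(ins[0]), nodeOfGrid(ins[1]),
              nodeOfGrid(ins[2]), nodeOfGrid(ins[3]));
      return;
    }
    double ref[3] = {0, 0, 0};
    for (int v = 0; v < ni; ++v) {
      double p[3]; gidToXyz(ins[v], p);
      ref[0] += p[0] / ni; ref[1] += p[1] / ni; ref[2] += p[2] / ni;
    }
    if (nin == 1) {
      int A  = nodeOfGrid(ins[0]);
      int AB = nodeOfCut(ins[0], outs[0]);
      int AC = nodeOfCut(ins[0], outs[1]);
      int AD = nodeOfCut(ins[0], outs[2]);
      pushTet(A, AB, AC, AD);
      pushTri(AB, AC, AD, ref);
    } else if (nin == 3) {
      int A = nodeOfGrid(ins[0]), B = nodeOfGrid(ins[1]), C = nodeOfGrid(ins[2]);
      int AD = nodeOfCut(ins[0], outs[0]);
      int BD = nodeOfCut(ins[1], outs[0]);
      int CD = nodeOfCut(ins[2], outs[0]);
      pushTet(A, B, C, AD);
      pushTet(B, C, AD, BD);
      pushTet(C, AD, BD, CD);
      pushTri(AD, BD, CD, ref);
    } else {  // nin == 2: prism (a,P,Q)/(b,R,S)
      int A = nodeOfGrid(ins[0]), B = nodeOfGrid(ins[1]);
      int P = nodeOfCut(ins[0], outs[0]);
      int Q = nodeOfCut(ins[0], outs[1]);
      int R = nodeOfCut(ins[1], outs[0]);
      int S = nodeOfCut(ins[1], outs[1]);
      pushTet(A, P, Q, B);
      pushTet(P, Q, B, R);
      pushTet(Q, B, R, S);
      pushTri(P, Q, R, ref);
      pushTri(Q, R, S, ref);
    }
  }
};

// [[Rcpp::export]]
List cpp_mesh_field(NumericVector field, IntegerVector dims,
                    NumericVector origin, NumericVector spacing,
                    double level) {
  MeshAcc acc;
  acc.field = field.begin();
  acc.nx = dims[0]; acc.ny = dims[1]; acc.nz = dims[2];
  acc.ox = origin[0]; acc.oy = origin[1]; acc.oz = origin[2];
  acc.sx = spacing[0]; acc.sy = spacing[1]; acc.sz = spacing[2];
  acc.level = level;

  // six Freudenthal tetrahedra of the unit cube: paths 000 -> 111
  static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  for (int k = 0; k + 1 < acc.nz; ++k)
    for (int j = 0; j + 1 < acc.ny; ++j)
      for (int i = 0; i + 1 < acc.nx; ++i)
        for (int t = 0; t < 6; ++t) {
          int off[4][3] = {{0,0,0},{0,0,0},{0,0,0},{1,1,1}};
          off[1][perms[t][0]] = 1;
          off[2][perms[t][0]] = 1;
          off[2][perms[t][1]] = 1;
          long long g[4];
          for (int v = 0; v < 4; ++v)
            g[v] = acc.gid(i + off[v][0], j + off[v][1], k + off[v][2]);
          acc.handleTet(g);
        }

  int nn = (int)(acc.nodes.size() / 3);
  NumericMatrix nodes(nn, 3);
  for (int v = 0; v < nn; ++v)
    for (int c = 0; c < 3; ++c) nodes(v, c) = acc.nodes[3 * v + c];

  int nt = (int)(acc.tets.size() / 4);
  IntegerMatrix tets(nt, 4);
  // enforce positive signed volume
  for (int t = 0; t < nt; ++t) {
    int id[4];
    for (int v = 0; v < 4; ++v) id[v] = acc.tets[4 * t + v];
    const double* p0 = &acc.nodes[3 * id[0]];
    double m[3][3];
    for (int v = 0; v < 3; ++v)
      for (int c = 0; c < 3; ++c)
        m[v][c] = acc.nodes[3 * id[v + 1] + c] - p0[c];
    double det = m[0][0]*(m[1][1]*m[2][2]-m[1][2]*m[2][1])
               - m[0][1]*(m[1][0]*m[2][2]-m[1][2]*m[2][0])
               + m[0][2]*(m[1][0]*m[2][1]-m[1][1]*m[2][0]);
    if (det < 0) std::swap(id[2], id[3]);
    for (int v = 0; v < 4; ++v) tets(t, v) = id[v] + 1;
  }

  int ns = (int)(acc.tris.size() / 3);
  IntegerMatrix tris(ns, 3);
  LogicalVector isSurf(nn);
  for (int t = 0; t < ns; ++t)
    for (int v = 0; v < 3; ++v) {
      tris(t, v) = acc.tris[3 * t + v] + 1;
      isSurf[acc.tris[3 * t + v]] = true;
    }

  return List::create(_["nodes"] = nodes, _["tets"] = tets,
                      _["tris"] = tris, _["is_surface"] = isSurf);
}
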