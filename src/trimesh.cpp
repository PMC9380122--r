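#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Voxelize a closed triangle mesh on a regular grid: a voxel is inside iff
// its center is inside the surface, decided by z-ray crossing parity.
// Column positions are jittered by a sub-micron irrational offset so rays
// never pass exactly through mesh edges or vertices.
// [[Rcpp::export]]
LogicalVector cpp_voxelize_mesh(NumericMatrix verts, IntegerMatrix tris,
                                IntegerVector dims, NumericVector origin,
                                NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double jx = 4.12e-5 * spacing[0], jy = 2.71e-5 * spacing[1];
  std::vector<std::vector<double>> hits((size_t)nx * ny);

  for (int t = 0; t < tris.nrow(); ++t) {
    double ax = verts(tris(t,0)-1, 0), ay = verts(tris(t,0)-1, 1), az = verts(tris(t,0)-1, 2);
    double bx = verts(tris(t,1)-1, 0), by = verts(tris(t,1)-1, 1), bz = verts(tris(t,1)-1, 2);
    double cx = verts(tris(t,2)-1, 0), cy = verts(tris(t,2)-1, 1), cz = verts(tris(t,2)-1, 2);
    double xmin = std::min(ax, std::min(bx, cx)), xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    int i0 = (int)std::ceil((xmin - jx - origin[0]) / spacing[0]);
    int i1 = (int)std::floor((xmax - jx - origin[0]) / spacing[0]);
    int j0 = (int)std::ceil((ymin - jy - origin[1]) / spacing[1]);
    int j1 = (int)std::floor((ymax - jy - origin[1]) / spacing[1]);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    double d = (bx-ax)*(cy-ay) - (cx-ax)*(by-ay);   // 2*signed area in xy
    if (d == 0) continue;                            // parallel to z
    for (int j = j0; j <= j1; ++j) {
      double y = origin[1] + spacing[1] * j + jy;
      for (int i = i0; i <= i1; ++i) {
        double x = origin[0] + spacing[0] * i + jx;
        double l1 = ((x-ax)*(cy-ay) - (cx-ax)*(y-ay)) / d;
        double l2 = ((bx-ax)*(y-ay) - (x-ax)*(by-ay)) / d;
        double l0 = 1.0 - l1 - l2;
        if (l0 < 0 || l1 < 0 || l2 < 0) continue;
        hits[(size_t)i + (size_t)nx * j].push_back(l0*az + l1*bz + l2*cz);
      }
    }
  }

  LogicalVector out((size_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      auto& h = hits[(size_t)i + (size_t)nx * j];
      if (h.empty()) continue;
      std::sort(h.begin(), h.end());
      // fill between consecutive crossing pairs
      for (size_t m = 0; m + 1 < h.size(); m += 2) {
        int k0 = (int)std::ceil((h[m] - origin[2]) / spacing[2]);
        int k1 = (int)std::floor((h[m+1] - origin[2]) / spacing[2]);
        k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
        for (int k = k0; k <= k1; ++k)
          out[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = true;
      }
    }
  return out;
}

static void closestOnTri(const double* p, const double* a, const double* b,
                         const double* c, double* out, double* bary) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i]=b[i]-a[i]; ac[i]=c[i]-a[i]; ap[i]=p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; bary[0]=1;bary[1]=0;bary[2]=0; return; }
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; bary[0]=0;bary[1]=1;bary[2]=0; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i]=a[i]+v*ab[i];
    bary[0]=1-v; bary[1]=v; bary[2]=0; return;
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; bary[0]=0;bary[1]=0;bary[2]=1; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i]=a[i]+w*ac[i];
    bary[0]=1-w; bary[1]=0; bary[2]=w; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i]=b[i]+w*(c[i]-b[i]);
    bary[0]=0; bary[1]=1-w; bary[2]=w; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i]=a[i]+ab[i]*v+ac[i]*w;
  bary[0]=1-v-w; bary[1]=v; bary[2]=w;
}

// Closest point on a triangle mesh for each query point.
// Returns closest points, distances, 1-based triangle index and barycentric
// coordinates of the foot point.
// [[Rcpp::export]]
List cpp_closest_point_mesh(NumericMatrix points, NumericMatrix verts,
                            IntegerMatrix tris) {
  const int np = points.nrow(), nt = tris.nrow();
  NumericMatrix cp(np, 3), bary(np, 3);
  NumericVector dist(np);
  IntegerVector tri(np);
  // per-triangle bounding boxes for pruning
  std::vector<double> bb(6 * nt);
  for (int t = 0; t < nt; ++t) {
    for (int c = 0; c < 3; ++c) {
      double v0 = verts(tris(t,0)-1, c), v1 = verts(tris(t,1)-1, c), v2 = verts(tris(t,2)-1, c);
      bb[6*t + c]     = std::min(v0, std::min(v1, v2));
      bb[6*t + 3 + c] = std::max(v0, std::max(v1, v2));
    }
  }
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = {points(ip,0), points(ip,1), points(ip,2)};
    double best = R_PosInf, bestPt[3] = {0,0,0}, bestBary[3] = {0,0,0};
    int bestT = -1;
    for (int t = 0; t < nt; ++t) {
      // lower bound on distance from box
      double lb = 0;
      for (int c = 0; c < 3; ++c) {
        double d = std::max(bb[6*t+c] - p[c], p[c] - bb[6*t+3+c]);
        if (d > 0) lb += d * d;
      }
      if (lb >= best) continue;
      double a[3] = {verts(tris(t,0)-1,0), verts(tris(t,0)-1,1), verts(tris(t,0)-1,2)};
      double b[3] = {verts(tris(t,1)-1,0), verts(tris(t,1)-1,1), verts(tris(t,1)-1,2)};
      double c3[3] = {verts(tris(t,2)-1,0), verts(tris(t,2)-1,1), verts(tris(t,2)-1,2)};
      double q[3], w[3];
      closestOnTri(p, a, b, c3, q, w);
      double d2 = 0;
      for (int c = 0; c < 3; ++c) d2 += (q[c]-p[c])*(q[c]-p[c]);
      if (d2 < best) {
        best = d2; bestT = t;
        for (int c = 0; c < 3; ++c) { bestPt[c] = q[c]; bestBary[c] = w[c]; }
      }
    }
    dist[ip] = std::sqrt(best);
    tri[ip] = bestT + 1;
    for (int c = 0; c < 3; ++c) { cp(ip,c) = bestPt[c]; bary(ip,c) = bestBary[c]; }
  }
  return List::create(_["point"] = cp, _["dist"] = dist, _["tri"] = tri,
                      _["bary"] = bary);
}

// Barycentric interpolation of per-node vectors at query points inside a tet
// mesh. Points in no tet get inside = FALSE (values 0). A uniform spatial
// hash over tet bounding boxes keeps lookup near O(1).
// [[Rcpp::export]]
List cpp_interp_tet(NumericMatrix nodes, IntegerMatrix tets,
                    NumericMatrix vals, NumericMatrix points) {
  const int nt = tets.nrow(), np = points.nrow(), nv = vals.ncol();
  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) {
    lo[c] = R_PosInf; hi[c] = R_NegInf;
    for (int i = 0; i < nodes.nrow(); ++i) {
      lo[c] = std::min(lo[c], nodes(i, c));
      hi[c] = std::max(hi[c], nodes(i, c));
    }
  }
  // cell size ~ mean tet bbox edge
  double cell = 1.0;
  {
    double s = 0;
    for (int t = 0; t < std::min(nt, 200); ++t) {
      for (int c = 0; c < 3; ++c) {
        double mn = R_PosInf, mx = R_NegInf;
        for (int v = 0; v < 4; ++v) {
          mn = std::min(mn, nodes(tets(t,v)-1, c));
          mx = std::max(mx, nodes(tets(t,v)-1, c));
        }
        s += mx - mn;
      }
    }
    cell = std::max(s / (3.0 * std::min(nt, 200)), 1e-6);
  }
  int gx = std::max(1, (int)((hi[0]-lo[0])/cell) + 1);
  int gy = std::max(1, (int)((hi[1]-lo[1])/cell) + 1);
  int gz = std::max(1, (int)((hi[2]-lo[2])/cell) + 1);
  std::vector<std::vector<int>> bins((size_t)gx * gy * gz);
  for (int t = 0; t < nt; ++t) {
    int c0[3], c1[3];
    for (int c = 0; c < 3; ++c) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int v = 0; v < 4; ++v) {
        mn = std::min(mn, nodes(tets(t,v)-1, c));
        mx = std::max(mx, nodes(tets(t,v)-1, c));
      }
      c0[c] = std::max(0, (int)((mn - lo[c]) / cell));
      c1[c] = std::min((c==0?gx:(c==1?gy:gz)) - 1, (int)((mx - lo[c]) / cell));
    }
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          bins[(size_t)i + (size_t)gx * (j + (size_t)gy * k)].push_back(t);
  }

  NumericMatrix out(np, nv);
  LogicalVector inside(np);
  const double eps = 1e-8;
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = {points(ip,0), points(ip,1), points(ip,2)};
    int ci = (int)((p[0]-lo[0])/cell), cj = (int)((p[1]-lo[1])/cell), ck = (int)((p[2]-lo[2])/cell);
    if (ci < 0 || cj < 0 || ck < 0 || ci >= gx || cj >= gy || ck >= gz) continue;
    const auto& cand = bins[(size_t)ci + (size_t)gx * (cj + (size_t)gy * ck)];
    for (int t : cand) {
      const double* p0 = &nodes(0,0);  // column-major access below
      double a[3], m[3][3];
      for (int c = 0; c < 3; ++c) {
        a[c] = nodes(tets(t,0)-1, c);
        for (int v = 0; v < 3; ++v) m[c][v] = nodes(tets(t,v+1)-1, c) - a[c];
      }
      (void)p0;
      double det = m[0][0]*(m[1][1]*m[2][2]-m[1][2]*m[2][1])
                 - m[0][1]*(m[1][0]*m[2][2]-m[1][2]*m[2][0])
                 + m[0][2]*(m[1][0]*m[2][1]-m[1][1]*m[2][0]);
      if (std::fabs(det) < 1e-30) continue;
      double r[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
      // Cramer
      double l1 = (r[0]*(m[1][1]*m[2][2]-m[1][2]*m[2][1])
                 - m[0][1]*(r[1]*m[2][2]-m[1][2]*r[2])
                 + m[0][2]*(r[1]*m[2][1]-m[1][1]*r[2])) / det;
      double l2 = (m[0][0]*(r[1]*m[2][2]-r[2]*m[1][2])
                 - r[0]*(m[1][0]*m[2][2]-m[1][2]*m[2][0])
                 + m[0][2]*(m[1][0]*r[2]-r[1]*m[2][0])) / det;
      double l3 = (m[0][0]*(m[1][1]*r[2]-r[1]*m[2][1])
                 - m[0][1]*(m[1][0]*r[2]-r[1]*m[2][0])
                 + r[0]*(m[1][0]*m[2][1]-m[1][1]*m[2][0])) / det;
      double l0 = 1.0 - l1 - l2 - l3;
      if (l0 >= -eps && l1 >= -eps && l2 >= -eps && l3 >= -eps) {
        for (int c = 0; c < nv; ++c)
          out(ip, c) = l0 * vals(tets(t,0)-1, c) + l1 * vals(tets(t,1)-1, c)
                     + l2 * vals(tets(t,2)-1, c) + l3 * vals(tets(t,3)-1, c);
        inside[ip] = true;
        break;
      }
    }
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Feature-augmented closest point: for each query point, choose the target
// vertex minimizing |p - v|^2 + w^2 (f_p - f_v)^2, then return the
// geometric closest point on the triangles incident to that vertex. Keeps
// the result on the target surface while steering tangentially toward
// matching surface features (e.g. curvature).
// [[Rcpp::export]]
List cpp_closest_point_feature(NumericMatrix points, NumericVector pfeat,
                               NumericMatrix verts, NumericVector vfeat,
                               IntegerMatrix tris, double w) {
  const int np = points.nrow(), nv = verts.nrow(), nt = tris.nrow();
  // incident triangles per vertex (CSR)
  std::vector<int> cnt(nv, 0);
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 3; ++k) cnt[tris(t, k) - 1]++;
  std::vector<int> off(nv + 1, 0);
  for (int v = 0; v < nv; ++v) off[v + 1] = off[v] + cnt[v];
  std::vector<int> inc(off[nv]);
  std::vector<int> fill(nv, 0);
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 3; ++k) {
      int v = tris(t, k) - 1;
      inc[off[v] + fill[v]++] = t;
    }

  NumericMatrix cp(np, 3);
  NumericVector dist(np);
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = {points(ip,0), points(ip,1), points(ip,2)};
    double fp = pfeat[ip];
    double best = R_PosInf;
    int bv = 0;
    for (int v = 0; v < nv; ++v) {
      double df = fp - vfeat[v];
      double d2 = w * w * df * df;
      if (d2 >= best) continue;
      for (int c = 0; c < 3; ++c) {
        double d = p[c] - verts(v, c);
        d2 += d * d;
        if (d2 >= best) break;
      }
      if (d2 < best) { best = d2; bv = v; }
    }
    // geometric projection onto the triangles around the chosen vertex
    double bq[3] = {verts(bv,0), verts(bv,1), verts(bv,2)};
    double bd = R_PosInf;
    for (int j = off[bv]; j < off[bv + 1]; ++j) {
      int t = inc[j];
      double a[3] = {verts(tris(t,0)-1,0), verts(tris(t,0)-1,1), verts(tris(t,0)-1,2)};
      double b[3] = {verts(tris(t,1)-1,0), verts(tris(t,1)-1,1), verts(tris(t,1)-1,2)};
      double c3[3] = {verts(tris(t,2)-1,0), verts(tris(t,2)-1,1), verts(tris(t,2)-1,2)};
      double q[3], wb[3];
      closestOnTri(p, a, b, c3, q, wb);
      double d2 = 0;
      for (int c = 0; c < 3; ++c) d2 += (q[c]-p[c])*(q[c]-p[c]);
      if (d2 < bd) { bd = d2; for (int c = 0; c < 3; ++c) bq[c] = q[c]; }
    }
    for (int c = 0; c < 3; ++c) cp(ip, c) = bq[c];
    dist[ip] = std::sqrt(bd);
  }
  return List::create(_["point"] = cp, _["dist"] = dist);
}
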