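// 3-D convex hull volume by the quickhull algorithm. Kept fully
// independent of the Delaunay code: used as a cross-check that the
// alpha complex converges to the convex hull as alpha grows.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Face {
  int v[3];
  int nb[3];            // neighbour across edge (v[i], v[(i+1)%3])
  double n[3], d;       // plane: n . x = d, n outward (not normalized)
  std::vector<int> outside;
  bool alive;
};

struct Hull {
  const double* pts;
  int n;
  double eps;
  std::vector<Face> faces;

  const double* P(int i) const { return pts + 3 * i; }

  void plane(Face& f) const {
    const double* a = P(f.v[0]);
    const double* b = P(f.v[1]);
    const double* c = P(f.v[2]);
    double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double w[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    f.n[0] = u[1] * w[2] - u[2] * w[1];
    f.n[1] = u[2] * w[0] - u[0] * w[2];
    f.n[2] = u[0] * w[1] - u[1] * w[0];
    f.d = f.n[0] * a[0] + f.n[1] * a[1] + f.n[2] * a[2];
  }

  double dist(const Face& f, int p) const {
    const double* q = P(p);
    return f.n[0] * q[0] + f.n[1] * q[1] + f.n[2] * q[2] - f.d;
  }
};

}  // namespace

// [[Rcpp::export(name = ".convex_hull_volume_cpp")]]
double convex_hull_volume_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<double> P(3 * n);
  double lo[3], hi[3];
  for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      double v = pts(i, j);
      if (!R_finite(v)) stop("non-finite coordinate");
      P[3 * i + j] = v;
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  double diag = 0;
  for (int j = 0; j < 3; ++j) diag += (hi[j] - lo[j]) * (hi[j] - lo[j]);
  diag = std::sqrt(diag);
  if (diag <= 0) return 0.0;

  Hull H;
  H.pts = P.data();
  H.n = n;
  H.eps = 1e-12 * diag * diag;  // distance scale of n . x - d (area*length)

  // initial simplex: extreme pair, farthest from line, farthest from plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (P[3 * i] < P[3 * i0]) i0 = i;
    if (P[3 * i] > P[3 * i1]) i1 = i;
  }
  if (i0 == i1) i1 = (i0 + 1) % n;
  const double* a = &P[3 * i0];
  const double* b = &P[3 * i1];
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  int i2 = -1; double best = -1;
  for (int i = 0; i < n; ++i) {
    const double* q = &P[3 * i];
    double aq[3] = {q[0] - a[0], q[1] - a[1], q[2] - a[2]};
    double cx = ab[1] * aq[2] - ab[2] * aq[1];
    double cy = ab[2] * aq[0] - ab[0] * aq[2];
    double cz = ab[0] * aq[1] - ab[1] * aq[0];
    double d = cx * cx + cy * cy + cz * cz;
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= 0) return 0.0;
  Face f0;
  f0.v[0] = i0; f0.v[1] = i1; f0.v[2] = i2;
  H.plane(f0);
  int i3 = -1; best = 0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(H.dist(f0, i));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0 || best <= H.eps) return 0.0;  // coplanar input

  // build the 4 outward faces of the initial tetrahedron
  int vv[4] = {i0, i1, i2, i3};
  const int FI[4][3] = {{0, 1, 2}, {0, 3, 1}, {1, 3, 2}, {2, 3, 0}};
  for (int fi = 0; fi < 4; ++fi) {
    Face f;
    f.v[0] = vv[FI[fi][0]]; f.v[1] = vv[FI[fi][1]]; f.v[2] = vv[FI[fi][2]];
    f.alive = true;
    H.plane(f);
    // orient away from the remaining vertex
    int other = -1;
    for (int k = 0; k < 4; ++k) {
      bool inF = false;
      for (int m = 0; m < 3; ++m) if (f.v[m] == vv[k]) inF = true;
      if (!inF) { other = vv[k]; break; }
    }
    if (H.dist(f, other) > 0) { std::swap(f.v[1], f.v[2]); H.plane(f); }
    H.faces.push_back(f);
  }
  // neighbour links by shared (undirected) edges
  for (int fi = 0; fi < 4; ++fi)
    for (int e = 0; e < 3; ++e) {
      int u = H.faces[fi].v[e], w = H.faces[fi].v[(e + 1) % 3];
      for (int fj = 0; fj < 4; ++fj) {
        if (fj == fi) continue;
        for (int e2 = 0; e2 < 3; ++e2) {
          int u2 = H.faces[fj].v[e2], w2 = H.faces[fj].v[(e2 + 1) % 3];
          if ((u == u2 && w == w2) || (u == w2 && w == u2))
            H.faces[fi].nb[e] = fj;
        }
      }
    }
  // assign outside sets
  for (int i = 0; i < n; ++i) {
    for (size_t fi = 0; fi < H.faces.size(); ++fi)
      if (H.dist(H.faces[fi], i) > H.eps) {
        H.faces[fi].outside.push_back(i);
        break;
      }
  }

  std::vector<int> pending;
  for (int fi = 0; fi < 4; ++fi)
    if (!H.faces[fi].outside.empty()) pending.push_back(fi);

  while (!pending.empty()) {
    int fi = pending.back(); pending.pop_back();
    Face& f = H.faces[fi];
    if (!f.alive || f.outside.empty()) continue;
    int far = -1; double bd = -1;
    for (size_t k = 0; k < f.outside.size(); ++k) {
      double d = H.dist(f, f.outside[k]);
      if (d > bd) { bd = d; far = f.outside[k]; }
    }
    // visible faces (BFS from fi)
    std::vector<int> visible;
    std::vector<int> st;
    st.push_back(fi);
    std::vector<char> seen(H.faces.size(), 0);
    seen[fi] = 1;
    while (!st.empty()) {
      int id = st.back(); st.pop_back();
      visible.push_back(id);
      for (int e = 0; e < 3; ++e) {
        int nb = H.faces[id].nb[e];
        if (nb < 0 || seen[nb] || !H.faces[nb].alive) continue;
        if (H.dist(H.faces[nb], far) > H.eps) { seen[nb] = 1; st.push_back(nb); }
      }
    }
    // horizon edges: edges of visible faces whose neighbour is not visible
    struct HEdge { int u, w, ext, extEdge; };
    std::vector<HEdge> horizon;
    for (size_t k = 0; k < visible.size(); ++k) {
      Face& vf = H.faces[visible[k]];
      for (int e = 0; e < 3; ++e) {
        int nb = vf.nb[e];
        if (nb >= 0 && seen[nb]) continue;
        HEdge he;
        he.u = vf.v[e]; he.w = vf.v[(e + 1) % 3];
        he.ext = nb;
        he.extEdge = -1;
        if (nb >= 0) {
          Face& ef = H.faces[nb];
          for (int e2 = 0; e2 < 3; ++e2) {
            int u2 = ef.v[e2], w2 = ef.v[(e2 + 1) % 3];
            if ((u2 == he.w && w2 == he.u)) he.extEdge = e2;
          }
        }
        horizon.push_back(he);
      }
    }
    // gather orphaned outside points
    std::vector<int> orphans;
    for (size_t k = 0; k < visible.size(); ++k) {
      Face& vf = H.faces[visible[k]];
      orphans.insert(orphans.end(), vf.outside.begin(), vf.outside.end());
      vf.outside.clear();
      vf.alive = false;
    }
    // new faces (u, w, far) per horizon edge
    std::vector<int> created;
    for (size_t k = 0; k < horizon.size(); ++k) {
      Face nf;
      nf.v[0] = horizon[k].u; nf.v[1] = horizon[k].w; nf.v[2] = far;
      nf.alive = true;
      H.plane(nf);
      nf.nb[0] = horizon[k].ext;
      nf.nb[1] = -1; nf.nb[2] = -1;
      int id = (int)H.faces.size();
      H.faces.push_back(nf);
      created.push_back(id);
      if (horizon[k].ext >= 0 && horizon[k].extEdge >= 0)
        H.faces[horizon[k].ext].nb[horizon[k].extEdge] = id;
    }
    // link new faces around far: edge (w, far) of one matches (far, u)=edge2
    for (size_t k = 0; k < created.size(); ++k)
      for (size_t m = 0; m < created.size(); ++m) {
        if (k == m) continue;
        Face& fk = H.faces[created[k]];
        Face& fm = H.faces[created[m]];
        // fk edge1 = (v1, far); fm edge2 = (far, v0)
        if (fk.v[1] == fm.v[0]) { fk.nb[1] = created[m]; fm.nb[2] = created[k]; }
      }
    // reassign orphans
    for (size_t k = 0; k < orphans.size(); ++k) {
      int pt = orphans[k];
      if (pt == far) continue;
      for (size_t m = 0; m < created.size(); ++m)
        if (H.dist(H.faces[created[m]], pt) > H.eps) {
          H.faces[created[m]].outside.push_back(pt);
          break;
        }
    }
    for (size_t m = 0; m < created.size(); ++m)
      if (!H.faces[created[m]].outside.empty()) pending.push_back(created[m]);
  }

  // signed volume from the origin over outward faces
  double vol = 0;
  for (size_t fi = 0; fi < H.faces.size(); ++fi) {
    const Face& f = H.faces[fi];
    if (!f.alive) continue;
    const double* p0 = H.P(f.v[0]);
    const double* p1 = H.P(f.v[1]);
    const double* p2 = H.P(f.v[2]);
    vol += (p0[0] * (p1[1] * p2[2] - p1[2] * p2[1])
          - p0[1] * (p1[0] * p2[2] - p1[2] * p2[0])
          + p0[2] * (p1[0] * p2[1] - p1[1] * p2[0])) / 6.0;
  }
  return std::fabs(vol);
}
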