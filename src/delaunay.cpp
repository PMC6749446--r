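// Incremental (Bowyer-Watson) Delaunay tetrahedralization with a single
// infinite vertex, so the finite tetrahedra exactly partition the convex
// hull of the input points. Degenerate/inconsistent configurations throw;
// the R wrapper retries with a deterministic jitter.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const int INF_V = -2;  // sentinel for the infinite vertex
const int NONE = -1;

struct Tet {
  int v[4];    // vertex ids; infinite tets keep INF_V in slot 3
  int nb[4];   // neighbour tet across the face opposite v[i]
  double cc[3];
  double r2;   // squared circumradius (finite tets only)
  bool alive;
};

struct Delaunay {
  const double* pts;  // n x 3, row-major
  int n;
  std::vector<Tet> tets;
  std::vector<int> freed;
  double eps_o;   // orientation tolerance (length^3 scale)
  double eps_s;   // in-sphere tolerance (length^2 scale)
  int last;       // hint tet for the walk
  std::vector<int> mark;  // cavity membership stamps
  int stamp;

  const double* P(int i) const { return pts + 3 * i; }

  static double det3(double a0, double a1, double a2,
                     double b0, double b1, double b2,
                     double c0, double c1, double c2) {
    return a0 * (b1 * c2 - b2 * c1)
         - a1 * (b0 * c2 - b2 * c0)
         + a2 * (b0 * c1 - b1 * c0);
  }

  // > 0 when d lies on the positive side of plane (a,b,c)
  double orient(const double* a, const double* b, const double* c,
                const double* d) const {
    return det3(b[0] - a[0], b[1] - a[1], b[2] - a[2],
                c[0] - a[0], c[1] - a[1], c[2] - a[2],
                d[0] - a[0], d[1] - a[1], d[2] - a[2]);
  }
  double orientIdx(int a, int b, int c, int d) const {
    return orient(P(a), P(b), P(c), P(d));
  }

  bool circumsphere(const double* a, const double* b, const double* c,
                    const double* d, double* cc, double& r2) const {
    // solve 2 (x - a) . (b - a) = |b|^2 - |a|^2 etc., via Cramer's rule
    double m[3][3], rhs[3];
    const double* q[3] = {b, c, d};
    for (int i = 0; i < 3; ++i) {
      double s = 0.0;
      for (int j = 0; j < 3; ++j) {
        m[i][j] = 2.0 * (q[i][j] - a[j]);
        s += q[i][j] * q[i][j] - a[j] * a[j];
      }
      rhs[i] = s;
    }
    double det = det3(m[0][0], m[0][1], m[0][2],
                      m[1][0], m[1][1], m[1][2],
                      m[2][0], m[2][1], m[2][2]);
    if (std::fabs(det) < 1e-300) return false;
    for (int j = 0; j < 3; ++j) {
      double mm[3][3];
      for (int i = 0; i < 3; ++i)
        for (int k = 0; k < 3; ++k) mm[i][k] = m[i][k];
      for (int i = 0; i < 3; ++i) mm[i][j] = rhs[i];
      cc[j] = det3(mm[0][0], mm[0][1], mm[0][2],
                   mm[1][0], mm[1][1], mm[1][2],
                   mm[2][0], mm[2][1], mm[2][2]) / det;
    }
    double dx = cc[0] - a[0], dy = cc[1] - a[1], dz = cc[2] - a[2];
    r2 = dx * dx + dy * dy + dz * dz;
    return true;
  }

  int newTet() {
    int id;
    if (!freed.empty()) { id = freed.back(); freed.pop_back(); }
    else { id = (int)tets.size(); tets.push_back(Tet()); }
    Tet& t = tets[id];
    t.alive = true;
    for (int i = 0; i < 4; ++i) t.nb[i] = NONE;
    return id;
  }
  void killTet(int id) { tets[id].alive = false; freed.push_back(id); }

  bool isInfinite(const Tet& t) const { return t.v[3] == INF_V; }

  // "point conflicts with tet": inside circumsphere (finite) or facet
  // visible / coplanar (infinite)
  bool conflict(const Tet& t, int p) const {
    if (isInfinite(t)) {
      double o = orientIdx(t.v[0], t.v[1], t.v[2], p);
      return o > eps_o;  // strictly visible facets only; coplanar points
                         // are handled through finite circumspheres
    }
    const double* q = P(p);
    double dx = q[0] - t.cc[0], dy = q[1] - t.cc[1], dz = q[2] - t.cc[2];
    return dx * dx + dy * dy + dz * dz < t.r2 - eps_s;
  }

  void setCircum(int id) {
    Tet& t = tets[id];
    if (isInfinite(t)) { t.r2 = -1.0; return; }
    if (!circumsphere(P(t.v[0]), P(t.v[1]), P(t.v[2]), P(t.v[3]),
                      t.cc, t.r2))
      stop("degenerate tetrahedron encountered (flat circumsphere)");
  }

  // initial tetrahedron from 4 affinely independent points
  void init(const std::vector<int>& seed) {
    int a = seed[0], b = seed[1], c = seed[2], d = seed[3];
    if (orientIdx(a, b, c, d) < 0) std::swap(c, d);
    int t0 = newTet();
    int tv[4] = {a, b, c, d};
    for (int i = 0; i < 4; ++i) tets[t0].v[i] = tv[i];
    setCircum(t0);
    // outward-oriented facets of a positively oriented tet (opposite each
    // vertex slot), ordered CCW seen from outside
    const int F[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
    int inf[4];
    for (int i = 0; i < 4; ++i) {
      int id = newTet();  // may reallocate tets: re-fetch references below
      inf[i] = id;
      Tet& ti = tets[id];
      ti.v[0] = tv[F[i][0]]; ti.v[1] = tv[F[i][1]];
      ti.v[2] = tv[F[i][2]]; ti.v[3] = INF_V;
      ti.r2 = -1.0;
      ti.nb[3] = t0;         // across the real facet lies the seed tet
      tets[t0].nb[i] = id;
    }
    // link infinite tets to each other across their INF-bearing faces:
    // face opposite ti.v[k] (k<3) contains INF and the other two reals
    for (int i = 0; i < 4; ++i)
      for (int k = 0; k < 3; ++k) {
        int u = tets[inf[i]].v[(k + 1) % 3];
        int w = tets[inf[i]].v[(k + 2) % 3];
        for (int j = 0; j < 4; ++j) {
          if (j == i) continue;
          const Tet& tj = tets[inf[j]];
          bool hasU = false, hasW = false;
          for (int m = 0; m < 3; ++m) {
            if (tj.v[m] == u) hasU = true;
            if (tj.v[m] == w) hasW = true;
          }
          if (hasU && hasW) { tets[inf[i]].nb[k] = inf[j]; break; }
        }
      }
    last = t0;
  }

  // walk toward a tet in conflict with p
  int locate(int p) {
    int cur = (last >= 0 && tets[last].alive) ? last : firstAlive();
    int steps = 0, cap = (int)tets.size() * 4 + 64;
    while (steps++ < cap) {
      Tet& t = tets[cur];
      if (conflict(t, p)) return cur;
      if (isInfinite(t)) { cur = t.nb[3]; continue; }  // step back inside
      // move through a face that separates p from the opposite vertex
      int next = NONE;
      for (int i = 0; i < 4; ++i) {
        int f0 = t.v[(i + 1) % 4], f1 = t.v[(i + 2) % 4],
            f2 = t.v[(i + 3) % 4];
        double ov = orientIdx(f0, f1, f2, t.v[i]);
        double op = orientIdx(f0, f1, f2, p);
        if (ov > 0 ? (op < -eps_o) : (op > eps_o)) { next = t.nb[i]; break; }
      }
      if (next == NONE) {
        // numerically inside but not in conflict: scan neighbours
        for (int i = 0; i < 4 && next == NONE; ++i)
          if (t.nb[i] != NONE && conflict(tets[t.nb[i]], p)) next = t.nb[i];
        if (next == NONE) break;
      }
      cur = next;
    }
    // fallback: brute scan
    for (int i = 0; i < (int)tets.size(); ++i)
      if (tets[i].alive && conflict(tets[i], p)) return i;
    stop("point location failed");
    return NONE;
  }

  int firstAlive() const {
    for (int i = 0; i < (int)tets.size(); ++i)
      if (tets[i].alive) return i;
    return NONE;
  }

  static int64_t edgeKey(int u, int v) {
    int a = u == INF_V ? INT32_MAX : u;
    int b = v == INF_V ? INT32_MAX : v;
    if (a > b) std::swap(a, b);
    return (int64_t)a * ((int64_t)INT32_MAX + 2) + b;
  }

  void insert(int p) {
    int t0 = locate(p);
    // cavity = connected conflict region
    if (mark.size() < tets.size()) mark.resize(tets.size(), 0);
    ++stamp;
    std::vector<int> cavity;
    std::vector<int> stack;
    stack.push_back(t0);
    mark[t0] = stamp;
    while (!stack.empty()) {
      int id = stack.back(); stack.pop_back();
      cavity.push_back(id);
      for (int i = 0; i < 4; ++i) {
        int nbid = tets[id].nb[i];
        if (nbid == NONE || mark[nbid] == stamp) continue;
        if (conflict(tets[nbid], p)) {
          mark[nbid] = stamp;
          stack.push_back(nbid);
        }
      }
    }
    // boundary facets -> new tets around p
    struct HalfFace { int tet, slot; };
    std::unordered_map<int64_t, HalfFace> open;  // edge-of-p faces to link
    std::vector<int> created;
    for (size_t ci = 0; ci < cavity.size(); ++ci) {
      const Tet t = tets[cavity[ci]];  // copy (tets may reallocate)
      for (int i = 0; i < 4; ++i) {
        int nbid = t.nb[i];
        if (nbid != NONE && mark[nbid] == stamp) continue;
        // facet opposite v[i]
        int f[3] = {t.v[(i + 1) % 4], t.v[(i + 2) % 4], t.v[(i + 3) % 4]};
        int id = newTet();
        created.push_back(id);
        Tet& nt = tets[id];
        if (f[0] == INF_V || f[1] == INF_V || f[2] == INF_V) {
          // hull edge facet: new infinite tet (u, w, p, INF);
          // orientation (CCW from outside) fixed after linking
          int u = NONE, w = NONE;
          for (int k = 0; k < 3; ++k) if (f[k] != INF_V) (u == NONE ? u : w) = f[k];
          nt.v[0] = u; nt.v[1] = w; nt.v[2] = p; nt.v[3] = INF_V;
          nt.r2 = -1.0;
        } else {
          double o = orient(P(f[0]), P(f[1]), P(f[2]), P(p));
          if (std::fabs(o) <= eps_o && t.v[i] != INF_V)
            stop("degenerate cavity facet");
          if (t.v[i] == INF_V) {
            // was the real facet of an infinite tet: new finite tet must
            // be on the inner side; orientation from o's sign directly
            if (std::fabs(o) <= eps_o) stop("coplanar hull facet");
          }
          if (o < 0) std::swap(f[1], f[2]);
          nt.v[0] = p; nt.v[1] = f[0]; nt.v[2] = f[1]; nt.v[3] = f[2];
          setCircum(id);
        }
        // link across the inherited facet
        int inheritSlot;  // slot of the facet not containing p in nt
        if (isInfinite(nt)) {
          // nt = (u, w, p, INF); inherited facet was (u, w, INF) -> the
          // face opposite slot 2 (p)
          inheritSlot = 2;
        } else {
          inheritSlot = 0;  // face opposite p = (f0,f1,f2)
        }
        nt.nb[inheritSlot] = nbid;
        if (nbid != NONE) {
          Tet& ext = tets[nbid];
          for (int k = 0; k < 4; ++k)
            if (ext.nb[k] == cavity[ci]) { ext.nb[k] = id; break; }
        }
        // remaining faces (those containing p): register by opposite edge
        for (int slot = 0; slot < 4; ++slot) {
          if (slot == inheritSlot) continue;
          // face opposite nt.v[slot]; it contains p; key = the two
          // other vertices
          int o1 = NONE, o2 = NONE;
          for (int k = 0; k < 4; ++k) {
            if (k == slot) continue;
            int vv = nt.v[k];
            if (vv == p) continue;
            (o1 == NONE ? o1 : o2) = vv;
          }
          if (o1 == NONE || o2 == NONE) continue;  // face lacks 2 non-p verts
          int64_t key = edgeKey(o1, o2);
          std::unordered_map<int64_t, HalfFace>::iterator it = open.find(key);
          if (it == open.end()) {
            HalfFace hf; hf.tet = id; hf.slot = slot;
            open[key] = hf;
          } else {
            nt.nb[slot] = it->second.tet;
            tets[it->second.tet].nb[it->second.slot] = id;
            open.erase(it);
          }
        }
      }
    }
    if (!open.empty()) stop("cavity retriangulation failed to close");
    // fix outward orientation of new infinite facets
    for (size_t k = 0; k < created.size(); ++k) {
      Tet& t = tets[created[k]];
      if (!isInfinite(t)) continue;
      int nbid = t.nb[3];  // finite neighbour across the real facet
      if (nbid == NONE) continue;
      const Tet& fin = tets[nbid];
      int oppo = NONE;
      for (int m = 0; m < 4; ++m) {
        int vv = fin.v[m];
        if (vv != t.v[0] && vv != t.v[1] && vv != t.v[2]) { oppo = vv; break; }
      }
      if (oppo != NONE &&
          orientIdx(t.v[0], t.v[1], t.v[2], oppo) > 0) {
        std::swap(t.v[0], t.v[1]);
        std::swap(t.nb[0], t.nb[1]);
      }
    }
    for (size_t ci = 0; ci < cavity.size(); ++ci) killTet(cavity[ci]);
    if (!created.empty()) {
      for (size_t k = 0; k < created.size(); ++k)
        if (!isInfinite(tets[created[k]])) { last = created[k]; break; }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".delaunay_tets_cpp")]]
List delaunay_tets_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<double> P(3 * n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      double v = pts(i, j);
      if (!R_finite(v)) stop("non-finite coordinate");
      P[3 * i + j] = v;
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  double diag = 0.0;
  for (int j = 0; j < 3; ++j) diag += (hi[j] - lo[j]) * (hi[j] - lo[j]);
  diag = std::sqrt(diag);
  if (diag <= 0) stop("all points coincide");

  Delaunay D;
  D.pts = P.data();
  D.n = n;
  D.eps_o = 1e-12 * diag * diag * diag;
  D.eps_s = 1e-11 * diag * diag;
  D.last = NONE;
  D.stamp = 0;

  // choose 4 affinely independent seed points
  std::vector<int> seed;
  seed.push_back(0);
  {
    double best = -1.0; int bi = -1;
    for (int i = 1; i < n; ++i) {
      double d = 0;
      for (int j = 0; j < 3; ++j) {
        double t = P[3 * i + j] - P[j];
        d += t * t;
      }
      if (d > best) { best = d; bi = i; }
    }
    if (best <= 0) stop("degenerate input: coincident points");
    seed.push_back(bi);
    // farthest from line
    best = -1.0; int ci = -1;
    const double* a = &P[0];
    const double* b = &P[3 * bi];
    double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    for (int i = 1; i < n; ++i) {
      const double* q = &P[3 * i];
      double aq[3] = {q[0] - a[0], q[1] - a[1], q[2] - a[2]};
      double cx = ab[1] * aq[2] - ab[2] * aq[1];
      double cy = ab[2] * aq[0] - ab[0] * aq[2];
      double cz = ab[0] * aq[1] - ab[1] * aq[0];
      double d = cx * cx + cy * cy + cz * cz;
      if (d > best) { best = d; ci = i; }
    }
    if (best <= D.eps_o * D.eps_o) stop("degenerate input: collinear points");
    seed.push_back(ci);
    best = -1.0; int di = -1;
    for (int i = 1; i < n; ++i) {
      double o = std::fabs(D.orient(&P[0], &P[3 * bi], &P[3 * ci], &P[3 * i]));
      if (o > best) { best = o; di = i; }
    }
    if (best <= D.eps_o) stop("degenerate input: coplanar points");
    seed.push_back(di);
  }

  D.init(seed);
  std::vector<char> used(n, 0);
  for (size_t k = 0; k < seed.size(); ++k) used[seed[k]] = 1;
  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    // skip exact duplicates of already-inserted points
    D.insert(i);
  }

  // collect finite tets
  int nt = 0;
  for (size_t i = 0; i < D.tets.size(); ++i)
    if (D.tets[i].alive && !D.isInfinite(D.tets[i])) ++nt;
  IntegerMatrix T(nt, 4);
  NumericVector circ(nt), vol(nt);
  int r = 0;
  for (size_t i = 0; i < D.tets.size(); ++i) {
    const Tet& t = D.tets[i];
    if (!t.alive || D.isInfinite(t)) continue;
    for (int j = 0; j < 4; ++j) T(r, j) = t.v[j] + 1;
    circ[r] = std::sqrt(t.r2);
    vol[r] = std::fabs(D.orientIdx(t.v[0], t.v[1], t.v[2], t.v[3])) / 6.0;
    ++r;
  }
  return List::create(_["tets"] = T, _["circumradius"] = circ,
                      _["volume"] = vol);
}
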