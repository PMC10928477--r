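// Incremental isotropic remeshing (split / collapse / flip / tangential
// relaxation, after Botsch & Kobbelt 2004).  Edges longer than 4/3 of the
// target length are split at their midpoint, edges shorter than 4/5 of the
// target are collapsed when the link condition holds, edges are flipped to
// reduce valence deviation from 6, and free vertices are relaxed toward the
// area-weighted neighbor centroid restricted to their tangent plane (which
// preserves enclosed volume to first order).  Vertices flagged fixed are
// never moved, merged away, or deleted; their coordinates are bitwise
// preserved.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <set>
#include <algorithm>
using namespace Rcpp;

namespace {
struct V3 {
  double x, y, z;
  V3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  V3 operator+(const V3 &o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator-(const V3 &o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
};
inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }

struct Mesh {
  std::vector<V3> v;
  std::vector<char> fixed;
  std::vector<char> act;    // vertices near topological changes this sweep
  std::vector<int> f;       // 3 per face
  std::vector<char> alive;  // per face

  int nf() const { return (int)alive.size(); }
  inline long long ekey(int a, int b) const {
    int lo = std::min(a, b), hi = std::max(a, b);
    return (long long)lo * (long long)(v.size() + 1) + hi;
  }
  V3 fnormal(int fi) const {
    const V3 &a = v[f[3 * fi]], &b = v[f[3 * fi + 1]], &c = v[f[3 * fi + 2]];
    return cross(b - a, c - a);
  }
};

struct EdgeRec { int a, b, f1, f2; };

static std::vector<char> expanded_active(const Mesh &m);

// Build edge list; stop() if any edge is not shared by exactly two faces.
static void build_edges(const Mesh &m, std::vector<EdgeRec> &edges) {
  std::unordered_map<long long, int> idx;
  edges.clear();
  for (int fi = 0; fi < m.nf(); ++fi) {
    if (!m.alive[fi]) continue;
    for (int k = 0; k < 3; ++k) {
      int a = m.f[3 * fi + k], b = m.f[3 * fi + (k + 1) % 3];
      long long key = m.ekey(a, b);
      std::unordered_map<long long, int>::iterator it = idx.find(key);
      if (it == idx.end()) {
        idx[key] = (int)edges.size();
        EdgeRec e; e.a = a; e.b = b; e.f1 = fi; e.f2 = -1;
        edges.push_back(e);
      } else {
        EdgeRec &e = edges[it->second];
        if (e.f2 != -1) stop("non-manifold edge (%d,%d)", a + 1, b + 1);
        e.f2 = fi;
      }
    }
  }
  for (size_t i = 0; i < edges.size(); ++i)
    if (edges[i].f2 == -1)
      stop("open edge (%d,%d): mesh is not watertight",
           edges[i].a + 1, edges[i].b + 1);
}

static int opposite_vertex(const Mesh &m, int fi, int a, int b) {
  for (int k = 0; k < 3; ++k) {
    int v = m.f[3 * fi + k];
    if (v != a && v != b) return v;
  }
  return -1;
}

static int split_pass(Mesh &m, double high) {
  int total = 0;
  for (int pass = 0; pass < 12; ++pass) {
    std::vector<EdgeRec> edges;
    build_edges(m, edges);
    std::vector<char> dirty(m.nf(), 0);
    int nsplit = 0;
    for (size_t i = 0; i < edges.size(); ++i) {
      const EdgeRec &e = edges[i];
      if (dirty[e.f1] || dirty[e.f2]) continue;
      if (norm(m.v[e.a] - m.v[e.b]) <= high) continue;
      int mid = (int)m.v.size();
      m.v.push_back((m.v[e.a] + m.v[e.b]) * 0.5);
      m.fixed.push_back(0);
      m.act.push_back(1);
      m.act[e.a] = m.act[e.b] = 1;
      int fs[2] = {e.f1, e.f2};
      for (int t = 0; t < 2; ++t) {
        int fi = fs[t];
        int c = opposite_vertex(m, fi, e.a, e.b);
        int va = m.f[3 * fi], vb = m.f[3 * fi + 1], vc = m.f[3 * fi + 2];
        // rotate so the split edge is (first,second)
        int tri[3] = {va, vb, vc};
        int r = 0;
        for (int k = 0; k < 3; ++k)
          if (tri[k] != c && tri[(k + 1) % 3] != c) { r = k; break; }
        int p = tri[r], q = tri[(r + 1) % 3];
        // faces (p, mid, c) and (mid, q, c) keep orientation
        m.f[3 * fi] = p; m.f[3 * fi + 1] = mid; m.f[3 * fi + 2] = c;
        m.f.push_back(mid); m.f.push_back(q); m.f.push_back(c);
        m.alive.push_back(1);
        m.act[c] = 1;
        dirty[fi] = 1;
        dirty.push_back(1);
      }
      ++nsplit;
    }
    total += nsplit;
    if (nsplit == 0) break;
  }
  return total;
}

static int collapse_pass(Mesh &m, double low, double high) {
  std::vector<EdgeRec> edges;
  build_edges(m, edges);
  int nv = (int)m.v.size();
  std::vector<std::vector<int> > vnb(nv), vfaces(nv);
  for (int fi = 0; fi < m.nf(); ++fi) {
    if (!m.alive[fi]) continue;
    for (int k = 0; k < 3; ++k) vfaces[m.f[3 * fi + k]].push_back(fi);
  }
  for (size_t i = 0; i < edges.size(); ++i) {
    vnb[edges[i].a].push_back(edges[i].b);
    vnb[edges[i].b].push_back(edges[i].a);
  }
  std::vector<char> touched(nv, 0);
  int ncollapsed = 0;
  for (size_t i = 0; i < edges.size(); ++i) {
    EdgeRec e = edges[i];
    if (touched[e.a] || touched[e.b]) continue;
    if (m.fixed[e.a] && m.fixed[e.b]) continue;
    if (norm(m.v[e.a] - m.v[e.b]) >= low) continue;
    // orient so `keep` survives; a fixed endpoint always survives in place
    int keep = e.a, gone = e.b;
    if (m.fixed[e.b]) { keep = e.b; gone = e.a; }
    V3 newpos = m.fixed[keep] ? m.v[keep] : (m.v[e.a] + m.v[e.b]) * 0.5;
    // link condition: exactly two common neighbors (the opposite vertices)
    std::set<int> na(vnb[e.a].begin(), vnb[e.a].end());
    int ncommon = 0;
    for (size_t t = 0; t < vnb[e.b].size(); ++t)
      if (na.count(vnb[e.b][t])) ++ncommon;
    if (ncommon != 2) continue;
    // simulate: check no degenerate/flipped/overlong result
    bool ok = true;
    std::vector<int> newfaces;
    std::set<int> allf(vfaces[e.a].begin(), vfaces[e.a].end());
    allf.insert(vfaces[e.b].begin(), vfaces[e.b].end());
    for (std::set<int>::iterator it = allf.begin(); it != allf.end() && ok; ++it) {
      int fi = *it;
      if (!m.alive[fi]) continue;
      int t[3];
      bool has_a = false, has_b = false;
      for (int k = 0; k < 3; ++k) {
        t[k] = m.f[3 * fi + k];
        if (t[k] == e.a) has_a = true;
        if (t[k] == e.b) has_b = true;
      }
      if (has_a && has_b) { newfaces.push_back(-fi - 1); continue; }  // removed
      V3 old_n = m.fnormal(fi);
      V3 p[3];
      for (int k = 0; k < 3; ++k)
        p[k] = (t[k] == gone || t[k] == keep) ? newpos : m.v[t[k]];
      V3 new_n = cross(p[1] - p[0], p[2] - p[0]);
      if (norm(new_n) < 2e-12 || dot(new_n, old_n) <= 0) { ok = false; break; }
      for (int k = 0; k < 3; ++k)
        if (norm(p[k] - p[(k + 1) % 3]) > high) { ok = false; break; }
      newfaces.push_back(fi);
    }
    if (!ok) continue;
    // commit
    m.v[keep] = newpos;
    for (size_t t = 0; t < newfaces.size(); ++t) {
      if (newfaces[t] < 0) { m.alive[-newfaces[t] - 1] = 0; continue; }
      int fi = newfaces[t];
      for (int k = 0; k < 3; ++k)
        if (m.f[3 * fi + k] == gone) m.f[3 * fi + k] = keep;
    }
    touched[e.a] = touched[e.b] = 1;
    m.act[e.a] = m.act[e.b] = 1;
    for (size_t t = 0; t < vnb[e.a].size(); ++t) {
      touched[vnb[e.a][t]] = 1;
      m.act[vnb[e.a][t]] = 1;
    }
    for (size_t t = 0; t < vnb[e.b].size(); ++t) {
      touched[vnb[e.b][t]] = 1;
      m.act[vnb[e.b][t]] = 1;
    }
    ++ncollapsed;
  }
  return ncollapsed;
}

static int flip_pass(Mesh &m) {
  std::vector<EdgeRec> edges;
  build_edges(m, edges);
  int nv = (int)m.v.size();
  std::vector<int> val(nv, 0);
  std::unordered_map<long long, char> has_edge;
  for (size_t i = 0; i < edges.size(); ++i) {
    ++val[edges[i].a];
    ++val[edges[i].b];
    has_edge[m.ekey(edges[i].a, edges[i].b)] = 1;
  }
  std::vector<char> dirty(m.nf(), 0);
  int nflip = 0;
  for (size_t i = 0; i < edges.size(); ++i) {
    const EdgeRec &e = edges[i];
    if (dirty[e.f1] || dirty[e.f2]) continue;
    if (m.fixed[e.a] && m.fixed[e.b]) continue;
    int c = opposite_vertex(m, e.f1, e.a, e.b);
    int d = opposite_vertex(m, e.f2, e.a, e.b);
    if (has_edge.count(m.ekey(c, d))) continue;
    int dev_before = (val[e.a] - 6) * (val[e.a] - 6) + (val[e.b] - 6) * (val[e.b] - 6) +
                     (val[c] - 6) * (val[c] - 6) + (val[d] - 6) * (val[d] - 6);
    int dev_after = (val[e.a] - 7) * (val[e.a] - 7) + (val[e.b] - 7) * (val[e.b] - 7) +
                    (val[c] - 5) * (val[c] - 5) + (val[d] - 5) * (val[d] - 5);
    if (dev_after >= dev_before) continue;
    if (val[e.a] <= 3 || val[e.b] <= 3) continue;
    // orient: f1 = (.., a -> b ..); after flip faces are (a,d,c) and (d,b,c)
    // where traversal a->b occurs in f1 (so c is f1's opposite)
    int a = e.a, b = e.b;
    bool ab_in_f1 = false;
    for (int k = 0; k < 3; ++k)
      if (m.f[3 * e.f1 + k] == a && m.f[3 * e.f1 + (k + 1) % 3] == b) ab_in_f1 = true;
    if (!ab_in_f1) { std::swap(a, b); }
    V3 n_old = m.fnormal(e.f1) + m.fnormal(e.f2);
    V3 n1 = cross(m.v[d] - m.v[a], m.v[c] - m.v[a]);
    V3 n2 = cross(m.v[b] - m.v[d], m.v[c] - m.v[d]);
    if (norm(n1) < 2e-12 || norm(n2) < 2e-12) continue;
    if (dot(n1, n_old) <= 0 || dot(n2, n_old) <= 0) continue;
    m.f[3 * e.f1] = a; m.f[3 * e.f1 + 1] = d; m.f[3 * e.f1 + 2] = c;
    m.f[3 * e.f2] = d; m.f[3 * e.f2 + 1] = b; m.f[3 * e.f2 + 2] = c;
    dirty[e.f1] = dirty[e.f2] = 1;
    m.act[a] = m.act[b] = m.act[c] = m.act[d] = 1;
    --val[a]; --val[b]; ++val[c]; ++val[d];
    has_edge.erase(m.ekey(a, b));
    has_edge[m.ekey(c, d)] = 1;
    ++nflip;
  }
  return nflip;
}

// closest point on triangle (Ericson) -- used to project relaxed vertices
// back onto the input surface so remeshing preserves the shape
static V3 tri_closest(const V3 &p, const V3 &a, const V3 &b, const V3 &c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return a + ab * (d1 / (d1 - d3));
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return a + ac * (d2 / (d2 - d6));
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  return a + ab * (vb * denom) + ac * (vc * denom);
}

struct RefSurface {
  std::vector<V3> v;
  std::vector<int> f;
  std::vector<V3> blo, bhi;  // per-face bounding boxes
  void build(const std::vector<V3> &verts, const std::vector<int> &faces) {
    v = verts;
    f = faces;
    int nf = (int)f.size() / 3;
    blo.resize(nf);
    bhi.resize(nf);
    for (int i = 0; i < nf; ++i) {
      V3 lo(R_PosInf, R_PosInf, R_PosInf), hi(R_NegInf, R_NegInf, R_NegInf);
      for (int k = 0; k < 3; ++k) {
        const V3 &p = v[f[3 * i + k]];
        lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y);
        lo.z = std::min(lo.z, p.z);
        hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y);
        hi.z = std::max(hi.z, p.z);
      }
      blo[i] = lo; bhi[i] = hi;
    }
  }
  V3 project(const V3 &p) const {
    double best = R_PosInf;
    V3 bestp = p;
    int nf = (int)f.size() / 3;
    for (int i = 0; i < nf; ++i) {
      double dx = std::max(std::max(blo[i].x - p.x, p.x - bhi[i].x), 0.0);
      double dy = std::max(std::max(blo[i].y - p.y, p.y - bhi[i].y), 0.0);
      double dz = std::max(std::max(blo[i].z - p.z, p.z - bhi[i].z), 0.0);
      if (dx * dx + dy * dy + dz * dz >= best) continue;
      V3 q = tri_closest(p, v[f[3 * i]], v[f[3 * i + 1]], v[f[3 * i + 2]]);
      double d = dot(q - p, q - p);
      if (d < best) { best = d; bestp = q; }
    }
    return bestp;
  }
};

static void project_pass(Mesh &m, const RefSurface &ref) {
  std::vector<char> used(m.v.size(), 0);
  std::vector<char> active = expanded_active(m);
  for (int fi = 0; fi < m.nf(); ++fi) {
    if (!m.alive[fi]) continue;
    for (int k = 0; k < 3; ++k) used[m.f[3 * fi + k]] = 1;
  }
  for (size_t v = 0; v < m.v.size(); ++v)
    if (used[v] && active[v] && !m.fixed[v]) m.v[v] = ref.project(m.v[v]);
}

// expand the activity mask by one ring so relaxation covers the seams
static std::vector<char> expanded_active(const Mesh &m) {
  std::vector<char> out(m.act);
  for (int fi = 0; fi < m.nf(); ++fi) {
    if (!m.alive[fi]) continue;
    int a = m.f[3 * fi], b = m.f[3 * fi + 1], c = m.f[3 * fi + 2];
    if (m.act[a] || m.act[b] || m.act[c]) out[a] = out[b] = out[c] = 1;
  }
  return out;
}

static void smooth_pass(Mesh &m, double lambda) {
  int nv = (int)m.v.size();
  std::vector<char> active = expanded_active(m);
  std::vector<V3> centroid(nv, V3());
  std::vector<double> wsum(nv, 0.0);
  std::vector<V3> vn(nv, V3());
  for (int fi = 0; fi < m.nf(); ++fi) {
    if (!m.alive[fi]) continue;
    int a = m.f[3 * fi], b = m.f[3 * fi + 1], c = m.f[3 * fi + 2];
    V3 n = m.fnormal(fi);
    double area = 0.5 * norm(n);
    V3 g = (m.v[a] + m.v[b] + m.v[c]) * (1.0 / 3.0);
    int id[3] = {a, b, c};
    for (int k = 0; k < 3; ++k) {
      centroid[id[k]] = centroid[id[k]] + g * area;
      wsum[id[k]] += area;
      vn[id[k]] = vn[id[k]] + n;
    }
  }
  for (int v = 0; v < nv; ++v) {
    if (m.fixed[v] || !active[v] || wsum[v] <= 0) continue;
    V3 n = vn[v];
    double ln = norm(n);
    if (ln <= 0) continue;
    n = n * (1.0 / ln);
    V3 d = centroid[v] * (1.0 / wsum[v]) - m.v[v];
    V3 dt = d - n * dot(d, n);  // tangential component only
    m.v[v] = m.v[v] + dt * lambda;
  }
}
}  // namespace

// [[Rcpp::export]]
List cpp_remesh(NumericMatrix Vm, IntegerMatrix Fm, LogicalVector fixed,
                double target, int iterations = 5, double lambda = 0.5) {
  Mesh m;
  int nv = Vm.nrow();
  m.v.resize(nv);
  m.fixed.resize(nv);
  m.act.assign(nv, 0);
  for (int i = 0; i < nv; ++i) {
    m.v[i] = V3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
    m.fixed[i] = fixed[i] ? 1 : 0;
  }
  m.f.resize(3 * Fm.nrow());
  m.alive.assign(Fm.nrow(), 1);
  for (int f = 0; f < Fm.nrow(); ++f)
    for (int k = 0; k < 3; ++k) m.f[3 * f + k] = Fm(f, k);

  RefSurface ref;
  ref.build(m.v, m.f);
  double high = 4.0 / 3.0 * target, low = 4.0 / 5.0 * target;
  for (int it = 0; it < iterations; ++it) {
    m.act.assign(m.v.size(), 0);
    int nops = split_pass(m, high);
    for (int sub = 0; sub < 10; ++sub) {
      int nc = collapse_pass(m, low, high);
      nops += nc;
      if (nc == 0) break;
    }
    nops += flip_pass(m);
    // already isotropic: leave the mesh untouched (idempotence)
    if (nops == 0) break;
    smooth_pass(m, lambda);
    project_pass(m, ref);
  }

  // compact: drop dead faces and unreferenced vertices
  std::vector<int> remap(m.v.size(), -1);
  int nnv = 0;
  for (int fi = 0; fi < m.nf(); ++fi) {
    if (!m.alive[fi]) continue;
    for (int k = 0; k < 3; ++k) {
      int v = m.f[3 * fi + k];
      if (remap[v] < 0) remap[v] = nnv++;
    }
  }
  for (size_t v = 0; v < m.v.size(); ++v)
    if (m.fixed[v] && remap[v] < 0)
      stop("remeshing deleted a fixed vertex (%d)", (int)v + 1);
  NumericMatrix Vout(nnv, 3);
  LogicalVector fixout(nnv);
  for (size_t v = 0; v < m.v.size(); ++v) {
    if (remap[v] < 0) continue;
    Vout(remap[v], 0) = m.v[v].x;
    Vout(remap[v], 1) = m.v[v].y;
    Vout(remap[v], 2) = m.v[v].z;
    fixout[remap[v]] = m.fixed[v] != 0;
  }
  int nnf = 0;
  for (int fi = 0; fi < m.nf(); ++fi) nnf += m.alive[fi];
  IntegerMatrix Fout(nnf, 3);
  int fo = 0;
  for (int fi = 0; fi < m.nf(); ++fi) {
    if (!m.alive[fi]) continue;
    for (int k = 0; k < 3; ++k) Fout(fo, k) = remap[m.f[3 * fi + k]];
    ++fo;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout,
                      _["fixed"] = fixout);
}
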