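// Knot-theoretic kernels for closed/open polygonal curves:
// Gauss-integral writhe, projection crossing counts (signed / ACN),
// KMT triangle elimination, Alexander determinant at t = -1.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct V3 { double x, y, z; };
static inline V3 sub(const V3& a, const V3& b) { return V3{a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 crs(const V3& a, const V3& b) {
  return V3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double nrm(const V3& a) { return sqrt(dot(a, a)); }

static std::vector<V3> as_vec(const NumericMatrix& m) {
  std::vector<V3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = V3{m(i, 0), m(i, 1), m(i, 2)};
  return v;
}

// Exact solid-angle contribution of a segment pair to the Gauss double
// integral (Klenin & Langowski method 1a).
static double pair_writhe(const V3& p1, const V3& p2, const V3& p3, const V3& p4) {
  V3 r12 = sub(p2, p1), r34 = sub(p4, p3);
  V3 r13 = sub(p3, p1), r14 = sub(p4, p1), r23 = sub(p3, p2), r24 = sub(p4, p2);
  V3 n1 = crs(r13, r14), n2 = crs(r14, r24), n3 = crs(r24, r23), n4 = crs(r23, r13);
  double l1 = nrm(n1), l2 = nrm(n2), l3 = nrm(n3), l4 = nrm(n4);
  if (l1 < 1e-14 || l2 < 1e-14 || l3 < 1e-14 || l4 < 1e-14) return 0.0;  // coplanar/degenerate pair
  auto cl = [](double x) { return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x); };
  double omega = asin(cl(dot(n1, n2) / (l1 * l2))) + asin(cl(dot(n2, n3) / (l2 * l3)))
               + asin(cl(dot(n3, n4) / (l3 * l4))) + asin(cl(dot(n4, n1) / (l4 * l1)));
  double sgn = dot(crs(r34, r12), r13) >= 0 ? 1.0 : -1.0;
  return omega * sgn;
}

//' @noRd
// [[Rcpp::export(rng = false)]]
double writhe_gauss_cpp(NumericMatrix verts, bool closed) {
  std::vector<V3> v = as_vec(verts);
  int n = (int) v.size();
  int nseg = closed ? n : n - 1;
  double tot = 0.0;
  for (int i = 0; i < nseg; ++i) {
    for (int j = i + 2; j < nseg; ++j) {
      if (closed && i == 0 && j == nseg - 1) continue;  // adjacent across the seam
      tot += pair_writhe(v[i], v[(i + 1) % n], v[j], v[(j + 1) % n]);
    }
  }
  return tot / (2.0 * M_PI);
}

// Build an orthonormal basis (e1, e2, u) with e1 x e2 = u.
static void basis_from_dir(const V3& u, V3& e1, V3& e2) {
  V3 a = (fabs(u.x) < 0.9) ? V3{1, 0, 0} : V3{0, 1, 0};
  e1 = crs(a, u);
  double l = nrm(e1);
  e1 = V3{e1.x / l, e1.y / l, e1.z / l};
  e2 = crs(u, e1);
}

struct Crossing {
  int si, sj;        // segment indices (si < sj)
  double ti, tj;     // intersection parameters on each segment
  bool i_over;       // true if segment si is the over-strand
  int sign;          // right-handed = +1
};

// All transversal crossings of the projection along direction u.
// Returns false if the projection is degenerate (tangency, endpoint hit,
// coincident crossing parameters).
static bool project_crossings(const std::vector<V3>& v, bool closed, const V3& u,
                              std::vector<Crossing>& out, double eps = 1e-9) {
  int n = (int) v.size();
  int nseg = closed ? n : n - 1;
  V3 e1, e2;
  basis_from_dir(u, e1, e2);
  std::vector<double> px(n), py(n), ph(n);
  for (int i = 0; i < n; ++i) {
    px[i] = dot(v[i], e1); py[i] = dot(v[i], e2); ph[i] = dot(v[i], u);
  }
  out.clear();
  for (int i = 0; i < nseg; ++i) {
    int i2 = (i + 1) % n;
    double ax = px[i], ay = py[i], bx = px[i2], by = py[i2];
    double dax = bx - ax, day = by - ay;
    for (int j = i + 2; j < nseg; ++j) {
      if (closed && i == 0 && j == nseg - 1) continue;
      int j2 = (j + 1) % n;
      double cx = px[j], cy = py[j], dx = px[j2], dy = py[j2];
      double dcx = dx - cx, dcy = dy - cy;
      double den = dax * dcy - day * dcx;
      if (fabs(den) < eps) {
        // parallel in projection: harmless unless the two segments are
        // collinear *and* their intervals overlap (a true degeneracy)
        double o1 = (cx - ax) * day - (cy - ay) * dax;
        if (fabs(o1) >= eps) continue;  // distinct parallel lines
        double la2 = dax * dax + day * day;
        if (la2 < eps) return false;    // zero-length projected segment
        double sc = ((cx - ax) * dax + (cy - ay) * day) / la2;
        double sd = ((dx - ax) * dax + (dy - ay) * day) / la2;
        double lo = sc < sd ? sc : sd, hi = sc < sd ? sd : sc;
        if (hi < -eps || lo > 1 + eps) continue;  // disjoint collinear spans
        return false;
      }
      double t = ((cx - ax) * dcy - (cy - ay) * dcx) / den;
      double s = ((cx - ax) * day - (cy - ay) * dax) / den;
      if (t <= -eps || t >= 1 + eps || s <= -eps || s >= 1 + eps) continue;
      if (t < eps || t > 1 - eps || s < eps || s > 1 - eps) return false;  // endpoint hit
      double hi = ph[i] + t * (ph[i2] - ph[i]);
      double hj = ph[j] + s * (ph[j2] - ph[j]);
      if (fabs(hi - hj) < eps) return false;  // strands touch in 3D along u
      Crossing c;
      c.si = i; c.sj = j; c.ti = t; c.tj = s;
      c.i_over = hi > hj;
      // sign: cross2(t_over, t_under) in the (e1, e2, u) right-handed frame
      double cr = c.i_over ? (dax * dcy - day * dcx) : (dcx * day - dcy * dax);
      c.sign = cr > 0 ? 1 : -1;
      out.push_back(c);
    }
  }
  return true;
}

//' Signed crossing counts for explicit projection directions (internal)
//' @noRd
// [[Rcpp::export(rng = false)]]
NumericMatrix crossings_project_cpp(NumericMatrix verts, bool closed,
                                    NumericMatrix dirs) {
  std::vector<V3> v = as_vec(verts);
  int np = dirs.nrow();
  NumericMatrix out(np, 3);  // n_plus, n_minus, degenerate flag
  std::vector<Crossing> cr;
  for (int p = 0; p < np; ++p) {
    V3 u{dirs(p, 0), dirs(p, 1), dirs(p, 2)};
    double l = nrm(u);
    u = V3{u.x / l, u.y / l, u.z / l};
    if (!project_crossings(v, closed, u, cr)) {
      out(p, 0) = NA_REAL; out(p, 1) = NA_REAL; out(p, 2) = 1;
      continue;
    }
    int np_ = 0, nm_ = 0;
    for (const Crossing& c : cr) (c.sign > 0 ? np_ : nm_)++;
    out(p, 0) = np_; out(p, 1) = nm_; out(p, 2) = 0;
  }
  return out;
}

// ---- KMT triangle elimination ----------------------------------------------

// 2-D (in-plane) segment/triangle overlap used for the coplanar case of
// the KMT test.  Orientations are computed about the triangle normal;
// touching counts as overlap (conservative).
static bool seg_overlaps_triangle_2d(const V3& a, const V3& b,
                                     const V3& t0, const V3& t1, const V3& t2,
                                     const V3& nr) {
  auto orient = [&](const V3& p, const V3& q, const V3& r) {
    return dot(nr, crs(sub(q, p), sub(r, p)));
  };
  const double tol = 1e-12;
  // endpoint inside the triangle (signs of the three edge orientations agree)
  auto inside = [&](const V3& p) {
    double o0 = orient(t0, t1, p), o1 = orient(t1, t2, p), o2 = orient(t2, t0, p);
    bool nonneg = o0 >= -tol && o1 >= -tol && o2 >= -tol;
    bool nonpos = o0 <= tol && o1 <= tol && o2 <= tol;
    return nonneg || nonpos;
  };
  if (inside(a) || inside(b)) return true;
  // segment against each triangle edge
  const V3* e[3][2] = {{&t0, &t1}, {&t1, &t2}, {&t2, &t0}};
  for (int k = 0; k < 3; ++k) {
    const V3& p = *e[k][0];
    const V3& q = *e[k][1];
    double o1 = orient(a, b, p), o2 = orient(a, b, q);
    double o3 = orient(p, q, a), o4 = orient(p, q, b);
    if (((o1 > tol && o2 < -tol) || (o1 < -tol && o2 > tol)) &&
        ((o3 > tol && o4 < -tol) || (o3 < -tol && o4 > tol))) return true;
    // touching/collinear configurations: conservative
    if (fabs(o1) <= tol && fabs(o2) <= tol) {
      // collinear: overlap if intervals intersect along the edge direction
      V3 dir = sub(q, p);
      double L2 = dot(dir, dir);
      if (L2 < tol) continue;
      double sa = dot(sub(a, p), dir) / L2, sb2 = dot(sub(b, p), dir) / L2;
      double lo = sa < sb2 ? sa : sb2, hi = sa < sb2 ? sb2 : sa;
      if (hi >= -1e-9 && lo <= 1 + 1e-9) return true;
    } else if ((fabs(o1) <= tol && o3 * o4 <= tol) ||
               (fabs(o2) <= tol && o3 * o4 <= tol) ||
               (fabs(o3) <= tol && o1 * o2 <= tol) ||
               (fabs(o4) <= tol && o1 * o2 <= tol)) {
      return true;
    }
  }
  return false;
}

// Does segment (a, b) intersect triangle (t0, t1, t2)?  Conservative:
// configurations it cannot prove safe count as intersecting so that the
// simplification never removes a vertex illegally.
static bool seg_hits_triangle(const V3& a, const V3& b,
                              const V3& t0, const V3& t1, const V3& t2) {
  const double eps = 1e-12;
  V3 e1 = sub(t1, t0), e2 = sub(t2, t0), d = sub(b, a);
  V3 p = crs(d, e2);
  double det = dot(e1, p);
  if (fabs(det) < eps) {
    // parallel to the triangle plane: safe if clearly off-plane, else a
    // genuine in-plane 2-D overlap test
    V3 nr = crs(e1, e2);
    double ln = nrm(nr);
    if (ln < eps) return true;  // degenerate triangle: be conservative
    double d0 = dot(sub(a, t0), nr) / ln, d1 = dot(sub(b, t0), nr) / ln;
    if (fabs(d0) > 1e-9 && fabs(d1) > 1e-9 && d0 * d1 > 0) return false;
    if (fabs(d0) < 1e-9 && fabs(d1) < 1e-9)
      return seg_overlaps_triangle_2d(a, b, t0, t1, t2, nr);
    return true;  // crosses the plane but Moller-Trumbore is singular
  }
  double inv = 1.0 / det;
  V3 s = sub(a, t0);
  double uu = dot(s, p) * inv;
  if (uu < -1e-9 || uu > 1 + 1e-9) return false;
  V3 q = crs(s, e1);
  double vv = dot(d, q) * inv;
  if (vv < -1e-9 || uu + vv > 1 + 1e-9) return false;
  double tt = dot(e2, q) * inv;
  return (tt > -1e-9 && tt < 1 + 1e-9);
}

//' KMT simplification of a polygonal curve (internal kernel)
//' @noRd
// [[Rcpp::export(rng = false)]]
NumericMatrix kmt_cpp(NumericMatrix verts, bool closed) {
  std::vector<V3> v = as_vec(verts);
  std::vector<int> idx(v.size());
  for (size_t i = 0; i < v.size(); ++i) idx[i] = (int) i;

  bool changed = true;
  while (changed && (int) idx.size() > 3) {
    changed = false;
    int m = (int) idx.size();
    int first = closed ? 0 : 1, last = closed ? m : m - 1;
    for (int jj = first; jj < last && (int) idx.size() > 3; ++jj) {
      m = (int) idx.size();
      if (jj >= m - (closed ? 0 : 1)) break;
      int jp = (jj - 1 + m) % m, jn = (jj + 1) % m;
      if (!closed && (jj == 0 || jj == m - 1)) continue;
      const V3& A = v[idx[jp]];
      const V3& B = v[idx[jj]];
      const V3& C = v[idx[jn]];
      bool blocked = false;
      int nseg = closed ? m : m - 1;
      for (int s = 0; s < nseg && !blocked; ++s) {
        int s2 = (s + 1) % m;
        // skip segments sharing a vertex with the triangle
        if (s == jp || s == jj || s2 == jp || s2 == jj || s == jn || s2 == jn) continue;
        if (seg_hits_triangle(v[idx[s]], v[idx[s2]], A, B, C)) blocked = true;
      }
      if (!blocked) {
        idx.erase(idx.begin() + jj);
        --jj;
        changed = true;
      }
    }
  }
  NumericMatrix out((int) idx.size(), 3);
  for (size_t i = 0; i < idx.size(); ++i) {
    out(i, 0) = v[idx[i]].x; out(i, 1) = v[idx[i]].y; out(i, 2) = v[idx[i]].z;
  }
  return out;
}

// ---- Alexander determinant at t = -1 ---------------------------------------

// |det| of an integer-valued matrix via partial-pivot elimination.
static double abs_det(std::vector<double>& M, int n) {
  if (n == 0) return 1.0;
  double det = 1.0;
  for (int c = 0; c < n; ++c) {
    int piv = c;
    for (int r = c + 1; r < n; ++r)
      if (fabs(M[r * n + c]) > fabs(M[piv * n + c])) piv = r;
    if (fabs(M[piv * n + c]) < 1e-12) return 0.0;
    if (piv != c) {
      for (int k = 0; k < n; ++k) std::swap(M[c * n + k], M[piv * n + k]);
      det = -det;
    }
    det *= M[c * n + c];
    for (int r = c + 1; r < n; ++r) {
      double f = M[r * n + c] / M[c * n + c];
      for (int k = c; k < n; ++k) M[r * n + k] -= f * M[c * n + k];
    }
  }
  return fabs(det);
}

//' Alexander determinant |Delta(-1)| from one projection (internal kernel)
//' Returns -1 for a degenerate projection.
//' @noRd
// [[Rcpp::export(rng = false)]]
double alexander_det_cpp(NumericMatrix verts, NumericVector dir) {
  std::vector<V3> v = as_vec(verts);
  V3 u{dir[0], dir[1], dir[2]};
  double l = nrm(u);
  u = V3{u.x / l, u.y / l, u.z / l};
  std::vector<Crossing> cr;
  if (!project_crossings(v, true, u, cr)) return -1.0;
  int nc = (int) cr.size();
  if (nc == 0) return 1.0;

  // positions along the curve of each strand of each crossing
  struct Pass { double pos; int cross; bool over; };
  std::vector<Pass> passes;
  passes.reserve(2 * nc);
  for (int c = 0; c < nc; ++c) {
    passes.push_back({cr[c].si + cr[c].ti, c, cr[c].i_over});
    passes.push_back({cr[c].sj + cr[c].tj, c, !cr[c].i_over});
  }
  // underpasses ordered along the curve define the generators
  std::vector<Pass> under;
  for (const Pass& p : passes) if (!p.over) under.push_back(p);
  std::sort(under.begin(), under.end(),
            [](const Pass& a, const Pass& b) { return a.pos < b.pos; });
  int n = (int) under.size();  // == nc
  // generator index k: arc from underpass k-1 (exclusive) to underpass k
  // find for each crossing the generator arc carrying its over-strand
  std::vector<int> under_rank(nc);  // crossing -> its rank among underpasses
  for (int k = 0; k < n; ++k) under_rank[under[k].cross] = k;
  auto arc_of = [&](double pos) {
    // arc index k such that under[k-1].pos < pos <= under[k].pos (cyclic)
    for (int k = 0; k < n; ++k) if (pos <= under[k].pos) return k;
    return 0;  // wraps past the last underpass into arc 0
  };
  std::vector<double> M((size_t) n * n, 0.0);
  for (int c = 0; c < nc; ++c) {
    int k = under_rank[c];  // this crossing is underpass number k
    double over_pos = cr[c].i_over ? (cr[c].si + cr[c].ti) : (cr[c].sj + cr[c].tj);
    int i = arc_of(over_pos);
    int k1 = (k + 1) % n;
    if (i == k || i == k1) {
      M[(size_t) k * n + k] += -1.0;
      M[(size_t) k * n + k1] += 1.0;
    } else {
      // at t = -1 both crossing signs give the same row
      M[(size_t) k * n + k] += 1.0;
      M[(size_t) k * n + k1] += 1.0;
      M[(size_t) k * n + i] += -2.0;
    }
  }
  // minor: drop last row and column
  int nm = n - 1;
  std::vector<double> Mm((size_t) nm * nm);
  for (int r = 0; r < nm; ++r)
    for (int cc = 0; cc < nm; ++cc) Mm[(size_t) r * nm + cc] = M[(size_t) r * n + cc];
  double d = abs_det(Mm, nm);
  return std::round(d);
}
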