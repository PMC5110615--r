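#include "core.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Axis-aligned bounding-box BVH over triangle meshes.
//
// The tree is stored as flat parallel arrays (pre-order, children always have
// a larger index than their parent, so a reverse sweep refits bottom-up).
// Construction: median split of the face list sorted along the longest axis
// of the node AABB, ties broken by face index; deterministic by design.
// ---------------------------------------------------------------------------

struct BvhBuild {
  std::vector<V3> fmin, fmax, centroid; // per face
  std::vector<int> order;               // permutation of faces
  int leaf_size;
  std::vector<V3> nmin, nmax;
  std::vector<int> left, right, start, count;
};

static int bvh_build_node(BvhBuild &b, int lo, int hi) {
  int idx = (int)b.nmin.size();
  b.nmin.push_back(V3(0, 0, 0));
  b.nmax.push_back(V3(0, 0, 0));
  b.left.push_back(-1);
  b.right.push_back(-1);
  b.start.push_back(-1);
  b.count.push_back(0);
  V3 mn = b.fmin[b.order[lo]], mx = b.fmax[b.order[lo]];
  for (int i = lo + 1; i < hi; ++i) {
    mn = vmin(mn, b.fmin[b.order[i]]);
    mx = vmax(mx, b.fmax[b.order[i]]);
  }
  b.nmin[idx] = mn;
  b.nmax[idx] = mx;
  if (hi - lo <= b.leaf_size) {
    b.start[idx] = lo;
    b.count[idx] = hi - lo;
    return idx;
  }
  V3 ext = mx - mn;
  int axis = 0;
  if (ext.y > ext.x) axis = 1;
  if (ext.z > (axis == 0 ? ext.x : ext.y)) axis = 2;
  std::stable_sort(b.order.begin() + lo, b.order.begin() + hi,
                   [&](int a, int c) {
                     double ca = (axis == 0) ? b.centroid[a].x
                                 : (axis == 1) ? b.centroid[a].y
                                               : b.centroid[a].z;
                     double cc = (axis == 0) ? b.centroid[c].x
                                 : (axis == 1) ? b.centroid[c].y
                                               : b.centroid[c].z;
                     if (ca != cc) return ca < cc;
                     return a < c;
                   });
  int mid = (lo + hi) / 2;
  int l = bvh_build_node(b, lo, mid);
  int r = bvh_build_node(b, mid, hi);
  b.left[idx] = l;
  b.right[idx] = r;
  return idx;
}

static void face_bounds(const NumericMatrix &V, const IntegerMatrix &F, int f,
                        V3 &mn, V3 &mx) {
  V3 a = row3(V, F(f, 0) - 1), b = row3(V, F(f, 1) - 1),
     c = row3(V, F(f, 2) - 1);
  mn = vmin(a, vmin(b, c));
  mx = vmax(a, vmax(b, c));
}

// [[Rcpp::export]]
List cpp_bvh_build(NumericMatrix vertices, IntegerMatrix faces,
                   int leaf_size) {
  int nf = faces.nrow();
  if (nf < 1) stop("empty mesh: cannot build BVH");
  BvhBuild b;
  b.leaf_size = std::max(leaf_size, 1);
  b.fmin.resize(nf);
  b.fmax.resize(nf);
  b.centroid.resize(nf);
  b.order.resize(nf);
  for (int f = 0; f < nf; ++f) {
    face_bounds(vertices, faces, f, b.fmin[f], b.fmax[f]);
    b.centroid[f] = (b.fmin[f] + b.fmax[f]) * 0.5;
    b.order[f] = f;
  }
  bvh_build_node(b, 0, nf);
  int nn = (int)b.nmin.size();
  NumericMatrix nmin(nn, 3), nmax(nn, 3);
  IntegerVector left(nn), right(nn), start(nn), count(nn), order(nf);
  for (int i = 0; i < nn; ++i) {
    setrow3(nmin, i, b.nmin[i]);
    setrow3(nmax, i, b.nmax[i]);
    left[i] = b.left[i];
    right[i] = b.right[i];
    start[i] = b.start[i];
    count[i] = b.count[i];
  }
  for (int f = 0; f < nf; ++f) order[f] = b.order[f] + 1; // 1-based
  return List::create(_["node_min"] = nmin, _["node_max"] = nmax,
                      _["left"] = left, _["right"] = right,
                      _["start"] = start, _["count"] = count,
                      _["face_order"] = order, _["leaf_size"] = b.leaf_size,
                      _["n_faces"] = nf);
}

// [[Rcpp::export]]
List cpp_bvh_refit(List bvh, NumericMatrix vertices, IntegerMatrix faces) {
  NumericMatrix nmin = clone(as<NumericMatrix>(bvh["node_min"]));
  NumericMatrix nmax = clone(as<NumericMatrix>(bvh["node_max"]));
  IntegerVector left = bvh["left"], right = bvh["right"],
                start = bvh["start"], count = bvh["count"],
                order = bvh["face_order"];
  int nn = nmin.nrow();
  for (int i = nn - 1; i >= 0; --i) {
    V3 mn, mx;
    if (left[i] < 0) { // leaf
      face_bounds(vertices, faces, order[start[i]] - 1, mn, mx);
      for (int k = 1; k < count[i]; ++k) {
        V3 a, b;
        face_bounds(vertices, faces, order[start[i] + k] - 1, a, b);
        mn = vmin(mn, a);
        mx = vmax(mx, b);
      }
    } else {
      mn = vmin(row3(nmin, left[i]), row3(nmin, right[i]));
      mx = vmax(row3(nmax, left[i]), row3(nmax, right[i]));
    }
    setrow3(nmin, i, mn);
    setrow3(nmax, i, mx);
  }
  List out = clone(bvh);
  out["node_min"] = nmin;
  out["node_max"] = nmax;
  return out;
}

static double aabb_dist2(const V3 &mn, const V3 &mx, const V3 &p) {
  double d2 = 0.0;
  double d;
  d = std::max(std::max(mn.x - p.x, 0.0), p.x - mx.x); d2 += d * d;
  d = std::max(std::max(mn.y - p.y, 0.0), p.y - mx.y); d2 += d * d;
  d = std::max(std::max(mn.z - p.z, 0.0), p.z - mx.z); d2 += d * d;
  return d2;
}

// [[Rcpp::export]]
IntegerVector cpp_bvh_query_sphere(List bvh, NumericVector center,
                                   double radius) {
  NumericMatrix nmin = bvh["node_min"], nmax = bvh["node_max"];
  IntegerVector left = bvh["left"], right = bvh["right"],
                start = bvh["start"], count = bvh["count"],
                order = bvh["face_order"];
  V3 p(center[0], center[1], center[2]);
  double r2 = radius * radius;
  std::vector<int> hits;
  std::vector<int> stack;
  stack.push_back(0);
  while (!stack.empty()) {
    int i = stack.back();
    stack.pop_back();
    if (aabb_dist2(row3(nmin, i), row3(nmax, i), p) > r2) continue;
    if (left[i] < 0) {
      for (int k = 0; k < count[i]; ++k) hits.push_back(order[start[i] + k]);
    } else {
      stack.push_back(right[i]);
      stack.push_back(left[i]);
    }
  }
  std::sort(hits.begin(), hits.end());
  return wrap(hits);
}

// Closest point on a triangle (Ericson, Real-Time Collision Detection).
static V3 closest_on_triangle(const V3 &p, const V3 &a, const V3 &b,
                              const V3 &c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// [[Rcpp::export]]
List cpp_closest_point_triangle(NumericVector p, NumericVector a,
                                NumericVector b, NumericVector c) {
  V3 pa(a[0], a[1], a[2]), pb(b[0], b[1], b[2]), pc(c[0], c[1], c[2]);
  V3 ab = pb - pa, ac = pc - pa;
  if (norm(cross(ab, ac)) < 1e-14) stop("degenerate triangle");
  V3 pp(p[0], p[1], p[2]);
  V3 cp = closest_on_triangle(pp, pa, pb, pc);
  return List::create(
      _["point"] = NumericVector::create(cp.x, cp.y, cp.z),
      _["distance"] = norm(pp - cp));
}

// Nearest surface point of one mesh to a query point, within `radius`.
// Returns distance (Inf if none), closest point and its face id.
bool mesh_nearest(const MeshView &M, const V3 &p, double radius,
                  double &dist, V3 &cp, int &face) {
  double best2 = radius * radius;
  bool found = false;
  int stack[128];
  int sp = 0;
  stack[sp++] = 0;
  while (sp > 0) {
    int i = stack[--sp];
    if (aabb_dist2(M.node_min_at(i), M.node_max_at(i), p) > best2) continue;
    if (M.left[i] < 0) {
      for (int k = 0; k < M.count[i]; ++k) {
        int fid = M.order[M.start[i] + k] - 1;
        V3 a = M.vertex(M.f[fid] - 1);
        V3 b = M.vertex(M.f[fid + M.nf] - 1);
        V3 c = M.vertex(M.f[fid + 2 * M.nf] - 1);
        V3 q = closest_on_triangle(p, a, b, c);
        V3 d = p - q;
        double d2 = dot(d, d);
        if (d2 <= best2) {
          // deterministic tie-break: keep the lower face id on exact ties
          if (d2 < best2 || !found || fid + 1 < face) {
            best2 = d2;
            cp = q;
            face = fid + 1;
            found = true;
          }
        }
      }
    } else if (sp < 126) {
      stack[sp++] = M.right[i];
      stack[sp++] = M.left[i];
    } else {
      stop("BVH traversal stack overflow");
    }
  }
  if (found) dist = std::sqrt(best2);
  return found;
}

// Sphere-vs-mesh contacts for a set of rod points: one contact per
// (point, mesh) at the nearest surface point when penetrating.
// [[Rcpp::export]]
List cpp_mesh_contacts(NumericMatrix points, NumericMatrix prev_points,
                       double radius, List meshes) {
  int np = points.nrow();
  int nm = meshes.size();
  std::vector<MeshView> views;
  for (int m = 0; m < nm; ++m) {
    List M = meshes[m];
    views.emplace_back(as<NumericMatrix>(M["vertices"]),
                       as<IntegerMatrix>(M["faces"]), as<List>(M["bvh"]));
  }
  std::vector<int> idx, mesh_id;
  std::vector<double> depth, nx, ny, nz, cx, cy, cz;
  for (int i = 0; i < np; ++i) {
    V3 p = row3(points, i);
    for (int m = 0; m < nm; ++m) {
      double dist;
      V3 cp;
      int face;
      if (!mesh_nearest(views[m], p, radius, dist, cp, face)) continue;
      if (dist >= radius) continue; // touching but not penetrating
      V3 nrm;
      if (dist > 1e-12) {
        nrm = (p - cp) * (1.0 / dist);
      } else {
        // point exactly on the surface: push back toward where it came from
        V3 back = row3(prev_points, i) - cp;
        nrm = (norm(back) > 1e-12) ? normalized(back) : V3(0, 0, 1);
      }
      idx.push_back(i + 1);
      mesh_id.push_back(m + 1);
      depth.push_back(radius - dist);
      nx.push_back(nrm.x); ny.push_back(nrm.y); nz.push_back(nrm.z);
      cx.push_back(cp.x); cy.push_back(cp.y); cz.push_back(cp.z);
    }
  }
  return List::create(_["point_index"] = wrap(idx), _["mesh"] = wrap(mesh_id),
                      _["depth"] = wrap(depth), _["nx"] = wrap(nx),
                      _["ny"] = wrap(ny), _["nz"] = wrap(nz),
                      _["cx"] = wrap(cx), _["cy"] = wrap(cy),
                      _["cz"] = wrap(cz));
}
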