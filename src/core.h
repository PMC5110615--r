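#pragma once

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

// ---------------------------------------------------------------------------
// Small 3-vector / quaternion value types used throughout the compiled core.
// Quaternions are stored (w, x, y, z); unit quaternions act as rotations via
// v' = q v q*.  All rotations are right-handed.
// ---------------------------------------------------------------------------

struct V3 {
  double x, y, z;
  V3() : x(0.0), y(0.0), z(0.0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  V3 operator+(const V3 &o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator-(const V3 &o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
  V3 operator-() const { return V3(-x, -y, -z); }
  V3 &operator+=(const V3 &o) { x += o.x; y += o.y; z += o.z; return *this; }
  V3 &operator-=(const V3 &o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
  V3 &operator*=(double s) { x *= s; y *= s; z *= s; return *this; }
};

inline double dot(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x);
}
inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
inline V3 normalized(const V3 &a) {
  double n = norm(a);
  return (n > 0.0) ? a * (1.0 / n) : V3(0.0, 0.0, 0.0);
}
inline V3 vmin(const V3 &a, const V3 &b) {
  return V3(std::min(a.x, b.x), std::min(a.y, b.y), std::min(a.z, b.z));
}
inline V3 vmax(const V3 &a, const V3 &b) {
  return V3(std::max(a.x, b.x), std::max(a.y, b.y), std::max(a.z, b.z));
}

struct Q4 {
  double w, x, y, z;
  Q4() : w(1.0), x(0.0), y(0.0), z(0.0) {}
  Q4(double w_, double x_, double y_, double z_)
      : w(w_), x(x_), y(y_), z(z_) {}
};

inline Q4 qmul(const Q4 &a, const Q4 &b) {
  return Q4(a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
            a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
            a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
            a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w);
}
inline Q4 qconj(const Q4 &a) { return Q4(a.w, -a.x, -a.y, -a.z); }
inline double qnorm(const Q4 &a) {
  return std::sqrt(a.w * a.w + a.x * a.x + a.y * a.y + a.z * a.z);
}
inline Q4 qscale(const Q4 &a, double s) {
  return Q4(a.w * s, a.x * s, a.y * s, a.z * s);
}
inline Q4 qnormalize(const Q4 &a) {
  double n = qnorm(a);
  return (n > 0.0) ? qscale(a, 1.0 / n) : Q4();
}
inline Q4 qadd(const Q4 &a, const Q4 &b) {
  return Q4(a.w + b.w, a.x + b.x, a.y + b.y, a.z + b.z);
}

// Rotation of v by unit quaternion q.
inline V3 qrotate(const Q4 &q, const V3 &v) {
  V3 u(q.x, q.y, q.z);
  V3 c = cross(u, v);
  V3 c2 = cross(u, c);
  return v + (c * (2.0 * q.w)) + (c2 * 2.0);
}

// Columns (directors) of the rotation matrix of q.
inline void qdirectors(const Q4 &q, V3 &d1, V3 &d2, V3 &d3) {
  double w = q.w, x = q.x, y = q.y, z = q.z;
  d1 = V3(1.0 - 2.0 * (y * y + z * z), 2.0 * (x * y + w * z),
          2.0 * (x * z - w * y));
  d2 = V3(2.0 * (x * y - w * z), 1.0 - 2.0 * (x * x + z * z),
          2.0 * (y * z + w * x));
  d3 = V3(2.0 * (x * z + w * y), 2.0 * (y * z - w * x),
          1.0 - 2.0 * (x * x + y * y));
}

inline V3 qd3(const Q4 &q) {
  return V3(2.0 * (q.x * q.z + q.w * q.y), 2.0 * (q.y * q.z - q.w * q.x),
            1.0 - 2.0 * (q.x * q.x + q.y * q.y));
}

// Exponential map of a body-frame rotation vector phi (rad).
inline Q4 qexp_rotvec(const V3 &phi) {
  double a = norm(phi);
  if (a < 1e-14) {
    // second-order small-angle expansion keeps unit norm to machine precision
    return qnormalize(Q4(1.0, 0.5 * phi.x, 0.5 * phi.y, 0.5 * phi.z));
  }
  double s = std::sin(0.5 * a) / a;
  return Q4(std::cos(0.5 * a), phi.x * s, phi.y * s, phi.z * s);
}

inline Q4 qaxis_angle(const V3 &axis, double angle) {
  V3 u = normalized(axis);
  double s = std::sin(0.5 * angle);
  return Q4(std::cos(0.5 * angle), u.x * s, u.y * s, u.z * s);
}

// Discrete Darboux vector between two adjacent material frames spanning
// `span` metres: Omega = (2/span) * vec(conj(q_a) x q_b).
inline V3 darboux_vec(const Q4 &qa, const Q4 &qb, double span) {
  Q4 u = qmul(qconj(qa), qb);
  double s = 2.0 / span;
  return V3(u.x * s, u.y * s, u.z * s);
}

// Elastic parameters of the discrete Cosserat rod (defined in rod.cpp).
struct RodElastic {
  double rest_length;   // per-element rest length, m
  double EI1, EI2, GJ;  // bending / torsion stiffnesses, N m^2
  double kc;            // parallelism (frame-tangent) stiffness, N
};

void rod_elastic_core(const std::vector<V3> &r, const std::vector<Q4> &q,
                      int a0, int n, const RodElastic &el,
                      const std::vector<V3> &Omega0, double *V_bt, double *V_p,
                      std::vector<V3> *F, std::vector<Q4> *dVdq);

V3 torque_from_gradient(const Q4 &q, const Q4 &g);

// Pre-extracted mesh + BVH arrays with raw pointers (Rcpp element access is
// too slow for the collision inner loops).  The Rcpp objects are kept as
// members so the memory stays protected while the view is alive.
struct MeshView {
  Rcpp::NumericMatrix V;
  Rcpp::IntegerMatrix F;
  Rcpp::NumericMatrix nmin_m, nmax_m;
  Rcpp::IntegerVector left_v, right_v, start_v, count_v, order_v;
  const double *v, *nmin, *nmax;
  const int *f, *left, *right, *start, *count, *order;
  int nv, nf, nn;
  MeshView(Rcpp::NumericMatrix V_, Rcpp::IntegerMatrix F_, Rcpp::List bvh)
      : V(V_), F(F_),
        nmin_m(Rcpp::as<Rcpp::NumericMatrix>(bvh["node_min"])),
        nmax_m(Rcpp::as<Rcpp::NumericMatrix>(bvh["node_max"])),
        left_v(Rcpp::as<Rcpp::IntegerVector>(bvh["left"])),
        right_v(Rcpp::as<Rcpp::IntegerVector>(bvh["right"])),
        start_v(Rcpp::as<Rcpp::IntegerVector>(bvh["start"])),
        count_v(Rcpp::as<Rcpp::IntegerVector>(bvh["count"])),
        order_v(Rcpp::as<Rcpp::IntegerVector>(bvh["face_order"])) {
    v = REAL(V);
    f = INTEGER(F);
    nmin = REAL(nmin_m);
    nmax = REAL(nmax_m);
    left = INTEGER(left_v);
    right = INTEGER(right_v);
    start = INTEGER(start_v);
    count = INTEGER(count_v);
    order = INTEGER(order_v);
    nv = V.nrow();
    nf = F.nrow();
    nn = nmin_m.nrow();
  }
  inline V3 vertex(int i) const {
    return V3(v[i], v[i + nv], v[i + 2 * nv]);
  }
  inline V3 node_min_at(int i) const {
    return V3(nmin[i], nmin[i + nn], nmin[i + 2 * nn]);
  }
  inline V3 node_max_at(int i) const {
    return V3(nmax[i], nmax[i + nn], nmax[i + 2 * nn]);
  }
};

// Defined in collision.cpp; nearest surface point of a mesh within `radius`.
bool mesh_nearest(const MeshView &M, const V3 &p, double radius,
                  double &dist, V3 &cp, int &face);

// Conversion helpers between Rcpp matrices and the value types.
inline V3 row3(const Rcpp::NumericMatrix &m, int i) {
  return V3(m(i, 0), m(i, 1), m(i, 2));
}
inline void setrow3(Rcpp::NumericMatrix &m, int i, const V3 &v) {
  m(i, 0) = v.x;
  m(i, 1) = v.y;
  m(i, 2) = v.z;
}
inline Q4 row4(const Rcpp::NumericMatrix &m, int i) {
  return Q4(m(i, 0), m(i, 1), m(i, 2), m(i, 3));
}
inline void setrow4(Rcpp::NumericMatrix &m, int i, const Q4 &q) {
  m(i, 0) = q.w;
  m(i, 1) = q.x;
  m(i, 2) = q.y;
  m(i, 3) = q.z;
}
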