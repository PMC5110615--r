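#include "core.h"
#include <R_ext/Lapack.h>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Cosserat rod elastic model.
//
// Discretization: n centreline mass points r_i, n-1 unit quaternion material
// frames q_j (frame j sits between points j and j+1), n-2 interior junctions
// where the discrete Darboux vector Omega_k = (2/span) vec(conj(q_k) q_{k+1})
// measures bend (components 1,2) and twist (component 3).
//
// Elastic energy:
//   V_bt = sum_k 1/2 (Omega_k - Omega0_k)^T K (Omega_k - Omega0_k) * span
//   V_p  = sum_j 1/2 k_c |d3(q_j) - t_j|^2 * l      (frame/tangent coupling)
// with K = diag(E I1, E I2, G J), t_j the unit element tangent, l the element
// rest length and span the junction span (mean of adjacent rest lengths;
// uniform here).
//
// Only points with 0-based index >= a0 ("active" inserted portion) carry
// dynamics; the same convention is used by every routine below.
// ---------------------------------------------------------------------------

// Accumulates energies; forces F (per point), quaternion gradients dVdq (per
// frame).  Any output pointer may be null.
void rod_elastic_core(const std::vector<V3> &r,
                             const std::vector<Q4> &q, int a0, int n,
                             const RodElastic &el,
                             const std::vector<V3> &Omega0,
                             double *V_bt, double *V_p,
                             std::vector<V3> *F, std::vector<Q4> *dVdq) {
  const double span = el.rest_length;
  // bend/twist junctions: frames k and k+1 both active
  for (int k = a0; k <= n - 3; ++k) {
    Q4 u = qmul(qconj(q[k]), q[k + 1]);
    double s = 2.0 / span;
    V3 Om(u.x * s, u.y * s, u.z * s);
    V3 dOm = Om - Omega0[k];
    V3 g(el.EI1 * dOm.x * span, el.EI2 * dOm.y * span, el.GJ * dOm.z * span);
    if (V_bt) *V_bt += 0.5 * (g.x * dOm.x + g.y * dOm.y + g.z * dOm.z);
    if (dVdq) {
      // dV/du has zero scalar part; chain rule through u = conj(q_k) q_{k+1}
      Q4 gu(0.0, g.x * s, g.y * s, g.z * s);
      (*dVdq)[k + 1] = qadd((*dVdq)[k + 1], qmul(q[k], gu));
      (*dVdq)[k] = qadd((*dVdq)[k], qconj(qmul(gu, qconj(q[k + 1]))));
    }
  }
  // parallelism: element j couples frame j to the tangent of (r_j, r_{j+1})
  for (int j = a0; j <= n - 2; ++j) {
    V3 e = r[j + 1] - r[j];
    double len = norm(e);
    if (len <= 0.0) stop("degenerate geometry: coincident adjacent points");
    V3 t = e * (1.0 / len);
    V3 d3 = qd3(q[j]);
    V3 diff = d3 - t;
    if (V_p)
      *V_p += 0.5 * el.kc * el.rest_length * dot(diff, diff);
    V3 h = diff * (el.kc * el.rest_length);
    if (F) {
      // force = +(I - t t^T) h / len on r_{j+1}, opposite on r_j
      V3 ht = (h - t * dot(t, h)) * (1.0 / len);
      (*F)[j + 1] += ht;
      (*F)[j] -= ht;
    }
    if (dVdq) {
      double w = q[j].w, x = q[j].x, y = q[j].y, z = q[j].z;
      Q4 g(2.0 * (y * h.x - x * h.y),
           2.0 * (z * h.x - w * h.y) - 4.0 * x * h.z,
           2.0 * (w * h.x + z * h.y) - 4.0 * y * h.z,
           2.0 * (x * h.x + y * h.y));
      (*dVdq)[j] = qadd((*dVdq)[j], g);
    }
  }
}

// Body-frame torque from the quaternion gradient: tau = 1/2 vec(conj(q) (-dVdq)).
V3 torque_from_gradient(const Q4 &q, const Q4 &g) {
  Q4 p = qmul(qconj(q), g);
  return V3(-0.5 * p.x, -0.5 * p.y, -0.5 * p.z);
}

static std::vector<V3> mat_to_v3(const NumericMatrix &m) {
  std::vector<V3> out(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) out[i] = row3(m, i);
  return out;
}
static std::vector<Q4> mat_to_q4(const NumericMatrix &m) {
  std::vector<Q4> out(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) out[i] = row4(m, i);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_quat_rotation(NumericVector q) {
  Q4 qq(q[0], q[1], q[2], q[3]);
  V3 d1, d2, d3;
  qdirectors(qq, d1, d2, d3);
  NumericMatrix R(3, 3);
  R(0, 0) = d1.x; R(1, 0) = d1.y; R(2, 0) = d1.z;
  R(0, 1) = d2.x; R(1, 1) = d2.y; R(2, 1) = d2.z;
  R(0, 2) = d3.x; R(1, 2) = d3.y; R(2, 2) = d3.z;
  return R;
}

// [[Rcpp::export]]
NumericVector cpp_darboux(NumericVector qa, NumericVector qb, double span) {
  V3 om = darboux_vec(Q4(qa[0], qa[1], qa[2], qa[3]),
                      Q4(qb[0], qb[1], qb[2], qb[3]), span);
  return NumericVector::create(om.x, om.y, om.z);
}

// [[Rcpp::export]]
List cpp_rod_energy(NumericMatrix positions, NumericMatrix quats,
                    int active_first, double rest_length, double EI1,
                    double EI2, double GJ, double kc, NumericMatrix Omega0) {
  int n = positions.nrow();
  std::vector<V3> r = mat_to_v3(positions);
  std::vector<Q4> q = mat_to_q4(quats);
  std::vector<V3> Om0(std::max(n - 2, 0));
  for (int k = 0; k < n - 2; ++k) Om0[k] = row3(Omega0, k);
  RodElastic el{rest_length, EI1, EI2, GJ, kc};
  double vbt = 0.0, vp = 0.0;
  rod_elastic_core(r, q, active_first - 1, n, el, Om0, &vbt, &vp, nullptr,
                   nullptr);
  return List::create(_["bend_twist"] = vbt, _["parallelism"] = vp);
}

// [[Rcpp::export]]
List cpp_rod_forces(NumericMatrix positions, NumericMatrix quats,
                    int active_first, double rest_length, double EI1,
                    double EI2, double GJ, double kc, NumericMatrix Omega0) {
  int n = positions.nrow();
  std::vector<V3> r = mat_to_v3(positions);
  std::vector<Q4> q = mat_to_q4(quats);
  std::vector<V3> Om0(std::max(n - 2, 0));
  for (int k = 0; k < n - 2; ++k) Om0[k] = row3(Omega0, k);
  RodElastic el{rest_length, EI1, EI2, GJ, kc};
  std::vector<V3> F(n);
  std::vector<Q4> G(n - 1, Q4(0, 0, 0, 0));
  rod_elastic_core(r, q, active_first - 1, n, el, Om0, nullptr, nullptr, &F,
                   &G);
  NumericMatrix Fm(n, 3), Tm(n - 1, 3), Gm(n - 1, 4);
  // rod_elastic_core accumulates forces (-dV/dr) directly
  for (int i = 0; i < n; ++i) setrow3(Fm, i, F[i]);
  for (int j = 0; j < n - 1; ++j) {
    setrow4(Gm, j, G[j]);
    setrow3(Tm, j, torque_from_gradient(q[j], G[j]));
  }
  return List::create(_["forces"] = Fm, _["torques"] = Tm,
                      _["dVdq"] = Gm);
}

// [[Rcpp::export]]
NumericMatrix cpp_stretch_forces(NumericMatrix positions, int active_first,
                                 double rest_length, double EsA) {
  int n = positions.nrow();
  NumericMatrix F(n, 3);
  for (int j = active_first - 1; j <= n - 2; ++j) {
    V3 e = row3(positions, j + 1) - row3(positions, j);
    double len = norm(e);
    if (len <= 0.0) stop("degenerate geometry: coincident adjacent points");
    V3 t = e * (1.0 / len);
    double strain = (len - rest_length) / rest_length;
    V3 f = t * (EsA * strain); // pulls j toward j+1 when stretched
    F(j, 0) += f.x; F(j, 1) += f.y; F(j, 2) += f.z;
    F(j + 1, 0) -= f.x; F(j + 1, 1) -= f.y; F(j + 1, 2) -= f.z;
  }
  return F;
}

// ---------------------------------------------------------------------------
// Inextensibility chain: J W J^T is tri-diagonal because each distance
// constraint shares a point only with its neighbours.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_assemble_distance(NumericMatrix positions, NumericVector inv_mass,
                           NumericVector rest_lengths, int active_first) {
  int n = positions.nrow();
  int a0 = active_first - 1;
  int m = n - 1 - a0; // number of constraints
  if (m < 1) stop("need at least one element");
  NumericVector d(m), dl(std::max(m - 1, 0)), du(std::max(m - 1, 0)), c(m);
  NumericMatrix tang(m, 3);
  std::vector<V3> t(m);
  std::vector<double> len(m);
  for (int k = 0; k < m; ++k) {
    int p = a0 + k;
    V3 e = row3(positions, p + 1) - row3(positions, p);
    len[k] = norm(e);
    if (len[k] <= 0.0)
      stop("degenerate geometry: coincident adjacent points");
    t[k] = e * (1.0 / len[k]);
    setrow3(tang, k, t[k]);
    c[k] = len[k] - rest_lengths[k];
    d[k] = inv_mass[p] + inv_mass[p + 1];
  }
  for (int k = 0; k + 1 < m; ++k) {
    double w_shared = inv_mass[a0 + k + 1];
    double coup = -w_shared * dot(t[k], t[k + 1]);
    du[k] = coup; // A_{k,k+1}
    dl[k] = coup; // A_{k+1,k} (symmetric)
  }
  return List::create(_["diagonal"] = d, _["lower"] = dl, _["upper"] = du,
                      _["residual"] = c, _["tangents"] = tang);
}

// Gaussian elimination with partial pivoting on a tri-diagonal system via
// LAPACK dgtsv.
// [[Rcpp::export]]
NumericVector cpp_solve_tridiag(NumericVector lower, NumericVector diagonal,
                                NumericVector upper, NumericVector b) {
  int n = diagonal.size();
  if (b.size() != n) stop("rhs length mismatch");
  std::vector<double> dl(lower.begin(), lower.end());
  std::vector<double> d(diagonal.begin(), diagonal.end());
  std::vector<double> du(upper.begin(), upper.end());
  NumericVector x = clone(b);
  int info = 0, nrhs = 1;
  if (n == 1) {
    if (d[0] == 0.0) stop("singular tri-diagonal system");
    x[0] = b[0] / d[0];
    return x;
  }
  F77_CALL(dgtsv)(&n, &nrhs, dl.data(), d.data(), du.data(),
                  REAL(x), &n, &info);
  if (info != 0) stop("singular tri-diagonal system (dgtsv info = %d)", info);
  return x;
}

// Delta r = -W J^T lambda
// [[Rcpp::export]]
NumericMatrix cpp_apply_correction(NumericMatrix positions,
                                   NumericVector inv_mass,
                                   NumericVector lambda, NumericMatrix tangents,
                                   int active_first) {
  int n = positions.nrow();
  int a0 = active_first - 1;
  int m = lambda.size();
  NumericMatrix out = clone(positions);
  for (int k = 0; k < m; ++k) {
    int p = a0 + k;
    V3 t = row3(tangents, k);
    V3 dr = t * lambda[k];
    // J row k: -t at p, +t at p+1; correction = -W J^T lambda
    out(p, 0) += inv_mass[p] * dr.x;
    out(p, 1) += inv_mass[p] * dr.y;
    out(p, 2) += inv_mass[p] * dr.z;
    out(p + 1, 0) -= inv_mass[p + 1] * dr.x;
    out(p + 1, 1) -= inv_mass[p + 1] * dr.y;
    out(p + 1, 2) -= inv_mass[p + 1] * dr.z;
  }
  return out;
}

// Local position-level contact projection with a Coulomb friction cone.
// [[Rcpp::export]]
List cpp_project_contacts(NumericMatrix positions, NumericMatrix prev_positions,
                          IntegerVector point_index, NumericMatrix normals,
                          NumericVector depths, NumericVector mu) {
  NumericMatrix out = clone(positions);
  int nc = point_index.size();
  NumericVector normal_corr(nc), tangential_corr(nc);
  for (int k = 0; k < nc; ++k) {
    int p = point_index[k] - 1;
    V3 nrm = row3(normals, k);
    double d = depths[k];
    if (d <= 0.0) { normal_corr[k] = 0.0; tangential_corr[k] = 0.0; continue; }
    V3 r = row3(out, p) + nrm * d; // non-penetration push-out
    // tangential drift accumulated this step, measured against prev position
    V3 drift = r - row3(prev_positions, p);
    V3 drift_t = drift - nrm * dot(nrm, drift);
    double dt_mag = norm(drift_t);
    double cap = mu[k] * d;
    double corr;
    if (dt_mag <= cap) {
      r -= drift_t;           // stick: cancel tangential drift entirely
      corr = dt_mag;
    } else if (dt_mag > 0.0) {
      r -= drift_t * (cap / dt_mag); // slip: clamp to the friction cone
      corr = cap;
    } else {
      corr = 0.0;
    }
    setrow3(out, p, r);
    normal_corr[k] = d;
    tangential_corr[k] = corr;
  }
  return List::create(_["positions"] = out, _["normal_corr"] = normal_corr,
                      _["tangential_corr"] = tangential_corr);
}
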