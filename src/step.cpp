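#include "core.h"
#include <R_ext/Lapack.h>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Hybrid constraint time step.
//
// 1. Semi-implicit prediction: external + elastic forces update velocities,
//    elastic torques update angular velocities; positions and frames advance.
// 2. n_iterations sweeps of [global tri-diagonal solve of the distance-chain
//    (Gaussian elimination with partial pivoting) -> local projection of
//    contact constraints with Coulomb friction], contacts regenerated per
//    sweep and processed proximal-to-distal.
// 3. Velocities rederived from the realized displacement; quaternions
//    renormalized.
//
// The "penalty" variant replaces the global solve by the original stretch
// penalty force (applied in the prediction), keeping contacts identical.
// ---------------------------------------------------------------------------

struct StepContact {
  int point;   // 0-based
  int mesh;    // 0-based
  V3 normal;
  double depth;
  double normal_corr, tangential_corr;
};

// [[Rcpp::export]]
List cpp_rod_step(NumericMatrix positions, NumericMatrix velocities,
                  NumericMatrix quats, NumericMatrix omegas, int active_first,
                  List params, List config, IntegerVector presc_idx,
                  NumericMatrix presc_pos, IntegerVector pframe_idx,
                  NumericMatrix pframe_q, List meshes, bool penalty,
                  NumericVector feed_axis, NumericVector port,
                  double time) {
  const int n = positions.nrow();
  const int a0 = active_first - 1;
  if (a0 < 0 || a0 > n - 2) stop("invalid active_first");

  const double rest = as<double>(params["rest_length"]);
  const double radius = as<double>(params["radius"]);
  const double mass = as<double>(params["point_mass"]);
  const double EI1 = as<double>(params["EI1"]);
  const double EI2 = as<double>(params["EI2"]);
  const double GJ = as<double>(params["GJ"]);
  const double kc = as<double>(params["parallelism_stiffness"]);
  const double EsA = as<double>(params["EsA"]);
  const double lin_damp = as<double>(params["linear_damping"]);
  const double ang_damp = as<double>(params["angular_damping"]);
  double I_rot = as<double>(params["rotational_inertia"]);
  NumericMatrix Omega0m = params["intrinsic_darboux"];

  const double dt = as<double>(config["dt"]);
  const int n_iter = as<int>(config["n_iterations"]);
  NumericVector grav = config["gravity"];
  const double mu = as<double>(config["friction_mu"]);
  V3 g(grav[0], grav[1], grav[2]);
  V3 axis(feed_axis[0], feed_axis[1], feed_axis[2]);
  V3 port_p(port[0], port[1], port[2]);

  if (I_rot <= 0.0) {
    // stabilizing frame inertia scaled to the step: keeps the stiffest
    // rotational mode at omega*dt ~ 0.25 (frames are quasi-static carriers)
    double krot = std::max(std::max(EI1, EI2), GJ) / rest + kc * rest;
    I_rot = 32.0 * dt * dt * krot;
  }

  std::vector<V3> r(n), v(n), r_start(n);
  std::vector<Q4> q(n - 1);
  std::vector<V3> w(n - 1);
  for (int i = 0; i < n; ++i) { r[i] = row3(positions, i); v[i] = row3(velocities, i); r_start[i] = r[i]; }
  for (int j = 0; j < n - 1; ++j) { q[j] = row4(quats, j); w[j] = row3(omegas, j); }

  std::vector<V3> Om0(std::max(n - 2, 0));
  for (int k = 0; k < n - 2; ++k) Om0[k] = row3(Omega0m, k);

  // --- elastic forces and torques at the start-of-step configuration -------
  RodElastic el{rest, EI1, EI2, GJ, kc};
  std::vector<V3> F(n);
  std::vector<Q4> dVdq(n - 1, Q4(0, 0, 0, 0));
  rod_elastic_core(r, q, a0, n, el, Om0, nullptr, nullptr, &F, &dVdq);
  if (penalty && EsA > 0.0) {
    for (int j = a0; j <= n - 2; ++j) {
      V3 e = r[j + 1] - r[j];
      double len = norm(e);
      if (len <= 0.0) stop("degenerate geometry: coincident adjacent points");
      V3 t = e * (1.0 / len);
      V3 f = t * (EsA * (len - rest) / rest);
      F[j] += f;
      F[j + 1] -= f;
    }
  }

  // prescribed lookup
  std::vector<char> is_presc(n, 0);
  for (int k = 0; k < presc_idx.size(); ++k) is_presc[presc_idx[k] - 1] = 1;
  std::vector<char> is_pframe(n - 1, 0);
  for (int k = 0; k < pframe_idx.size(); ++k) is_pframe[pframe_idx[k] - 1] = 1;

  // --- prediction ----------------------------------------------------------
  const double vdamp = std::max(0.0, 1.0 - lin_damp * dt);
  const double wdamp = std::max(0.0, 1.0 - ang_damp * dt);
  for (int i = a0; i < n; ++i) {
    if (is_presc[i]) continue;
    v[i] += (F[i] * (1.0 / mass) + g) * dt;
    v[i] *= vdamp;
    r[i] += v[i] * dt;
  }
  for (int k = 0; k < presc_idx.size(); ++k) {
    int i = presc_idx[k] - 1;
    V3 target = row3(presc_pos, k);
    v[i] = (target - r_start[i]) * (1.0 / dt);
    r[i] = target;
  }
  for (int j = a0; j <= n - 2; ++j) {
    if (is_pframe[j]) continue;
    V3 tau = torque_from_gradient(q[j], dVdq[j]);
    w[j] += tau * (dt / I_rot);
    w[j] *= wdamp;
    q[j] = qnormalize(qmul(q[j], qexp_rotvec(w[j] * dt)));
  }
  for (int k = 0; k < pframe_idx.size(); ++k) {
    int j = pframe_idx[k] - 1;
    Q4 target = qnormalize(row4(pframe_q, k));
    Q4 dq = qmul(qconj(q[j]), target);
    double ang = 2.0 * std::atan2(
        std::sqrt(dq.x * dq.x + dq.y * dq.y + dq.z * dq.z), std::fabs(dq.w));
    V3 ax = normalized(V3(dq.x, dq.y, dq.z));
    if (dq.w < 0) ax = -ax;
    w[j] = ax * (ang / dt);
    q[j] = target;
  }

  // --- hybrid constraint sweeps -------------------------------------------
  std::vector<double> inv_mass(n, 1.0 / mass);
  for (int i = 0; i < n; ++i) if (is_presc[i]) inv_mass[i] = 0.0;
  // Elements joining two prescribed points are satisfied by the drive
  // itself; keeping them would make the banded system singular.  Because
  // the off-diagonal coupling through a prescribed (zero inverse mass)
  // point vanishes, the remaining constraints split into independent
  // contiguous tri-diagonal blocks.
  std::vector<std::pair<int, int>> blocks; // [first, last] element index
  {
    int e = a0;
    while (e <= n - 2) {
      if (inv_mass[e] == 0.0 && inv_mass[e + 1] == 0.0) { ++e; continue; }
      int b0 = e;
      while (e <= n - 2 && !(inv_mass[e] == 0.0 && inv_mass[e + 1] == 0.0))
        ++e;
      blocks.push_back(std::make_pair(b0, e - 1));
    }
  }
  std::vector<double> lambda_acc(n - 1, 0.0); // per element
  std::vector<V3> tang(n - 1);

  std::vector<StepContact> contacts_all;
  double contact_impulse_sum = 0.0; // N (|impulse|/dt summed over contacts)
  int nm = meshes.size();
  std::vector<MeshView> mesh_views;
  for (int mi = 0; mi < nm; ++mi) {
    List M = meshes[mi];
    mesh_views.emplace_back(as<NumericMatrix>(M["vertices"]),
                            as<IntegerMatrix>(M["faces"]),
                            as<List>(M["bvh"]));
  }

  for (int it = 0; it < n_iter; ++it) {
    if (!penalty) {
      // global banded solve of the inextensibility chain, block by block
      for (size_t bi = 0; bi < blocks.size(); ++bi) {
        int b0 = blocks[bi].first, b1 = blocks[bi].second;
        int mb = b1 - b0 + 1;
        std::vector<double> dl(std::max(mb - 1, 0)), dd(mb),
            du(std::max(mb - 1, 0)), lam(mb);
        for (int k = 0; k < mb; ++k) {
          int p = b0 + k;
          V3 e = r[p + 1] - r[p];
          double len = norm(e);
          if (len <= 0.0)
            stop("degenerate geometry: coincident adjacent points");
          tang[p] = e * (1.0 / len);
          lam[k] = len - rest;
          dd[k] = inv_mass[p] + inv_mass[p + 1];
        }
        for (int k = 0; k + 1 < mb; ++k) {
          double coup =
              -inv_mass[b0 + k + 1] * dot(tang[b0 + k], tang[b0 + k + 1]);
          dl[k] = coup;
          du[k] = coup;
        }
        if (mb == 1) {
          if (dd[0] == 0.0) stop("singular constraint system");
          lam[0] /= dd[0];
        } else {
          int info = 0, nrhs_ = 1, mm = mb;
          F77_CALL(dgtsv)(&mm, &nrhs_, dl.data(), dd.data(), du.data(),
                          lam.data(), &mm, &info);
          if (info != 0)
            stop("singular constraint system (dgtsv info %d)", info);
        }
        for (int k = 0; k < mb; ++k) {
          int p = b0 + k;
          V3 dr = tang[p] * lam[k];
          r[p] += dr * inv_mass[p];
          r[p + 1] -= dr * inv_mass[p + 1];
          lambda_acc[p] += lam[k];
        }
      }
    }
    // local contact projection, proximal to distal
    if (nm > 0) {
      for (int i = a0; i < n; ++i) {
        if (is_presc[i]) continue;
        for (int mi = 0; mi < nm; ++mi) {
          double dist;
          V3 cp;
          int face;
          if (!mesh_nearest(mesh_views[mi], r[i], radius, dist, cp, face))
            continue;
          if (dist >= radius) continue;
          V3 nrm;
          if (dist > 1e-12) nrm = (r[i] - cp) * (1.0 / dist);
          else {
            V3 back = r_start[i] - cp;
            nrm = (norm(back) > 1e-12) ? normalized(back) : V3(0, 0, 1);
          }
          double depth = radius - dist;
          r[i] += nrm * depth;
          V3 drift = r[i] - r_start[i];
          V3 drift_t = drift - nrm * dot(nrm, drift);
          double dmag = norm(drift_t);
          double cap = mu * depth;
          double tcorr;
          if (dmag <= cap) { r[i] -= drift_t; tcorr = dmag; }
          else if (dmag > 0.0) { r[i] -= drift_t * (cap / dmag); tcorr = cap; }
          else tcorr = 0.0;
          StepContact sc;
          sc.point = i; sc.mesh = mi; sc.normal = nrm; sc.depth = depth;
          sc.normal_corr = depth; sc.tangential_corr = tcorr;
          contacts_all.push_back(sc);
          contact_impulse_sum +=
              mass * std::sqrt(depth * depth + tcorr * tcorr) / (dt * dt);
        }
      }
    }
  }

  // --- velocity rederivation and sanity ------------------------------------
  for (int i = a0; i < n; ++i) {
    if (!is_presc[i]) v[i] = (r[i] - r_start[i]) * (1.0 / dt);
    if (!std::isfinite(r[i].x) || !std::isfinite(r[i].y) ||
        !std::isfinite(r[i].z))
      stop("instability detected: non-finite position at point %d", i + 1);
    if (norm(v[i]) > 1e5)
      stop("instability detected: diverging velocity at point %d", i + 1);
  }
  for (int j = a0; j <= n - 2; ++j) {
    if (!std::isfinite(q[j].w) || !std::isfinite(q[j].x) ||
        !std::isfinite(q[j].y) || !std::isfinite(q[j].z))
      stop("instability detected: non-finite frame quaternion %d", j + 1);
    if (norm(w[j]) > 1e6)
      stop("instability detected: diverging angular velocity at frame %d",
           j + 1);
  }

  double max_rel_elong = 0.0;
  for (int k = a0; k <= n - 2; ++k) {
    int p = k;
    double len = norm(r[p + 1] - r[p]);
    max_rel_elong = std::max(max_rel_elong, std::fabs(len - rest) / rest);
  }

  // --- base reaction --------------------------------------------------------
  // Force the rod transmits to the prescribed (driven) points: gravity +
  // elastic + constraint-chain tension.  lambda/dt^2 converts the positional
  // multiplier into a force.
  V3 reaction(0, 0, 0);
  double reaction_torque = 0.0;
  for (int kk = 0; kk < presc_idx.size(); ++kk) {
    int i = presc_idx[kk] - 1;
    V3 f = F[i] + g * mass;
    int kR = i;     // element with left point i
    int kL = i - 1; // element with right point i
    if (kR >= 0 && kR <= n - 2)
      f += tang[kR] * (lambda_acc[kR] / (dt * dt));
    if (kL >= 0 && kL <= n - 2)
      f -= tang[kL] * (lambda_acc[kL] / (dt * dt));
    reaction += f;
    reaction_torque += dot(cross(r[i] - port_p, f), axis);
  }
  for (int kk = 0; kk < pframe_idx.size(); ++kk) {
    int j = pframe_idx[kk] - 1;
    V3 tau_body = torque_from_gradient(q[j], dVdq[j]);
    reaction_torque += dot(qrotate(q[j], tau_body), axis);
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3), q_out(n - 1, 4), w_out(n - 1, 3);
  for (int i = 0; i < n; ++i) { setrow3(pos_out, i, r[i]); setrow3(vel_out, i, v[i]); }
  for (int j = 0; j < n - 1; ++j) { setrow4(q_out, j, q[j]); setrow3(w_out, j, w[j]); }

  int nc = (int)contacts_all.size();
  IntegerVector c_pt(nc), c_mesh(nc);
  NumericVector c_ncorr(nc), c_tcorr(nc), c_depth(nc);
  std::vector<char> touched(n, 0);
  for (int k = 0; k < nc; ++k) {
    c_pt[k] = contacts_all[k].point + 1;
    c_mesh[k] = contacts_all[k].mesh + 1;
    c_ncorr[k] = contacts_all[k].normal_corr;
    c_tcorr[k] = contacts_all[k].tangential_corr;
    c_depth[k] = contacts_all[k].depth;
    touched[contacts_all[k].point] = 1;
  }
  int n_points_in_contact = 0;
  for (int i = 0; i < n; ++i) n_points_in_contact += touched[i];

  List diag = List::create(
      _["max_rel_elongation"] = max_rel_elong,
      _["n_contacts"] = nc,
      _["n_points_in_contact"] = n_points_in_contact,
      _["contact_points"] = c_pt,
      _["contact_mesh"] = c_mesh,
      _["contact_normal_corr"] = c_ncorr,
      _["contact_tangential_corr"] = c_tcorr,
      _["tissue_force"] = contact_impulse_sum,
      _["reaction_force"] =
          NumericVector::create(reaction.x, reaction.y, reaction.z),
      _["axial_force"] = dot(reaction, axis),
      _["axial_torque"] = reaction_torque);

  return List::create(_["positions"] = pos_out, _["velocities"] = vel_out,
                      _["frames"] = q_out, _["angular_velocities"] = w_out,
                      _["time"] = time + dt, _["diagnostics"] = diag);
}
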