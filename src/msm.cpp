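#include "core.h"

using namespace Rcpp;

// Semi-implicit Euler step of a mass-spring body.  Spring force
// -k (len - rest) dir - k_d (relvel . dir) dir applied equal and opposite;
// pinned nodes copy their driver position with zero velocity.
// [[Rcpp::export]]
List cpp_msm_step(NumericMatrix positions, NumericMatrix velocities,
                  NumericVector masses, IntegerVector si, IntegerVector sj,
                  NumericVector rest, NumericVector stiffness,
                  NumericVector damping, LogicalVector alive,
                  IntegerVector pin_idx, NumericMatrix pin_pos, double dt,
                  NumericVector gravity) {
  int n = positions.nrow();
  int ns = si.size();
  std::vector<V3> r(n), v(n), F(n);
  for (int i = 0; i < n; ++i) {
    r[i] = row3(positions, i);
    v[i] = row3(velocities, i);
  }
  for (int s = 0; s < ns; ++s) {
    if (!alive[s]) continue;
    int a = si[s] - 1, b = sj[s] - 1;
    V3 d = r[b] - r[a];
    double len = norm(d);
    if (len <= 0.0) stop("degenerate spring (coincident nodes)");
    V3 dir = d * (1.0 / len);
    V3 relv = v[b] - v[a];
    double fmag = stiffness[s] * (len - rest[s]) +
                  damping[s] * dot(relv, dir);
    V3 f = dir * fmag; // on node a, along +dir when stretched
    F[a] += f;
    F[b] -= f;
  }
  V3 g(gravity[0], gravity[1], gravity[2]);
  for (int i = 0; i < n; ++i) {
    v[i] += (F[i] * (1.0 / masses[i]) + g) * dt;
    r[i] += v[i] * dt;
  }
  for (int k = 0; k < pin_idx.size(); ++k) {
    int i = pin_idx[k] - 1;
    r[i] = row3(pin_pos, k);
    v[i] = V3(0, 0, 0);
  }
  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(r[i].x) || !std::isfinite(r[i].y) ||
        !std::isfinite(r[i].z))
      stop("instability detected: non-finite node position");
    setrow3(pos_out, i, r[i]);
    setrow3(vel_out, i, v[i]);
  }
  return List::create(_["positions"] = pos_out, _["velocities"] = vel_out);
}
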