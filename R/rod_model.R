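## Geometric and elastic core of the discrete Cosserat rod.
##
## A rod with n centreline mass points carries n-1 unit-quaternion material
## frames (one per element, between neighbouring points) and n-2 interior
## junctions at which the discrete Darboux vector measures bend and twist.

#' Rod parameters
#'
#' Geometric and material parameters of the discrete Cosserat rod.  Derived
#' section properties (area `A`, bending moments `I1 = I2`, polar moment `J`
#' and the stiffness matrix `K = diag(E I1, E I2, G J)`) are computed from
#' the radius and moduli and stored alongside.
#'
#' @param n_points Number of centreline mass points (>= 3).
#' @param rest_length Per-element rest length, m.
#' @param radius Cross-section radius, m.
#' @param point_mass Per-point mass, kg.
#' @param young_modulus Young's modulus E, Pa (bending).
#' @param shear_modulus Shear modulus G, Pa (torsion).
#' @param stretch_modulus Stretching Young's modulus E_s, Pa.  Only used by
#'   the stretch-penalty baseline variant; `NA` for the constrained rod.
#' @param parallelism_stiffness Frame-tangent coupling penalty k_c, N.
#' @param linear_damping Linear velocity damping rate, 1/s.
#' @param angular_damping Angular velocity damping rate, 1/s.
#' @param intrinsic_darboux Intrinsic (actuation target) Darboux vectors, an
#'   `(n_points - 2) x 3` matrix in 1/m, one row per interior junction;
#'   defaults to zero (straight, untwisted rest shape).
#' @param rotational_inertia Frame rotational inertia, kg m^2.  `NULL`
#'   (default) selects a stabilizing inertia scaled to the solver time step;
#'   the material frames are quasi-static carriers of orientation, so their
#'   inertia only sets the relaxation time scale, not equilibria.
#' @return An object of class `rod_parameters`.
#' @seealso [default_endoscope_parameters()]
#' @export
rod_parameters <- function(n_points, rest_length, radius, point_mass,
                           young_modulus, shear_modulus,
                           stretch_modulus = NA_real_,
                           parallelism_stiffness = 100,
                           linear_damping = 0, angular_damping = 0,
                           intrinsic_darboux = NULL,
                           rotational_inertia = NULL) {
  stopifnot(n_points >= 3, rest_length > 0, radius > 0, point_mass > 0,
            young_modulus > 0, shear_modulus > 0, parallelism_stiffness > 0,
            linear_damping >= 0, angular_damping >= 0)
  if (!is.na(stretch_modulus)) stopifnot(stretch_modulus > 0)
  if (is.null(intrinsic_darboux)) {
    intrinsic_darboux <- matrix(0, n_points - 2, 3)
  }
  intrinsic_darboux <- as.matrix(intrinsic_darboux)
  if (nrow(intrinsic_darboux) != n_points - 2 ||
      ncol(intrinsic_darboux) != 3) {
    stop("intrinsic_darboux must be an (n_points - 2) x 3 matrix")
  }
  A <- pi * radius^2
  I1 <- pi * radius^4 / 4
  J <- pi * radius^4 / 2
  structure(list(
    n_points = as.integer(n_points),
    rest_length = rest_length,
    radius = radius,
    point_mass = point_mass,
    young_modulus = young_modulus,
    shear_modulus = shear_modulus,
    stretch_modulus = stretch_modulus,
    parallelism_stiffness = parallelism_stiffness,
    linear_damping = linear_damping,
    angular_damping = angular_damping,
    intrinsic_darboux = intrinsic_darboux,
    rotational_inertia = if (is.null(rotational_inertia)) NA_real_
                         else rotational_inertia,
    area = A, I1 = I1, I2 = I1, J = J,
    EI1 = young_modulus * I1, EI2 = young_modulus * I1,
    GJ = shear_modulus * J
  ), class = "rod_parameters")
}

#' Default virtual-endoscope parameters
#'
#' A 100-point, 1.5 m rod of 6 mm radius: stand-in mechanical values for a
#' gastroscope-like instrument whose true stiffness and mass distribution
#' would be identified empirically against a physical scope.  All values can
#' be overridden in scenario configurations.
#'
#' @param ... Overrides passed to [rod_parameters()].
#' @return A `rod_parameters` object.
#' @export
default_endoscope_parameters <- function(...) {
  defaults <- list(
    n_points = 100L,
    rest_length = 1.5 / 99,
    radius = 0.006,
    point_mass = 0.004,
    young_modulus = 1e7,
    shear_modulus = 5e6,
    parallelism_stiffness = 100,
    linear_damping = 2,
    angular_damping = 5
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(rod_parameters, args)
}

#' Rod dynamic state
#'
#' Builds a rod state from explicit components, validating the invariants:
#' unit frame quaternions (within 1e-9), finite components and an active
#' count between 2 and `n_points`.  The `active_count` most distal points
#' (the highest indices) are "inside the workspace"; the remainder are not
#' yet inserted and carry no dynamics.
#'
#' @param time Simulation time, s.
#' @param positions `n x 3` matrix of centreline point positions, m.
#' @param velocities `n x 3` matrix, m/s.
#' @param frames `(n-1) x 4` matrix of unit material-frame quaternions
#'   `(w, x, y, z)`, one per element.
#' @param angular_velocities `(n-1) x 3` matrix of body-frame angular
#'   velocities, rad/s.
#' @param active_count Number of points currently inside the workspace.
#' @return An object of class `rod_state`.
#' @export
rod_state <- function(positions, frames,
                      velocities = NULL, angular_velocities = NULL,
                      time = 0, active_count = nrow(positions)) {
  positions <- as.matrix(positions)
  frames <- as.matrix(frames)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(angular_velocities)) angular_velocities <- matrix(0, n - 1, 3)
  st <- structure(list(
    time = time,
    positions = positions,
    velocities = as.matrix(velocities),
    frames = frames,
    angular_velocities = as.matrix(angular_velocities),
    active_count = as.integer(active_count)
  ), class = "rod_state")
  validate_rod_state(st)
  st
}

#' Validate a rod state's invariants
#'
#' @param state A `rod_state`.
#' @param quat_tol Allowed deviation of frame quaternion norms from 1.
#' @return `state`, invisibly; errors if an invariant is violated.
#' @export
validate_rod_state <- function(state, quat_tol = 1e-9) {
  n <- nrow(state$positions)
  stopifnot(ncol(state$positions) == 3,
            nrow(state$velocities) == n,
            nrow(state$frames) == n - 1, ncol(state$frames) == 4,
            nrow(state$angular_velocities) == n - 1)
  if (!all(is.finite(state$positions)) || !all(is.finite(state$velocities)) ||
      !all(is.finite(state$frames)) ||
      !all(is.finite(state$angular_velocities))) {
    stop("invalid state: non-finite component")
  }
  qn <- sqrt(rowSums(state$frames^2))
  j <- active_first_frame(state)
  if (any(abs(qn[j:(n - 1)] - 1) > quat_tol)) {
    stop("invalid state: frame quaternion norm deviates by ",
         format(max(abs(qn - 1))))
  }
  if (state$active_count < 2 || state$active_count > n) {
    stop("invalid state: active_count must be in [2, n_points]")
  }
  invisible(state)
}

# 1-based index of the first (most proximal) active point / frame
active_first_point <- function(state) {
  nrow(state$positions) - state$active_count + 1L
}
active_first_frame <- function(state) active_first_point(state)

#' Straight rod state along an axis
#'
#' Convenience constructor: points spaced at the rest length along `axis`
#' starting from `origin` (the most proximal point), frames aligned so that
#' the director \eqn{d_3} follows the axis, optionally rolled about it.
#'
#' @param params A `rod_parameters` object.
#' @param origin Position of the first (most proximal) point, m.
#' @param axis Direction of the centreline (3-vector).
#' @param roll Roll angle about the axis, rad.
#' @param active_count Number of active points (default: all).
#' @return A `rod_state`.
#' @export
straight_rod_state <- function(params, origin = c(0, 0, 0),
                               axis = c(1, 0, 0), roll = 0,
                               active_count = params$n_points) {
  n <- params$n_points
  u <- axis / sqrt(sum(axis^2))
  s <- (seq_len(n) - 1) * params$rest_length
  positions <- cbind(origin[1] + s * u[1], origin[2] + s * u[2],
                     origin[3] + s * u[3])
  q <- quat_multiply(quat_from_to(c(0, 0, 1), u),
                     quat_axis_angle(c(0, 0, 1), roll))
  frames <- matrix(rep(quat_normalize(q), each = n - 1), n - 1, 4)
  rod_state(positions, frames, active_count = active_count)
}

# Parameter list handed to the compiled core.
params_for_cpp <- function(params) {
  EsA <- if (is.na(params$stretch_modulus)) 0 else
    params$stretch_modulus * params$area
  list(rest_length = params$rest_length,
       radius = params$radius,
       point_mass = params$point_mass,
       EI1 = params$EI1, EI2 = params$EI2, GJ = params$GJ,
       parallelism_stiffness = params$parallelism_stiffness,
       EsA = EsA,
       linear_damping = params$linear_damping,
       angular_damping = params$angular_damping,
       rotational_inertia = if (is.na(params$rotational_inertia)) -1
                            else params$rotational_inertia,
       intrinsic_darboux = params$intrinsic_darboux)
}

#' Bend/twist elastic energy of the rod
#'
#' Discrete unified bend/twist energy
#' \deqn{V_{bt} = \sum_k \tfrac12 (\Omega_k - \Omega^0_k)^T K
#'   (\Omega_k - \Omega^0_k)\, \mathrm{span}_k}
#' with \eqn{K = \mathrm{diag}(E I_1, E I_2, G J)} and \eqn{\Omega_k} the
#' Darboux vector at interior junction k.
#'
#' @param state A `rod_state`.
#' @param params A `rod_parameters`.
#' @return Energy in J (>= 0, zero iff all junction strains equal the
#'   intrinsic Darboux targets).
#' @export
bend_twist_energy <- function(state, params) {
  e <- cpp_rod_energy(state$positions, state$frames,
                      active_first_point(state),
                      params$rest_length, params$EI1, params$EI2, params$GJ,
                      params$parallelism_stiffness, params$intrinsic_darboux)
  e$bend_twist
}

#' Frame-tangent parallelism energy
#'
#' Penalty coupling each material frame's director \eqn{d_3} to its element's
#' unit tangent:
#' \deqn{V_p = \sum_j \tfrac12 k_c |d_3(q_j) - t_j|^2 \, l_j.}
#' This is what transmits bending moments to the centreline.
#'
#' @inheritParams bend_twist_energy
#' @return Energy in J (zero iff every frame's d3 equals its element tangent).
#' @export
parallelism_energy <- function(state, params) {
  e <- cpp_rod_energy(state$positions, state$frames,
                      active_first_point(state),
                      params$rest_length, params$EI1, params$EI2, params$GJ,
                      params$parallelism_stiffness, params$intrinsic_darboux)
  e$parallelism
}

#' Elastic generalized forces of the rod
#'
#' Negative gradient of the total elastic energy (bend/twist + parallelism)
#' with respect to point positions and frame rotations.  Torques are
#' expressed in the body frame of each quaternion, obtained from the
#' quaternion gradient by \eqn{\tau = \tfrac12\,\mathrm{vec}(\bar q \otimes
#' (-\partial V/\partial q))}, i.e. the torque conjugate to a body-frame
#' rotation.
#'
#' @inheritParams bend_twist_energy
#' @return A list with `forces` (`n x 3`, N), `torques` (`(n-1) x 3`, N m,
#'   body frame) and `dVdq` (`(n-1) x 4`, raw quaternion gradient).
#' @export
elastic_forces <- function(state, params) {
  cpp_rod_forces(state$positions, state$frames, active_first_point(state),
                 params$rest_length, params$EI1, params$EI2, params$GJ,
                 params$parallelism_stiffness, params$intrinsic_darboux)
}

#' Stretch penalty forces (baseline variant)
#'
#' The original penalty treatment of centreline stretch: each element exerts
#' a restoring force of magnitude \eqn{E_s A \,\epsilon} along its axis,
#' equal and opposite on its endpoints.  Retained for benchmarking against
#' the hard distance-constraint chain.
#'
#' @inheritParams bend_twist_energy
#' @return `n x 3` matrix of forces, N.
#' @export
stretch_penalty_forces <- function(state, params) {
  if (is.na(params$stretch_modulus)) {
    stop("stretch_modulus is not set on these parameters")
  }
  cpp_stretch_forces(state$positions, active_first_point(state),
                     params$rest_length,
                     params$stretch_modulus * params$area)
}

#' @export
print.rod_parameters <- function(x, ...) {
  cat("<rod_parameters> ", x$n_points, " points, element ",
      format(x$rest_length * 1000), " mm, radius ",
      format(x$radius * 1000), " mm\n", sep = "")
  cat("  E = ", format(x$young_modulus), " Pa, G = ",
      format(x$shear_modulus), " Pa, k_c = ",
      format(x$parallelism_stiffness), " N\n", sep = "")
  invisible(x)
}

#' @export
print.rod_state <- function(x, ...) {
  cat("<rod_state> t = ", format(x$time), " s, ",
      nrow(x$positions), " points (", x$active_count, " active)\n", sep = "")
  invisible(x)
}
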