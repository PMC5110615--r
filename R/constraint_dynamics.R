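## Time stepping and the hybrid constraint solver: global tri-diagonal
## banded solve of the inextensibility chain, then local Coulomb-friction
## contact projection, iterated.

#' Solver configuration
#'
#' @param dt Time step, s.
#' @param n_iterations Number of global+local constraint sweeps per step.
#' @param distance_tolerance Maximum tolerated relative element elongation in
#'   contact-free flight (dimensionless).
#' @param gravity Gravitational acceleration vector, m/s^2.
#' @param friction_mu Coulomb friction coefficient (>= 0).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 1e-3, n_iterations = 2,
                          distance_tolerance = 1e-6,
                          gravity = c(0, 0, -9.81), friction_mu = 0.3) {
  stopifnot(dt > 0, n_iterations >= 1, friction_mu >= 0,
            length(gravity) == 3)
  structure(list(dt = dt, n_iterations = as.integer(n_iterations),
                 distance_tolerance = distance_tolerance,
                 gravity = as.numeric(gravity), friction_mu = friction_mu),
            class = "solver_config")
}

#' Contact constraint set
#'
#' A plain data frame of point contacts produced by collision detection and
#' consumed by the local projection step.
#'
#' @param point_index Rod point indices (1-based).
#' @param normal `k x 3` matrix of unit normals pointing out of the obstacle.
#' @param depth Penetration depths, m (>= 0).
#' @param mu Friction coefficients (recycled).
#' @return A `data.frame` with columns `point_index`, `nx`, `ny`, `nz`,
#'   `depth`, `mu`.
#' @export
contact_constraints <- function(point_index, normal, depth, mu = 0.3) {
  normal <- matrix(normal, ncol = 3)
  nn <- sqrt(rowSums(normal^2))
  if (any(abs(nn - 1) > 1e-9)) stop("contact normals must be unit vectors")
  if (any(depth < 0)) stop("contact depth must be >= 0")
  data.frame(point_index = as.integer(point_index),
             nx = normal[, 1], ny = normal[, 2], nz = normal[, 3],
             depth = depth, mu = rep_len(mu, length(point_index)))
}

#' Assemble the inextensibility-chain system
#'
#' Builds the tri-diagonal system \eqn{A = J W J^T} of the distance
#' constraints along the centreline, where row k of the Jacobian J is
#' \eqn{(-t_k, +t_k)} at points k and k+1 (t_k the unit element tangent) and
#' W the diagonal of inverse masses.  The residual is
#' \eqn{c_k = |r_{k+1} - r_k| - l_k}.
#'
#' @param positions `n x 3` matrix of point positions.
#' @param inverse_masses Length-n vector of inverse masses (0 = prescribed).
#' @param rest_lengths Per-element rest lengths (length n-1), m.
#' @return An object of class `tridiagonal_system`: list with `diagonal`,
#'   `lower`, `upper`, `residual` and `tangents`.
#' @export
assemble_distance_system <- function(positions, inverse_masses,
                                     rest_lengths) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(length(inverse_masses) == n, length(rest_lengths) == n - 1)
  sys <- cpp_assemble_distance(positions, as.numeric(inverse_masses),
                               as.numeric(rest_lengths), 1L)
  structure(sys, class = "tridiagonal_system")
}

#' @export
as.matrix.tridiagonal_system <- function(x, ...) {
  m <- length(x$diagonal)
  A <- diag(x$diagonal, m, m)
  if (m > 1) {
    A[cbind(2:m, 1:(m - 1))] <- x$lower
    A[cbind(1:(m - 1), 2:m)] <- x$upper
  }
  A
}

#' Solve a tri-diagonal system by Gaussian elimination with partial pivoting
#'
#' All distance constraints are solved at once ("globally") through the
#' LAPACK banded solver `dgtsv`, which performs Gaussian elimination with
#' partial pivoting on the three bands.
#'
#' @param A A `tridiagonal_system` (from [assemble_distance_system()]) or a
#'   list with `lower`, `diagonal`, `upper` band vectors.
#' @param b Right-hand side; defaults to the system's constraint residual.
#' @return The multiplier vector lambda solving `A lambda = b`.
#' @export
solve_banded_pp <- function(A, b = A$residual) {
  cpp_solve_tridiag(A$lower, A$diagonal, A$upper, b)
}

#' Apply the distance-constraint correction
#'
#' Completes the global step: positions move by \eqn{\Delta r = -W J^T
#' \lambda}, so each constraint's residual shrinks and prescribed points
#' (zero inverse mass) stay put.
#'
#' @inheritParams assemble_distance_system
#' @param lambda Multipliers from [solve_banded_pp()].
#' @param tangents `(n-1) x 3` unit element tangents used in the assembly.
#' @return Corrected `n x 3` position matrix.
#' @export
apply_distance_correction <- function(positions, inverse_masses, lambda,
                                      tangents) {
  cpp_apply_correction(as.matrix(positions), as.numeric(inverse_masses),
                       as.numeric(lambda), as.matrix(tangents), 1L)
}

#' Project contact constraints locally with Coulomb friction
#'
#' Each contacted point is displaced by its penetration depth along the
#' contact normal; the tangential drift accumulated since
#' `previous_positions` is then cancelled up to the friction cone
#' (\eqn{|\Delta t| \le \mu\,|\Delta n|}): fully in the stick regime,
#' clamped to the cone when sliding.
#'
#' @param positions Current `n x 3` positions.
#' @param previous_positions Positions at the start of the step.
#' @param contacts A contact data frame from [contact_constraints()] or
#'   [generate_rod_contacts()].
#' @param mu Optional scalar overriding the per-contact friction coefficient.
#' @return A list with corrected `positions` and per-contact `normal_corr`
#'   and `tangential_corr` magnitudes.
#' @export
project_contacts <- function(positions, previous_positions, contacts,
                             mu = NULL) {
  if (is.null(contacts) || nrow(contacts) == 0) {
    return(list(positions = as.matrix(positions),
                normal_corr = numeric(0), tangential_corr = numeric(0)))
  }
  muv <- if (is.null(mu)) contacts$mu else rep_len(mu, nrow(contacts))
  cpp_project_contacts(as.matrix(positions), as.matrix(previous_positions),
                       as.integer(contacts$point_index),
                       cbind(contacts$nx, contacts$ny, contacts$nz),
                       contacts$depth, muv)
}

#' Advance the rod by one hybrid time step
#'
#' Semi-implicit prediction under gravity, elastic forces/torques and
#' damping, followed by `n_iterations` sweeps of global banded distance
#' solve and local contact projection; velocities are rederived from the
#' realized displacement and frames renormalized.
#'
#' @param state A `rod_state`.
#' @param params A `rod_parameters`.
#' @param config A `solver_config`.
#' @param collision Optional list of collidable meshes (each a `tri_mesh`
#'   with a built BVH, see [build_bvh()]); contacts are generated
#'   sphere-vs-mesh at the rod radius inside each sweep.
#' @param prescribed_points Optional list with `index` (1-based point ids)
#'   and `positions` (`k x 3` targets): driven points with infinite mass.
#' @param prescribed_frames Optional list with `index` (1-based frame ids)
#'   and `quaternions` (`k x 4` targets).
#' @param variant `"constrained"` (hard distance chain, default) or
#'   `"penalty"` (original stretch-penalty baseline; requires
#'   `stretch_modulus`).
#' @param feed_axis Unit vector of the insertion axis used to resolve the
#'   base reaction, default +x.
#' @param port Reference point for reaction torques (defaults to the first
#'   prescribed point, or the origin).
#' @return The advanced `rod_state`; the step diagnostics (contacts,
#'   max relative elongation, base reaction) are attached as attribute
#'   `"diagnostics"`.
#' @export
rod_step <- function(state, params, config, collision = NULL,
                     prescribed_points = NULL, prescribed_frames = NULL,
                     variant = c("constrained", "penalty"),
                     feed_axis = c(1, 0, 0), port = NULL) {
  variant <- match.arg(variant)
  pp_idx <- integer(0); pp_pos <- matrix(0, 0, 3)
  if (!is.null(prescribed_points)) {
    pp_idx <- as.integer(prescribed_points$index)
    pp_pos <- matrix(prescribed_points$positions, ncol = 3)
  }
  pf_idx <- integer(0); pf_q <- matrix(0, 0, 4)
  if (!is.null(prescribed_frames)) {
    pf_idx <- as.integer(prescribed_frames$index)
    pf_q <- matrix(prescribed_frames$quaternions, ncol = 4)
  }
  if (is.null(port)) {
    port <- if (length(pp_idx)) state$positions[pp_idx[1], ] else c(0, 0, 0)
  }
  meshes <- prepare_collision(collision)
  out <- cpp_rod_step(state$positions, state$velocities, state$frames,
                      state$angular_velocities, active_first_point(state),
                      params_for_cpp(params), unclass(config),
                      pp_idx, pp_pos, pf_idx, pf_q, meshes,
                      identical(variant, "penalty"),
                      as.numeric(feed_axis), as.numeric(port), state$time)
  new_state <- structure(list(
    time = out$time,
    positions = out$positions,
    velocities = out$velocities,
    frames = out$frames,
    angular_velocities = out$angular_velocities,
    active_count = state$active_count
  ), class = "rod_state")
  attr(new_state, "diagnostics") <- out$diagnostics
  new_state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prepare a collidable mesh set
#'
#' Builds any missing BVHs and strips the meshes down to the arrays the
#' solver consumes.  Preparing once and reusing the result across many
#' [rod_step()] calls avoids per-step rebuild overhead; [rod_step()] calls
#' this automatically when handed raw `tri_mesh` lists.
#'
#' @param meshes List of `tri_mesh` objects (or `NULL`).
#' @return A prepared list (marked with attribute `"prepared"`).
#' @export
prepare_collision <- function(meshes) {
  if (!is.null(attr(meshes, "prepared"))) return(meshes)
  out <- lapply(meshes %||% list(), function(m) {
    if (is.null(m$bvh)) m$bvh <- build_bvh(m)
    list(vertices = m$vertices, faces = m$faces, bvh = unclass(m$bvh))
  })
  attr(out, "prepared") <- TRUE
  out
}

#' Base reaction of the last step
#'
#' Axial force and torque transmitted through the prescribed (driven) base
#' points during the last [rod_step()]: the haptic feedback channel.
#'
#' @param state A `rod_state` returned by [rod_step()].
#' @return A list with `axial_force` (N), `axial_torque` (N m) and the full
#'   `force` 3-vector.
#' @export
reaction_at_base <- function(state) {
  d <- attr(state, "diagnostics")
  if (is.null(d)) {
    return(list(axial_force = 0, axial_torque = 0, force = c(0, 0, 0)))
  }
  list(axial_force = d$axial_force, axial_torque = d$axial_torque,
       force = as.numeric(d$reaction_force))
}

#' Run many hybrid steps
#'
#' Convenience loop around [rod_step()] with fixed boundary conditions.
#'
#' @inheritParams rod_step
#' @param n_steps Number of steps.
#' @param record_every Record diagnostics every k-th step (0 = never).
#' @return The final `rod_state`; recorded diagnostics (list) attached as
#'   attribute `"history"`.
#' @export
rod_simulate <- function(state, params, config, n_steps, collision = NULL,
                         prescribed_points = NULL, prescribed_frames = NULL,
                         variant = "constrained", feed_axis = c(1, 0, 0),
                         record_every = 0) {
  history <- list()
  for (s in seq_len(n_steps)) {
    state <- rod_step(state, params, config, collision = collision,
                      prescribed_points = prescribed_points,
                      prescribed_frames = prescribed_frames,
                      variant = variant, feed_axis = feed_axis)
    if (record_every > 0 && s %% record_every == 0) {
      history[[length(history) + 1]] <- attr(state, "diagnostics")
    }
  }
  attr(state, "history") <- history
  state
}
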