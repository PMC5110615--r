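# shared builders and independent oracles

rand_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# small perturbed rod used by gradient checks
perturbed_rod <- function(n = 10, sd_pos = 1e-3, sd_q = 0.05) {
  p <- rod_parameters(n_points = n, rest_length = 0.01, radius = 0.002,
                      point_mass = 1e-3, young_modulus = 1e6,
                      shear_modulus = 5e5, parallelism_stiffness = 10)
  st <- straight_rod_state(p)
  st$positions <- st$positions + matrix(stats::rnorm(3 * n, sd = sd_pos),
                                        n, 3)
  st$frames <- t(apply(st$frames, 1, function(q) {
    quat_normalize(q + stats::rnorm(4, sd = sd_q))
  }))
  list(params = p, state = rod_state(st$positions, st$frames))
}

total_energy <- function(state, params) {
  bend_twist_energy(state, params) + parallelism_energy(state, params)
}

# central finite differences of the total elastic energy
fd_forces <- function(state, params, h = 1e-7) {
  n <- nrow(state$positions)
  Fn <- matrix(0, n, 3)
  for (i in seq_len(n)) for (d in 1:3) {
    sp <- state; sm <- state
    sp$positions[i, d] <- sp$positions[i, d] + h
    sm$positions[i, d] <- sm$positions[i, d] - h
    Fn[i, d] <- -(total_energy(sp, params) - total_energy(sm, params)) /
      (2 * h)
  }
  Fn
}

fd_torques <- function(state, params, h = 1e-7) {
  n <- nrow(state$positions)
  Tn <- matrix(0, n - 1, 3)
  for (j in seq_len(n - 1)) for (d in 1:3) {
    ax <- c(0, 0, 0); ax[d] <- 1
    sp <- state; sm <- state
    sp$frames[j, ] <- quat_multiply(state$frames[j, ], quat_axis_angle(ax, h))
    sm$frames[j, ] <- quat_multiply(state$frames[j, ], quat_axis_angle(ax, -h))
    Tn[j, d] <- -(total_energy(sp, params) - total_energy(sm, params)) /
      (2 * h)
  }
  Tn
}

# deterministic random triangle soup (not necessarily closed)
random_mesh <- function(n_faces, scale = 1) {
  centers <- matrix(stats::runif(3 * n_faces, -scale, scale), n_faces, 3)
  verts <- matrix(0, 3 * n_faces, 3)
  for (f in seq_len(n_faces)) {
    tri <- centers[rep(f, 3), ] +
      matrix(stats::runif(9, -0.1 * scale, 0.1 * scale), 3, 3)
    verts[(3 * f - 2):(3 * f), ] <- tri
  }
  tri_mesh(verts, matrix(seq_len(3 * n_faces), ncol = 3, byrow = TRUE))
}

# brute-force distance from a point to every face of a mesh
brute_force_face_distances <- function(mesh, p) {
  vapply(seq_len(nrow(mesh$faces)), function(f) {
    closest_point_triangle(p, mesh$vertices[mesh$faces[f, 1], ],
                           mesh$vertices[mesh$faces[f, 2], ],
                           mesh$vertices[mesh$faces[f, 3], ])$distance
  }, numeric(1))
}

# settle a rod with fixed boundary conditions until quiescent
settle_rod <- function(state, params, config, prescribed_points = NULL,
                       prescribed_frames = NULL, collision = NULL,
                       max_steps = 2e5, check_every = 5000, vtol = 1e-6) {
  for (k in seq_len(ceiling(max_steps / check_every))) {
    for (s in seq_len(check_every)) {
      state <- rod_step(state, params, config, collision = collision,
                        prescribed_points = prescribed_points,
                        prescribed_frames = prescribed_frames)
    }
    if (max(abs(state$velocities)) < vtol) break
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
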