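# Hybrid constraint solver: banded global solve, local contact projection,
# time stepping.

test_that("distance system assembly matches hand-built J W J^T", {
  # straight rod, uniform mass, at rest length
  n <- 5; m <- 1e-3; l <- 0.01
  pos <- cbind((0:(n - 1)) * l, 0, 0)
  sys <- assemble_distance_system(pos, rep(1 / m, n), rep(l, n - 1))
  expect_equal(sys$residual, rep(0, n - 1), tolerance = 1e-15)
  expect_equal(sys$diagonal, rep(2 / m, n - 1))
  expect_equal(sys$upper, rep(-1 / m, n - 2))
  expect_equal(sys$lower, rep(-1 / m, n - 2))

  # first point fixed: A_11 = 1/m
  sys2 <- assemble_distance_system(pos, c(0, rep(1 / m, n - 1)),
                                   rep(l, n - 1))
  expect_equal(sys2$diagonal[1], 1 / m)

  # 90 degree elbow: orthogonal tangents decouple the two constraints
  pos3 <- rbind(c(0, 0, 0), c(l, 0, 0), c(l, l, 0))
  sys3 <- assemble_distance_system(pos3, rep(1 / m, 3), rep(l, 2))
  expect_equal(sys3$upper[1], 0)

  expect_error(assemble_distance_system(rbind(c(0, 0, 0), c(0, 0, 0)),
                                        c(1, 1), 0.01), "degenerate")
})

test_that("banded solve with partial pivoting matches a dense solver", {
  A1 <- list(diagonal = rep(1, 4), lower = rep(0, 3), upper = rep(0, 3))
  b1 <- c(4, 3, 2, 1)
  expect_equal(solve_banded_pp(A1, b1), b1)

  set.seed(31)
  for (k in 1:100) {
    m <- 100
    A <- list(diagonal = stats::runif(m, 2, 3),
              lower = stats::runif(m - 1, -1, 1),
              upper = stats::runif(m - 1, -1, 1))
    b <- stats::rnorm(m)
    Ad <- diag(A$diagonal)
    Ad[cbind(2:m, 1:(m - 1))] <- A$lower
    Ad[cbind(1:(m - 1), 2:m)] <- A$upper
    expect_lt(max(abs(solve_banded_pp(A, b) - solve(Ad, b))), 1e-10)
  }

  # zero leading diagonal but nonsingular: partial pivoting required
  A0 <- list(diagonal = c(0, 1, 1), lower = c(1, 0.5), upper = c(1, -0.5))
  b0 <- c(1, 2, 3)
  Ad0 <- rbind(c(0, 1, 0), c(1, 1, -0.5), c(0, 0.5, 1))
  expect_lt(max(abs(solve_banded_pp(A0, b0) - solve(Ad0, b0))), 1e-12)

  expect_error(solve_banded_pp(list(diagonal = 0, lower = numeric(0),
                                    upper = numeric(0)), 1), "singular")
})

test_that("distance correction moves points by -W J^T lambda", {
  n <- 3; m <- 1e-3; l <- 0.01
  pos <- cbind(c(0, l * 1.1, 2.1 * l), 0, 0)
  w <- rep(1 / m, n)
  sys <- assemble_distance_system(pos, w, rep(l, 2))

  same <- apply_distance_correction(pos, w, c(0, 0), sys$tangents)
  expect_equal(same, pos)

  # single stretched element with equal masses corrects symmetrically
  pos1 <- cbind(c(0, 1.2 * l), 0, 0)
  s1 <- assemble_distance_system(pos1, c(1 / m, 1 / m), l)
  lam <- solve_banded_pp(s1)
  out <- apply_distance_correction(pos1, c(1 / m, 1 / m), lam, s1$tangents)
  d0 <- out[1, 1] - pos1[1, 1]
  d1 <- out[2, 1] - pos1[2, 1]
  expect_equal(d0, -d1, tolerance = 1e-15)
  expect_equal(out[2, 1] - out[1, 1], l, tolerance = 1e-12)

  # fixed endpoint: only the free point moves
  s2 <- assemble_distance_system(pos1, c(0, 1 / m), l)
  lam2 <- solve_banded_pp(s2)
  out2 <- apply_distance_correction(pos1, c(0, 1 / m), lam2, s2$tangents)
  expect_equal(out2[1, ], pos1[1, ])
  expect_equal(out2[2, 1] - out2[1, 1], l, tolerance = 1e-12)
})

test_that("contact projection enforces non-penetration and the friction cone", {
  pos <- rbind(c(0, 0, -0.001), c(1, 0, 0))
  prev <- rbind(c(0.004, 0, -0.001), c(1, 0, 0))

  none <- project_contacts(pos, prev, NULL)
  expect_equal(none$positions, pos)

  # frictionless: move exactly depth along the normal, tangent preserved
  con <- contact_constraints(1L, c(0, 0, 1), 0.001, mu = 0)
  out <- project_contacts(pos, prev, con)
  expect_equal(out$positions[1, ], c(0, 0, 0), tolerance = 1e-15)
  expect_equal(out$normal_corr, 0.001)
  expect_equal(out$tangential_corr, 0)

  # strong friction: tangential drift fully cancelled (stick regime)
  con2 <- contact_constraints(1L, c(0, 0, 1), 0.001, mu = 10)
  out2 <- project_contacts(pos, prev, con2)
  expect_equal(out2$positions[1, ], c(0.004, 0, 0), tolerance = 1e-12)
  expect_lte(out2$tangential_corr, 10 * out2$normal_corr + 1e-15)

  # sliding: clamped to the cone boundary
  con3 <- contact_constraints(1L, c(0, 0, 1), 0.001, mu = 0.5)
  out3 <- project_contacts(pos, prev, con3)
  expect_equal(out3$tangential_corr, 0.5 * 0.001, tolerance = 1e-15)
})

test_that("a rest state with no gravity is a fixed point of the step", {
  p <- rod_parameters(n_points = 10, rest_length = 0.01, radius = 0.002,
                      point_mass = 1e-3, young_modulus = 1e6,
                      shear_modulus = 5e5, parallelism_stiffness = 10)
  cfg <- solver_config(dt = 1e-3, gravity = c(0, 0, 0))
  st <- straight_rod_state(p)
  st2 <- rod_step(st, p, cfg)
  expect_equal(st2$positions, st$positions, tolerance = 1e-14)
  expect_equal(max(abs(st2$velocities)), 0, tolerance = 1e-14)
})

test_that("free fall follows the ballistic law with inextensible elements", {
  p <- rod_parameters(n_points = 10, rest_length = 0.01, radius = 0.002,
                      point_mass = 1e-3, young_modulus = 1e6,
                      shear_modulus = 5e5, parallelism_stiffness = 10)
  cfg <- solver_config(dt = 1e-3, gravity = c(0, 0, -9.81))
  st <- straight_rod_state(p)
  c0 <- colMeans(st$positions)
  n_steps <- 1000
  max_elong <- 0
  for (k in seq_len(n_steps)) {
    st <- rod_step(st, p, cfg)
    max_elong <- max(max_elong, attr(st, "diagnostics")$max_rel_elongation)
  }
  t <- n_steps * cfg$dt
  dz <- colMeans(st$positions)[3] - c0[3]
  expect_equal(dz, -0.5 * 9.81 * t^2, tolerance = 0.01)
  # contact-free: every element stays at its rest length all along
  expect_lt(max_elong, 1e-6)
})

test_that("step diagnostics report the base reaction of a hanging rod", {
  # rod hanging from its two most distal-index... proximal points, at rest
  p <- rod_parameters(n_points = 30, rest_length = 0.01, radius = 0.002,
                      point_mass = 2e-3, young_modulus = 1e6,
                      shear_modulus = 5e5, parallelism_stiffness = 5,
                      linear_damping = 20, angular_damping = 20)
  cfg <- solver_config(dt = 5e-4, gravity = c(0, 0, -9.81))
  down <- c(0, 0, -1)
  st <- straight_rod_state(p, origin = c(0, 0, 0), axis = down)
  presc <- list(index = c(1L, 2L), positions = st$positions[1:2, ])
  st <- settle_rod(st, p, cfg, prescribed_points = presc, max_steps = 4e4,
                   vtol = 1e-5)
  # re-step once to read the reaction; feed axis points downward
  st <- rod_step(st, p, cfg, prescribed_points = presc, feed_axis = down)
  W <- p$n_points * p$point_mass * 9.81
  expect_equal(reaction_at_base(st)$axial_force, W, tolerance = 0.02)

  # free rod with no gravity and no contacts transmits nothing
  cfg0 <- solver_config(dt = 5e-4, gravity = c(0, 0, 0))
  stf <- straight_rod_state(p)
  stf <- rod_step(stf, p, cfg0)
  expect_equal(reaction_at_base(stf)$axial_force, 0)
})

test_that("identical inputs give bit-identical trajectories", {
  p <- rod_parameters(n_points = 12, rest_length = 0.01, radius = 0.002,
                      point_mass = 1e-3, young_modulus = 1e6,
                      shear_modulus = 5e5, parallelism_stiffness = 10)
  cfg <- solver_config(dt = 1e-3)
  run <- function() {
    st <- straight_rod_state(p)
    presc <- list(index = c(1L, 2L), positions = st$positions[1:2, ])
    for (k in 1:200) st <- rod_step(st, p, cfg, prescribed_points = presc)
    st
  }
  s1 <- run(); s2 <- run()
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$frames, s2$frames)
})

test_that("rod draped over a frictionless cylinder reaches a near-rest-length steady state", {
  # horizontal cylinder along y at the origin; rod laid across it along x
  p <- rod_parameters(n_points = 31, rest_length = 0.01, radius = 0.002,
                      point_mass = 2e-3, young_modulus = 5e5,
                      shear_modulus = 2.5e5, parallelism_stiffness = 3,
                      linear_damping = 30, angular_damping = 30)
  cfg <- solver_config(dt = 2e-4, n_iterations = 3,
                       gravity = c(0, 0, -9.81), friction_mu = 0)
  line <- cbind(0, seq(-0.05, 0.05, length.out = 9), 0)
  sw <- flexscope:::sweep_tube(line, 0.02, 16)
  cyl <- tri_mesh(sw$vertices, sw$faces, name = "cylinder")
  st <- straight_rod_state(p, origin = c(-0.15, 0, 0.0222),
                           axis = c(1, 0, 0))
  collision <- prepare_collision(list(cyl))
  for (k in 1:15000) st <- rod_step(st, p, cfg, collision = collision)
  d <- attr(st, "diagnostics")
  expect_gt(d$n_points_in_contact, 0)
  expect_lt(d$max_rel_elongation, 1e-4)
})

test_that("quaternion norms stay unit through long dynamic runs", {
  p <- rod_parameters(n_points = 20, rest_length = 0.01, radius = 0.002,
                      point_mass = 1e-3, young_modulus = 1e6,
                      shear_modulus = 5e5, parallelism_stiffness = 10)
  cfg <- solver_config(dt = 1e-3)
  st <- straight_rod_state(p)
  presc <- list(index = c(1L, 2L), positions = st$positions[1:2, ])
  for (k in 1:500) {
    st <- rod_step(st, p, cfg, prescribed_points = presc)
    expect_lt(max(abs(sqrt(rowSums(st$frames^2)) - 1)), 1e-9)
  }
})

test_that("pushing the tip against a wall raises the axial reaction monotonically", {
  p <- rod_parameters(n_points = 30, rest_length = 0.01, radius = 0.002,
                      point_mass = 2e-3, young_modulus = 1e9,
                      shear_modulus = 5e8, parallelism_stiffness = 30,
                      linear_damping = 50, angular_damping = 50)
  cfg <- solver_config(dt = 2e-4, gravity = c(0, 0, 0), friction_mu = 0)
  # rigid wall normal to the feed axis at x = 0.2 (two triangles)
  wall <- tri_mesh(rbind(c(0.2, -1, -1), c(0.2, 1, -1), c(0.2, 1, 1),
                         c(0.2, -1, 1)),
                   rbind(c(1, 2, 3), c(1, 3, 4)), name = "wall")
  collision <- prepare_collision(list(wall))
  port <- list(position = c(0, 0, 0), axis = c(1, 0, 0))
  st <- straight_rod_state(p, origin = c(-(p$n_points - 1) * 0.01, 0, 0))
  st$active_count <- 2L
  forces <- c()
  for (ins in c(0.05, 0.18, 0.2005, 0.202, 0.204)) {
    drive <- apply_base_drive(st, list(insertion = ins, roll = 0), port, p)
    st <- drive$state
    for (k in 1:3000) {
      st <- rod_step(st, p, cfg, collision = collision,
                     prescribed_points = drive$prescribed_points,
                     prescribed_frames = drive$prescribed_frames,
                     feed_axis = port$axis, port = port$position)
    }
    forces <- c(forces, abs(reaction_at_base(st)$axial_force))
  }
  # free advance transmits nothing; past contact (insertion > 0.198) the
  # settled reaction grows monotonically with commanded insertion
  expect_lt(forces[1], 1e-6)
  expect_lt(forces[2], 1e-6)
  expect_gt(forces[3], 0.1)
  expect_gt(forces[4], forces[3])
  expect_gt(forces[5], forces[4])
})
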