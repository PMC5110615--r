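# Geometric and elastic core of the discrete Cosserat rod.

test_that("quaternion rotation matrices are proper and match known cases", {
  expect_equal(rotation_from_quaternion(c(1, 0, 0, 0)), diag(3))

  # 90 degrees about axis 3 maps d1 onto e2
  q <- c(cos(pi / 4), 0, 0, sin(pi / 4))
  R <- rotation_from_quaternion(q)
  expect_equal(as.numeric(R[, 1]), c(0, 1, 0), tolerance = 1e-12)

  set.seed(11)
  for (k in 1:100) {
    R <- rotation_from_quaternion(rand_unit_quat())
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
    expect_gt(det(R), 0)
  }

  expect_error(rotation_from_quaternion(c(1, 1, 0, 0)), "invalid state")
})

test_that("darboux strain measures bend/twist between frames", {
  set.seed(12)
  q <- rand_unit_quat()
  expect_equal(darboux(q, q, 0.01), c(0, 0, 0))

  # small twist about d3: |Omega| = 2 sin(phi/2) / span, along component 3
  phi <- 0.01
  qb <- quat_multiply(q, quat_axis_angle(c(0, 0, 1), phi))
  om <- darboux(q, qb, 1e-3)
  expect_equal(om[3], 2 * sin(phi / 2) / 1e-3, tolerance = 1e-3)
  expect_lt(max(abs(om[1:2])), 1e-9)

  # conjugation antisymmetry: swapping the frames negates the strain
  qa <- rand_unit_quat(); qb <- rand_unit_quat()
  expect_equal(darboux(qa, qb, 0.02), -darboux(qb, qa, 0.02),
               tolerance = 1e-12)
})

test_that("bend/twist energy matches analytic uniform-twist and arc forms", {
  p <- rod_parameters(n_points = 101, rest_length = 0.01, radius = 0.003,
                      point_mass = 1e-3, young_modulus = 1e7,
                      shear_modulus = 5e6, parallelism_stiffness = 10)
  st <- straight_rod_state(p, axis = c(1, 0, 0))
  expect_equal(bend_twist_energy(st, p), 0)

  # uniform end-to-end twist phi on a straight rod: V = GJ phi^2 / (2 L)
  phi <- 0.8
  nj <- p$n_points - 1
  st_tw <- st
  for (j in seq_len(nj)) {
    st_tw$frames[j, ] <- quat_multiply(
      st$frames[j, ], quat_axis_angle(c(0, 0, 1), phi * (j - 1) / (nj - 1)))
  }
  L <- (p$n_points - 2) * p$rest_length # twist lives on the junction spans
  expect_equal(bend_twist_energy(st_tw, p), 0.5 * p$GJ * phi^2 / L,
               tolerance = 0.01)

  # planar circular arc of curvature kappa: V = E I kappa^2 L / 2
  kappa <- 2
  Rarc <- 1 / kappa
  s <- (seq_len(p$n_points) - 1) * p$rest_length
  th <- s * kappa
  pos <- cbind(Rarc * sin(th), 0, Rarc * (1 - cos(th)))
  st_arc <- st
  st_arc$positions <- pos
  for (j in seq_len(nj)) {
    # frame rotates about -y (the d2 direction for an x-aligned rod)
    thj <- kappa * (s[j] + s[j + 1]) / 2
    st_arc$frames[j, ] <- quat_multiply(quat_axis_angle(c(0, -1, 0), thj),
                                        st$frames[j, ])
  }
  Larc <- (p$n_points - 2) * p$rest_length
  expect_equal(bend_twist_energy(st_arc, p),
               0.5 * p$young_modulus * p$I1 * kappa^2 * Larc,
               tolerance = 0.01)
})

test_that("parallelism energy penalizes frame-tangent misalignment", {
  p <- rod_parameters(n_points = 3, rest_length = 0.01, radius = 0.002,
                      point_mass = 1e-3, young_modulus = 1e6,
                      shear_modulus = 5e5, parallelism_stiffness = 7)
  st <- straight_rod_state(p, axis = c(0, 0, 1))
  expect_equal(parallelism_energy(st, p), 0, tolerance = 1e-20)

  # d3 perpendicular to the tangent: |d3 - t|^2 = 2 per element
  st_perp <- st
  q_perp <- quat_from_to(c(0, 0, 1), c(1, 0, 0))
  st_perp$frames <- rbind(q_perp, q_perp)
  expect_equal(parallelism_energy(st_perp, p),
               2 * 0.5 * 7 * 2 * 0.01, tolerance = 1e-10)

  # antiparallel: |d3 - t|^2 = 4
  st_anti <- st
  q_anti <- quat_axis_angle(c(1, 0, 0), pi)
  st_anti$frames <- rbind(q_anti, q_anti)
  expect_equal(parallelism_energy(st_anti, p),
               2 * 0.5 * 7 * 4 * 0.01, tolerance = 1e-10)
})

test_that("elastic forces are the exact negative energy gradient", {
  set.seed(21)
  rod <- perturbed_rod()
  f <- elastic_forces(rod$state, rod$params)

  Fn <- fd_forces(rod$state, rod$params)
  expect_lt(max(abs(Fn - f$forces)) / max(abs(f$forces)), 1e-5)

  Tn <- fd_torques(rod$state, rod$params)
  expect_lt(max(abs(Tn - f$torques)) / max(abs(f$torques)), 1e-5)

  # rest configuration: no forces, no torques
  st0 <- straight_rod_state(rod$params)
  f0 <- elastic_forces(st0, rod$params)
  expect_equal(max(abs(f0$forces)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f0$torques)), 0, tolerance = 1e-12)
})

test_that("internal forces and torques balance for random states", {
  set.seed(22)
  for (k in 1:50) {
    rod <- perturbed_rod(n = 8)
    f <- elastic_forces(rod$state, rod$params)
    expect_lt(max(abs(colSums(f$forces))), 1e-10)
    # total torque about the origin (frame torques in world + force moments)
    tw <- matrix(0, 1, 3)
    for (j in seq_len(7)) {
      Rj <- rotation_from_quaternion(rod$state$frames[j, ])
      tw <- tw + t(Rj %*% f$torques[j, ])
    }
    for (i in seq_len(8)) {
      r <- rod$state$positions[i, ]; Fi <- f$forces[i, ]
      tw <- tw + c(r[2] * Fi[3] - r[3] * Fi[2],
                   r[3] * Fi[1] - r[1] * Fi[3],
                   r[1] * Fi[2] - r[2] * Fi[1])
    }
    scale <- max(abs(f$torques), abs(f$forces))
    expect_lt(max(abs(tw)) / scale, 1e-8)
  }
})

test_that("energies and forces are frame indifferent", {
  set.seed(23)
  rod <- perturbed_rod()
  V0 <- total_energy(rod$state, rod$params)
  f0 <- elastic_forces(rod$state, rod$params)

  qrot <- rand_unit_quat()
  Rm <- rotation_from_quaternion(qrot)
  st <- rod$state
  st$positions <- rod$state$positions %*% t(Rm)
  st$frames <- t(apply(rod$state$frames, 1, function(q) {
    quat_normalize(quat_multiply(qrot, q))
  }))
  st <- rod_state(st$positions, st$frames)
  expect_equal(total_energy(st, rod$params), V0, tolerance = 1e-9)
  f1 <- elastic_forces(st, rod$params)
  expect_equal(f1$forces, f0$forces %*% t(Rm), tolerance = 1e-7)
})

test_that("stretch penalty forces follow the linear law", {
  p <- rod_parameters(n_points = 3, rest_length = 0.1, radius = 0.002,
                      point_mass = 1e-3, young_modulus = 1e6,
                      shear_modulus = 5e5,
                      stretch_modulus = 100 / (pi * 0.002^2),
                      parallelism_stiffness = 1)
  st <- straight_rod_state(p, axis = c(1, 0, 0))
  expect_equal(max(abs(stretch_penalty_forces(st, p))), 0)

  # one element at strain 0.01 with Es A = 100 N -> 1 N pull on each end
  st$positions[3, 1] <- st$positions[3, 1] + 0.001
  f <- stretch_penalty_forces(st, p)
  expect_equal(f[2, 1], 1, tolerance = 1e-9)
  expect_equal(f[3, 1], -1, tolerance = 1e-9)

  # compressed element pushes its endpoints apart
  st2 <- straight_rod_state(p, axis = c(1, 0, 0))
  st2$positions[3, 1] <- st2$positions[3, 1] - 0.001
  f2 <- stretch_penalty_forces(st2, p)
  expect_lt(f2[2, 1], 0)
  expect_gt(f2[3, 1], 0)

  p_na <- rod_parameters(n_points = 3, rest_length = 0.1, radius = 0.002,
                         point_mass = 1e-3, young_modulus = 1e6,
                         shear_modulus = 5e5)
  expect_error(stretch_penalty_forces(st, p_na), "stretch_modulus")
})

test_that("rod state invariants are validated", {
  p <- rod_parameters(n_points = 4, rest_length = 0.01, radius = 0.002,
                      point_mass = 1e-3, young_modulus = 1e6,
                      shear_modulus = 5e5)
  st <- straight_rod_state(p)
  expect_silent(validate_rod_state(st))
  st_bad <- st
  st_bad$frames[1, ] <- c(1, 1, 0, 0)
  expect_error(rod_state(st_bad$positions, st_bad$frames), "invalid state")
  expect_error(rod_parameters(n_points = 2, rest_length = 0.01,
                              radius = 0.002, point_mass = 1e-3,
                              young_modulus = 1e6, shear_modulus = 5e5))
})
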