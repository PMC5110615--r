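# Scene layer: base drive, tip steering, actuators, markers, task logic.

scene_rod <- function(n = 40, l = 0.01) {
  rod_parameters(n_points = n, rest_length = l, radius = 0.003,
                 point_mass = 1e-3, young_modulus = 1e7,
                 shear_modulus = 5e6, parallelism_stiffness = 20,
                 linear_damping = 20, angular_damping = 30)
}

test_that("base drive activates one point per element of insertion", {
  p <- scene_rod()
  port <- list(position = c(0, 0, 0), axis = c(1, 0, 0))
  st <- straight_rod_state(p, origin = c(-(p$n_points - 1) * p$rest_length,
                                         0, 0))
  st$active_count <- 2L
  d1 <- apply_base_drive(st, list(insertion = 0.05, roll = 0), port, p)
  ac1 <- d1$state$active_count
  d2 <- apply_base_drive(d1$state,
                         list(insertion = 0.05 + p$rest_length, roll = 0),
                         port, p)
  expect_equal(d2$state$active_count, ac1 + 1L)

  # prescribed points sit on the feed line at the commanded arclength
  pp <- d2$prescribed_points
  expect_equal(length(pp$index), 2)
  expect_equal(pp$positions[, 2], c(0, 0))
  expect_equal(diff(pp$positions[, 1]), p$rest_length)

  # zero commanded motion leaves the prescription unchanged
  d3 <- apply_base_drive(d2$state,
                         list(insertion = 0.05 + p$rest_length, roll = 0),
                         port, p)
  expect_equal(d3$prescribed_points$positions, pp$positions)
})

test_that("roll is transmitted to the distal frame through a straight rod", {
  p <- scene_rod(n = 30)
  cfg <- solver_config(dt = 5e-4, gravity = c(0, 0, 0))
  port <- list(position = c(0, 0, 0), axis = c(1, 0, 0))
  st <- straight_rod_state(p, origin = c(-(p$n_points - 1) * p$rest_length,
                                         0, 0))
  st$active_count <- 2L
  roll <- pi / 2
  drive <- apply_base_drive(st, list(insertion = 0.15, roll = roll), port, p)
  st <- drive$state
  st <- settle_rod(st, p, cfg, prescribed_points = drive$prescribed_points,
                   prescribed_frames = drive$prescribed_frames,
                   max_steps = 4e4, vtol = 1e-6)
  # distal frame d1 has rolled by the commanded angle about the feed axis
  Rtip <- rotation_from_quaternion(st$frames[p$n_points - 1, ])
  d1 <- Rtip[, 1]
  base_d1 <- rotation_from_quaternion(
    quat_multiply(quat_from_to(c(0, 0, 1), c(1, 0, 0)),
                  quat_axis_angle(c(0, 0, 1), roll)))[, 1]
  expect_lt(acos(min(1, sum(d1 * base_d1))), 1e-2)
})

test_that("tip steering settles to the commanded intrinsic curvature", {
  p <- scene_rod(n = 40)
  m_tip <- 10
  kappa_max <- 15
  cfg <- solver_config(dt = 5e-4, gravity = c(0, 0, 0))

  steer_and_settle <- function(wu, wl) {
    pp <- apply_tip_actuation(p, list(wheel_ud = wu, wheel_lr = wl),
                              m_tip = m_tip, kappa_max = kappa_max)
    st <- straight_rod_state(pp)
    presc <- list(index = c(1L, 2L), positions = st$positions[1:2, ])
    prescf <- list(index = 1L, quaternions = rbind(st$frames[1, ]))
    settle_rod(st, pp, cfg, prescribed_points = presc,
               prescribed_frames = prescf, max_steps = 6e4, vtol = 1e-6)
  }

  # wheels at zero: rod relaxes straight
  st0 <- steer_and_settle(0, 0)
  tip_dir <- st0$positions[40, ] - st0$positions[39, ]
  expect_lt(acos(min(1, sum(tip_dir * c(1, 0, 0)) / sqrt(sum(tip_dir^2)))),
            1e-3)

  # full up-down wheel: tip arc angle = m_tip * l * kappa_max
  st1 <- steer_and_settle(1, 0)
  q_before <- st1$frames[40 - 1 - m_tip, ]
  q_tip <- st1$frames[39, ]
  dq <- quat_multiply(quat_conjugate(q_before), q_tip)
  angle <- 2 * atan2(sqrt(sum(dq[2:4]^2)), abs(dq[1]))
  expect_equal(angle, m_tip * p$rest_length * kappa_max, tolerance = 0.02)

  # both wheels: curvature magnitude sqrt(2) * kappa_max
  st2 <- steer_and_settle(1, 1)
  q_before2 <- st2$frames[40 - 1 - m_tip, ]
  dq2 <- quat_multiply(quat_conjugate(q_before2), st2$frames[39, ])
  angle2 <- 2 * atan2(sqrt(sum(dq2[2:4]^2)), abs(dq2[1]))
  expect_equal(angle2, sqrt(2) * m_tip * p$rest_length * kappa_max,
               tolerance = 0.02)
})

test_that("actuator pose protrudes along the tip director", {
  p <- scene_rod(n = 10)
  st <- straight_rod_state(p, axis = c(0, 0, 1))
  pose0 <- actuator_tip_pose(st, 0)
  expect_equal(pose0$position, st$positions[10, ])

  pose <- actuator_tip_pose(st, 0.02)
  expect_equal(pose$position, st$positions[10, ] + c(0, 0, 0.02))
  expect_equal(pose$axis, c(0, 0, 1), tolerance = 1e-12)

  # curved tip: axis equals the tip frame's d3 exactly
  st$frames[9, ] <- quat_axis_angle(c(0, 1, 0), 0.7)
  pose2 <- actuator_tip_pose(st, 0.01)
  d3 <- rotation_from_quaternion(st$frames[9, ])[, 3]
  expect_equal(pose2$axis, as.numeric(d3))
})

test_that("clip events record distance and jaw-vessel angle", {
  p <- scene_rod(n = 10)
  st <- straight_rod_state(p, axis = c(1, 0, 0))  # d3 = +x
  tip <- st$positions[10, ]
  vessel <- soft_body(cbind(tip[1] + 0.01, seq(-0.03, 0.03, length.out = 8),
                            tip[3]),
                      tetrahedra = NULL, springs = cbind(1:7, 2:8),
                      node_mass = 1e-3, name = "vessel")
  markers <- list(scene_marker("clip_point", vessel$positions[4, ],
                               id = "m1"),
                  scene_marker("clip_point", vessel$positions[6, ],
                               id = "m2"))
  ctl <- scope_controls(tool = "clipper", protrusion = 0.01, jaws = TRUE)
  rec <- clip_event(st, ctl, vessel, markers)
  expect_true(rec$ok)
  # jaw axis +x vs vessel tangent +y: ideal right angle
  expect_equal(rec$angle_to_vessel, 90, tolerance = 1e-9)
  # tool tip coincides with the vessel y=~0 region; nearest marker is node 4
  expect_equal(rec$marker_id, "m1")
  expect_equal(rec$distance_to_marker,
               sqrt(sum((vessel$positions[4, ] -
                           (tip + c(0.01, 0, 0)))^2)))

  # tip offset by 5 mm from the marker reports 5 mm
  st2 <- st
  st2$positions[10, ] <- st$positions[10, ] + c(0, 0.005, 0)
  markers1 <- list(scene_marker("clip_point", tip + c(0.01, 0, 0),
                                id = "m"))
  rec2 <- clip_event(st2, ctl, vessel, markers1)
  expect_equal(rec2$distance_to_marker, 0.005, tolerance = 1e-12)

  # jaw axis parallel to the vessel: angle 0
  vessel_x <- soft_body(cbind(tip[1] + seq(0, 0.07, length.out = 8), 0,
                              tip[3]),
                        tetrahedra = NULL, springs = cbind(1:7, 2:8),
                        node_mass = 1e-3, name = "vx")
  rec3 <- clip_event(st, ctl, vessel_x, markers1)
  expect_equal(rec3$angle_to_vessel, 0, tolerance = 1e-9)

  # firing far from any vessel logs a no-op
  far <- soft_body(cbind(5, seq(0, 0.07, length.out = 8), 0),
                   tetrahedra = NULL, springs = cbind(1:7, 2:8),
                   node_mass = 1e-3, name = "far")
  rec4 <- clip_event(st, ctl, far, markers1)
  expect_false(rec4$ok)
})

test_that("ring passage detects disc crossings including the boundary", {
  ring <- scene_marker("viscerotomy_ring", c(0.2, 0, 0), axis = c(1, 0, 0),
                       radius = 0.015)
  expect_true(ring_passage_test(c(0.19, 0, 0), c(0.21, 0, 0), ring))
  # parallel to the ring plane: no crossing
  expect_false(ring_passage_test(c(0.25, -0.1, 0), c(0.25, 0.1, 0), ring))
  # crossing the plane outside the disc
  expect_false(ring_passage_test(c(0.19, 0.1, 0), c(0.21, 0.1, 0), ring))
  # intersection exactly on the rim counts (closed disc)
  expect_true(ring_passage_test(c(0.19, 0.015, 0), c(0.21, 0.015, 0), ring))
})

test_that("task completion logic is ordered and monotone", {
  ts <- new_task_state(c("artery", "duct"))
  expect_false(any(ts$completed))

  # cut before two clips: logged, not fatal, task 2 stays incomplete
  ts <- task_update(ts, list(time = 1,
                             cut = list(vessel = "artery", between = 4.5)))
  expect_false(ts$completed["task2"])
  expect_gt(length(ts$event_log), 0)

  ts <- task_update(ts, list(time = 2, ring_passed = TRUE))
  expect_true(ts$completed["task1"])
  expect_equal(unname(ts$t_completed["task1"]), 2)

  clip <- function(v, node) list(clip = list(vessel = v, node = node,
                                             ok = TRUE))
  ts <- task_update(ts, c(list(time = 3), clip("artery", 3)))
  ts <- task_update(ts, c(list(time = 4), clip("artery", 6)))
  # cut outside the clipped span is rejected
  ts <- task_update(ts, list(time = 5,
                             cut = list(vessel = "artery", between = 6.5)))
  expect_length(ts$cuts$artery, 0)
  ts <- task_update(ts, list(time = 6,
                             cut = list(vessel = "artery", between = 4.5)))
  expect_length(ts$cuts$artery, 1)
  expect_false(ts$completed["task2"])  # duct still pending

  ts <- task_update(ts, c(list(time = 7), clip("duct", 3)))
  ts <- task_update(ts, c(list(time = 8), clip("duct", 5)))
  ts <- task_update(ts, list(time = 9,
                             cut = list(vessel = "duct", between = 4)))
  expect_true(ts$completed["task2"])

  # no diathermy -> task 3 never completes
  ts <- task_update(ts, list(time = 10, segments_alive = 3L,
                             gallbladder_past_ring = TRUE))
  expect_false(ts$completed["task3"])
  ts <- task_update(ts, list(time = 11, segments_alive = 0L,
                             gallbladder_past_ring = TRUE))
  expect_true(ts$completed["task3"])

  # completion never reverts
  ts <- task_update(ts, list(time = 12, segments_alive = 5L))
  expect_true(all(ts$completed))
})
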