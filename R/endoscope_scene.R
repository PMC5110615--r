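## Interactive scene: rod + tissues, base insertion/rotation drive,
## steerable tip, actuators (grasper, clipper, scissors, diathermy),
## markers and task-completion logic for the three procedure tasks.

scope_tools <- c("none", "grasper", "clipper", "scissors", "diathermy")

#' Endoscope control frame
#'
#' One frame of operator input: shaft insertion/roll, the two steering
#' thumb wheels, the selected working-port instrument, its protrusion, the
#' jaw state and the diathermy pedal.
#'
#' @param insertion Insertion depth along the feed axis, m.
#' @param roll Shaft roll about the feed axis, rad.
#' @param wheel_ud,wheel_lr Thumb-wheel deflections in `[-1, 1]`.
#' @param tool One of `"none"`, `"grasper"`, `"clipper"`, `"scissors"`,
#'   `"diathermy"`.
#' @param protrusion Instrument protrusion beyond the tip, m (>= 0).
#' @param jaws Logical: jaws closed?
#' @param pedal Logical: diathermy pedal pressed?
#' @return An object of class `scope_controls`.
#' @export
scope_controls <- function(insertion = 0, roll = 0, wheel_ud = 0,
                           wheel_lr = 0, tool = "none", protrusion = 0,
                           jaws = FALSE, pedal = FALSE) {
  tool <- match.arg(tool, scope_tools)
  stopifnot(abs(wheel_ud) <= 1, abs(wheel_lr) <= 1, protrusion >= 0)
  structure(list(insertion = insertion, roll = roll, wheel_ud = wheel_ud,
                 wheel_lr = wheel_lr, tool = tool, protrusion = protrusion,
                 jaws = isTRUE(jaws), pedal = isTRUE(pedal)),
            class = "scope_controls")
}

#' Scene marker
#'
#' Glowing guidance markers: the viscerotomy ring, vessel clip points and
#' connective-tissue indicators.
#'
#' @param kind `"viscerotomy_ring"`, `"clip_point"` or `"connective"`.
#' @param position Marker position (3-vector), m.
#' @param axis Unit axis (ring normal / vessel direction hint).
#' @param radius Marker radius, m.
#' @param id Optional marker identifier.
#' @return A `scene_marker` list.
#' @export
scene_marker <- function(kind, position, axis = c(0, 0, 1), radius = 0.005,
                         id = NA_character_) {
  kind <- match.arg(kind, c("viscerotomy_ring", "clip_point", "connective"))
  axis <- axis / sqrt(sum(axis^2))
  structure(list(kind = kind, position = as.numeric(position),
                 axis = axis, radius = radius, id = id),
            class = "scene_marker")
}

#' Apply the base (haptic-device) drive to the rod
#'
#' Prescribes the two most proximal active points on the feed line at the
#' arclength set by the commanded insertion depth, with the commanded roll
#' entering as a prescribed rotation of the proximal material frame about
#' the feed axis.  Points not yet inserted are inactive; each whole element
#' of added insertion activates the next point (parked on the feed line
#' behind the port).
#'
#' @param state A `rod_state` (tip = highest point index).
#' @param controls A `scope_controls`.
#' @param port_pose List with `position` (port location) and `axis` (unit
#'   feed direction into the workspace).
#' @param params The rod's `rod_parameters`.
#' @return A list with the updated `state` (activation bookkeeping) and the
#'   `prescribed_points` / `prescribed_frames` lists for [rod_step()].
#' @export
apply_base_drive <- function(state, controls, port_pose, params) {
  n <- params$n_points
  l <- params$rest_length
  d <- min(max(controls$insertion, 0), (n - 1) * l)
  if (controls$insertion > (n - 1) * l) {
    warning("insertion clamped to rod length")
  }
  ac <- floor(d / l + 1e-9) + 2L
  if (ac < 2L) ac <- 2L
  if (ac > n) ac <- n
  if (ac < state$active_count) {
    # retraction: deactivate points (they park back on the feed line)
  }
  axis <- port_pose$axis / sqrt(sum(port_pose$axis^2))
  a0 <- n - ac + 1L
  # newly activated points start parked on the feed line
  if (ac > state$active_count) {
    prev_a0 <- n - state$active_count + 1L
    for (i in a0:(prev_a0 - 1L)) {
      s_i <- d - (n - i) * l
      state$positions[i, ] <- port_pose$position + axis * s_i
      state$velocities[i, ] <- 0
      if (i <= n - 1) {
        state$frames[i, ] <- quat_normalize(quat_multiply(
          quat_from_to(c(0, 0, 1), axis),
          quat_axis_angle(c(0, 0, 1), controls$roll)))
        state$angular_velocities[i, ] <- 0
      }
    }
  }
  state$active_count <- ac
  presc_idx <- c(a0, a0 + 1L)
  s0 <- d - (n - a0) * l
  s1 <- d - (n - a0 - 1L) * l
  presc_pos <- rbind(port_pose$position + axis * s0,
                     port_pose$position + axis * s1)
  base_q <- quat_normalize(quat_multiply(
    quat_from_to(c(0, 0, 1), axis),
    quat_axis_angle(c(0, 0, 1), controls$roll)))
  list(state = state,
       prescribed_points = list(index = presc_idx, positions = presc_pos),
       prescribed_frames = list(index = a0, quaternions = rbind(base_q)))
}

#' Steer the tip by setting intrinsic curvature
#'
#' The two thumb wheels command intrinsic Darboux targets on the last
#' `m_tip` junctions: `Omega0 = (kappa_max * wheel_ud, kappa_max *
#' wheel_lr, 0)` in the material frame, so the unloaded tip settles into a
#' circular arc.
#'
#' @param params A `rod_parameters`.
#' @param controls A `scope_controls`.
#' @param m_tip Number of steerable tip junctions (< n_points - 1).
#' @param kappa_max Curvature at full wheel deflection, 1/m.  The default
#'   gives 210 degrees of total articulation at full deflection, matching a
#'   standard gastroscope bending section.
#' @return `params` with the updated `intrinsic_darboux`.
#' @export
apply_tip_actuation <- function(params, controls, m_tip = 10,
                                kappa_max = NULL) {
  stopifnot(m_tip >= 1, m_tip < params$n_points - 1)
  if (is.null(kappa_max)) {
    kappa_max <- (210 / 180 * pi) / (m_tip * params$rest_length)
  }
  nj <- params$n_points - 2
  om <- params$intrinsic_darboux
  rows <- (nj - m_tip + 1):nj
  om[rows, 1] <- kappa_max * controls$wheel_ud
  om[rows, 2] <- kappa_max * controls$wheel_lr
  om[rows, 3] <- 0
  params$intrinsic_darboux <- om
  params
}

#' Working-port actuator tip pose
#'
#' Instruments protrude from the scope tip as rigid straight extensions
#' along the tip director \eqn{d_3}.
#'
#' @param state A `rod_state`.
#' @param protrusion Protrusion beyond the scope tip, m.
#' @return A list with `position` and `axis` (the tip director d3).
#' @export
actuator_tip_pose <- function(state, protrusion = 0) {
  stopifnot(protrusion >= 0)
  n <- nrow(state$positions)
  q <- state$frames[n - 1, ]
  d3 <- as.numeric(rotation_from_quaternion(quat_normalize(q))[, 3])
  list(position = as.numeric(state$positions[n, ]) + protrusion * d3,
       axis = d3)
}

#' Clip application event
#'
#' Fired when the clipper's jaws close: finds the nearest vessel chain node
#' and clip-point marker, records the distance to the indicated point and
#' the angle between the jaw axis (the tool axis) and the local vessel
#' tangent (90 degrees is ideal), and pins the clipped node to the clip
#' location.  Firing farther than `capture_radius` from the vessel logs a
#' no-op event.
#'
#' @param state A `rod_state`.
#' @param controls A `scope_controls` with `tool = "clipper"`.
#' @param vessel A vessel chain `soft_body`.
#' @param markers List of `scene_marker`s of kind `"clip_point"`.
#' @param capture_radius Maximum jaw-to-vessel distance for a clip to take,
#'   m.
#' @return A `clip_record` list: `time`, `position`, `jaw_axis`,
#'   `marker_id`, `distance_to_marker` (m), `angle_to_vessel` (deg),
#'   `node`, `ok`.
#' @export
clip_event <- function(state, controls, vessel, markers,
                       capture_radius = 0.02) {
  pose <- actuator_tip_pose(state, controls$protrusion)
  pos <- pose$position
  nd <- sqrt(rowSums((vessel$positions -
                        matrix(pos, nrow(vessel$positions), 3,
                               byrow = TRUE))^2))
  node <- which.min(nd)
  ok <- nd[node] <= capture_radius
  mk_d <- vapply(markers, function(m) sqrt(sum((m$position - pos)^2)), 1)
  mi <- which.min(mk_d)
  # local vessel tangent from the chain neighbours
  n_nodes <- nrow(vessel$positions)
  lo <- max(node - 1, 1); hi <- min(node + 1, n_nodes)
  tangent <- vessel$positions[hi, ] - vessel$positions[lo, ]
  tangent <- tangent / sqrt(sum(tangent^2))
  cosang <- abs(sum(pose$axis * tangent))
  angle <- acos(min(max(cosang, 0), 1)) * 180 / pi
  rec <- list(time = state$time, position = pos, jaw_axis = pose$axis,
              marker_id = markers[[mi]]$id,
              distance_to_marker = mk_d[mi],
              angle_to_vessel = angle, node = node, ok = ok)
  class(rec) <- "clip_record"
  rec
}

#' Ring passage test
#'
#' TRUE iff the tip segment from `tip_prev` to `tip_curr` crosses the
#' ring's disc: it crosses the ring plane and the intersection point lies
#' within the ring radius (boundary counts as a pass).
#'
#' @param tip_prev,tip_curr Tip positions before/after the frame.
#' @param ring A `scene_marker` of kind `"viscerotomy_ring"`.
#' @return Logical.
#' @export
ring_passage_test <- function(tip_prev, tip_curr, ring) {
  stopifnot(ring$radius > 0)
  s0 <- sum((tip_prev - ring$position) * ring$axis)
  s1 <- sum((tip_curr - ring$position) * ring$axis)
  if (s0 == 0 && s1 == 0) return(FALSE)          # travelling in the plane
  if (s0 * s1 > 0) return(FALSE)                 # no plane crossing
  if (s0 == s1) return(FALSE)
  tpar <- s0 / (s0 - s1)
  hit <- tip_prev + tpar * (tip_curr - tip_prev)
  sqrt(sum((hit - ring$position)^2)) <= ring$radius + 1e-12
}

#' New task state for the three-task procedure
#'
#' Task 1: navigation through the viscerotomy ring into the abdomen.
#' Task 2: two clips plus a cut between them on each of the cystic artery
#' and duct.  Task 3: all connective segments burnt and the gallbladder
#' grasped back past the ring plane.
#'
#' @param vessel_names Names of the vessels requiring clip-clip-cut.
#' @return A `task_state` list.
#' @export
new_task_state <- function(vessel_names = c("artery", "duct")) {
  structure(list(
    completed = c(task1 = FALSE, task2 = FALSE, task3 = FALSE),
    t_completed = c(task1 = NA_real_, task2 = NA_real_, task3 = NA_real_),
    clips = setNames(vector("list", length(vessel_names)), vessel_names),
    cuts = setNames(vector("list", length(vessel_names)), vessel_names),
    event_log = list()
  ), class = "task_state")
}

#' Update task completion from frame events
#'
#' @param task_state A `task_state`.
#' @param events List with any of: `ring_passed` (flag), `clip` (list with
#'   `vessel`, `node`, `ok`), `cut` (list with `vessel`, `between` chain
#'   positions), `segments_alive` (count), `gallbladder_past_ring` (flag),
#'   `time` (s).
#' @param dt Frame duration, s.
#' @return The updated `task_state`; completion flags never revert.
#' @export
task_update <- function(task_state, events, dt = 0) {
  tnow <- events$time %||% NA_real_
  log_event <- function(ts, what) {
    ts$event_log[[length(ts$event_log) + 1]] <- list(time = tnow, what = what)
    ts
  }
  if (isTRUE(events$ring_passed) && !task_state$completed["task1"]) {
    task_state$completed["task1"] <- TRUE
    task_state$t_completed["task1"] <- tnow
  }
  if (!is.null(events$clip) && isTRUE(events$clip$ok)) {
    v <- events$clip$vessel
    if (v %in% names(task_state$clips)) {
      task_state$clips[[v]] <- c(task_state$clips[[v]], events$clip$node)
    } else {
      task_state <- log_event(task_state, paste0("clip on unknown vessel ", v))
    }
  }
  if (!is.null(events$cut)) {
    v <- events$cut$vessel
    clips <- task_state$clips[[v]]
    if (length(clips) >= 2) {
      rng <- range(clips)
      between <- events$cut$between
      valid <- any(between > rng[1] & between < rng[2])
      if (valid) {
        task_state$cuts[[v]] <- c(task_state$cuts[[v]], list(events$cut))
      } else {
        task_state <- log_event(task_state, paste0("cut outside clips on ", v))
      }
    } else {
      task_state <- log_event(task_state,
                              paste0("cut before two clips on ", v))
    }
  }
  if (!task_state$completed["task2"]) {
    done <- all(vapply(names(task_state$clips), function(v) {
      length(task_state$clips[[v]]) >= 2 && length(task_state$cuts[[v]]) >= 1
    }, logical(1)))
    if (done) {
      task_state$completed["task2"] <- TRUE
      task_state$t_completed["task2"] <- tnow
    }
  }
  if (!task_state$completed["task3"] &&
      identical(events$segments_alive, 0L) &&
      isTRUE(events$gallbladder_past_ring)) {
    task_state$completed["task3"] <- TRUE
    task_state$t_completed["task3"] <- tnow
  }
  task_state
}

#' Run a scripted scenario
#'
#' Drives the scene with a control stream (one `scope_controls` row per
#' frame), advancing the rod with the hybrid solver at the solver `dt`
#' between control frames, stepping the soft bodies, processing tool events
#' at the frame rate, and recording a trajectory.
#'
#' @param scene A scene list from [generate_toy_abdomen()] (rod parameters,
#'   solver config, port pose, meshes, soft bodies, markers, task state).
#' @param controls_frame Data frame of control frames: columns `t_s`,
#'   `insertion_m`, `roll_rad`, `wheel_ud`, `wheel_lr`, `tool`,
#'   `protrusion_m`, `jaws`, `pedal`.
#' @param progress Print progress every k frames (0 = silent).
#' @return A list with `trajectory`, `task_state`, `task_boundaries`,
#'   `metrics` (per-task data frame) and the final `scene`.
#' @export
run_scenario <- function(scene, controls_frame, progress = 0) {
  params <- scene$rod_params
  cfg <- scene$solver
  state <- scene$rod_state
  gall <- scene$gallbladder
  vessels <- scene$vessels
  segments <- scene$segments
  tasks <- scene$task_state %||% new_task_state(names(vessels))
  traj <- new_trajectory()
  grasped_node <- NA_integer_
  prev_jaws <- FALSE
  prev_tip <- actuator_tip_pose(state, 0)$position
  gall_past_ring <- FALSE
  t_sim <- 0
  collision <- prepare_collision(scene$rigid_meshes)

  for (fi in seq_len(nrow(controls_frame))) {
    cf <- controls_frame[fi, ]
    ctl <- scope_controls(insertion = cf$insertion_m, roll = cf$roll_rad,
                          wheel_ud = cf$wheel_ud, wheel_lr = cf$wheel_lr,
                          tool = as.character(cf$tool),
                          protrusion = cf$protrusion_m,
                          jaws = cf$jaws, pedal = cf$pedal)
    dt_frame <- cf$t_s - t_sim
    n_sub <- max(1L, as.integer(round(dt_frame / cfg$dt)))
    params <- apply_tip_actuation(params, ctl, m_tip = scene$m_tip,
                                  kappa_max = scene$kappa_max)
    drive <- apply_base_drive(state, ctl, scene$port, params)
    state <- drive$state
    for (s in seq_len(n_sub)) {
      state <- rod_step(state, params, cfg, collision = collision,
                        prescribed_points = drive$prescribed_points,
                        prescribed_frames = drive$prescribed_frames,
                        feed_axis = scene$port$axis,
                        port = scene$port$position)
      if (!is.null(gall)) gall <- msm_step(gall, cfg$dt, cfg$gravity)
      for (vn in names(vessels)) {
        vessels[[vn]] <- msm_step(vessels[[vn]], cfg$dt, cfg$gravity)
      }
    }
    t_sim <- cf$t_s
    state$time <- t_sim
    diagn <- attr(state, "diagnostics")

    pose <- actuator_tip_pose(state, ctl$protrusion)
    events <- list()
    frame_events <- list(time = t_sim)

    # --- ring passage (scope tip, not the protruded instrument) ----------
    tip_now <- actuator_tip_pose(state, 0)$position
    if (ring_passage_test(prev_tip, tip_now, scene$ring)) {
      frame_events$ring_passed <- TRUE
      events$ring_passed <- TRUE
    }
    prev_tip <- tip_now

    # --- tool events on jaw edges and pedal -------------------------------
    jaw_edge <- ctl$jaws && !prev_jaws
    open_edge <- !ctl$jaws && prev_jaws
    if (jaw_edge && ctl$tool == "clipper") {
      # clip the nearest vessel
      vdist <- vapply(vessels, function(v) {
        min(sqrt(rowSums((v$positions -
                            matrix(pose$position, nrow(v$positions), 3,
                                   byrow = TRUE))^2)))
      }, 1)
      vn <- names(vessels)[which.min(vdist)]
      rec <- clip_event(state, ctl, vessels[[vn]],
                        scene$clip_markers[[vn]])
      rec$vessel <- vn
      if (rec$ok) {
        vessels[[vn]] <- pin_nodes(vessels[[vn]], rec$node, rec$position)
      }
      events$clips <- list(rec[c("time", "distance_to_marker",
                                 "angle_to_vessel", "node", "ok")])
      frame_events$clip <- list(vessel = vn, node = rec$node, ok = rec$ok)
    }
    if (jaw_edge && ctl$tool == "scissors") {
      for (vn in names(vessels)) {
        sv <- sever_springs(vessels[[vn]], pose$position,
                            scene$blade_radius %||% 0.01)
        if (length(sv$severed) > 0) {
          vessels[[vn]] <- sv$body
          between <- (vessels[[vn]]$springs$i[sv$severed] +
                        vessels[[vn]]$springs$j[sv$severed]) / 2
          events$cuts <- c(events$cuts %||% list(),
                           list(list(vessel = vn, severed = sv$severed)))
          frame_events$cut <- list(vessel = vn, between = between)
        }
      }
    }
    if (jaw_edge && ctl$tool == "grasper" && !is.null(gall)) {
      nd <- sqrt(rowSums((gall$positions -
                            matrix(pose$position, nrow(gall$positions), 3,
                                   byrow = TRUE))^2))
      if (min(nd) <= (scene$grasp_radius %||% 0.02)) {
        grasped_node <- which.min(nd)
        gall <- pin_nodes(gall, grasped_node, pose$position)
        # the endoscopic grasp takes over from the assistant's retraction
        if (!is.null(scene$retraction_nodes)) {
          gall <- release_nodes(gall,
                                setdiff(scene$retraction_nodes, grasped_node))
        }
      }
    }
    if (open_edge && !is.na(grasped_node) && !is.null(gall)) {
      gall <- release_nodes(gall, grasped_node)
      grasped_node <- NA_integer_
    }
    if (!is.na(grasped_node) && !is.null(gall)) {
      gall <- pin_nodes(gall, grasped_node, pose$position)
      s_node <- sum((gall$positions[grasped_node, ] - scene$ring$position) *
                      scene$ring$axis)
      if (s_node < 0) gall_past_ring <- TRUE
    }

    # --- diathermy --------------------------------------------------------
    if (!is.null(segments)) {
      # gallbladder-side endpoints follow the body
      upd <- which(!is.na(segments$body_node))
      if (length(upd) > 0 && !is.null(gall)) {
        segments[upd, c("bx", "by", "bz")] <-
          gall$positions[segments$body_node[upd], , drop = FALSE]
      }
      alive_before <- segments$alive
      bu <- burn_update(segments, pose$position,
                        ctl$pedal && ctl$tool == "diathermy", dt_frame)
      segments <- bu$segments
      # a burnt-through attachment releases its gallbladder node
      died <- which(alive_before & !segments$alive)
      if (length(died) > 0 && !is.null(gall)) {
        rel <- segments$body_node[died]
        gall <- release_nodes(gall, rel[!is.na(rel)])
      }
      events$burn_on_dt <- bu$on_target_dt
      events$burn_off_dt <- bu$off_target_dt
      frame_events$segments_alive <- sum(segments$alive)
    }
    frame_events$gallbladder_past_ring <- gall_past_ring
    tasks <- task_update(tasks, frame_events, dt_frame)
    events$tasks_completed <- unname(tasks$completed)

    traj <- record_frame(traj, t_sim, tip_now, ctl$insertion, ctl,
                         reaction = list(
                           axial_force = diagn$axial_force %||% 0,
                           axial_torque = diagn$axial_torque %||% 0),
                         tissue_force = diagn$tissue_force %||% 0,
                         events = events)
    prev_jaws <- ctl$jaws
    if (progress > 0 && fi %% progress == 0) {
      message(sprintf("frame %d/%d t=%.1fs tasks=%s", fi,
                      nrow(controls_frame), t_sim,
                      paste(as.integer(tasks$completed), collapse = "")))
    }
  }

  task_boundaries <- boundaries_from_trajectory(traj)
  metrics <- compute_metrics(traj, task_boundaries)
  scene$rod_state <- state
  scene$rod_params <- params
  scene$gallbladder <- gall
  scene$vessels <- vessels
  scene$segments <- segments
  scene$task_state <- tasks
  list(trajectory = traj, task_state = tasks,
       task_boundaries = task_boundaries, metrics = metrics, scene = scene)
}
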