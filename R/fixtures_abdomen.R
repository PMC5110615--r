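## Seeded toy abdomen: entry tube (oesophagus stand-in), stomach chamber
## with viscerotomy ring, abdominal cavity containing an ellipsoidal
## gallbladder, cystic duct/artery vessel chains, connective segments and a
## static concave liver surface -- plus a scripted expert control stream
## that completes the three procedure tasks.

#' Generate the toy abdomen scene
#'
#' Builds a deterministic (per seed) simplified trans-gastric scene laid
#' out along the +x feed axis: port at the origin, a straight entry tube, a
#' spherical stomach chamber whose far wall carries the glowing viscerotomy
#' ring, and an outer cavity with the gallbladder (tetrahedral mass-spring
#' body suspended from the liver bed by burnable connective segments), two
#' vessel chains (cystic artery and duct, each with two clip markers and a
#' cut marker) and a concave liver patch.
#'
#' @param seed Integer seed (small positional jitter on tissue anchors).
#' @return A scene list consumed by [run_scenario()].
#' @export
generate_toy_abdomen <- function(seed = 1) {
  with_seed(seed, {
    port <- list(position = c(0, 0, 0), axis = c(1, 0, 0))

    # --- rigid anatomy ----------------------------------------------------
    oeso_line <- cbind(seq(0, 0.12, length.out = 13), 0, 0)
    sw <- sweep_tube(oeso_line, 0.010, 12)
    oesophagus <- tri_mesh(sw$vertices, sw$faces, name = "oesophagus")

    stomach_c <- c(0.16, 0, 0)
    stomach <- sphere_shell_mesh(
      stomach_c, 0.045, n_theta = 14, n_phi = 20,
      holes = list(list(axis = c(-1, 0, 0), half_angle = 16 * pi / 180),
                   list(axis = c(1, 0, 0), half_angle = 20 * pi / 180)),
      name = "stomach")

    wall <- sphere_shell_mesh(
      c(0.22, 0, 0), 0.22, n_theta = 10, n_phi = 14,
      holes = list(list(axis = c(-1, 0, 0), half_angle = 10 * pi / 180)),
      name = "abdominal_wall")

    liver_f <- function(x, y) 0.045 - 8 * ((x - 0.30)^2 + y^2)
    liver <- surface_patch_mesh(c(0.25, 0.35), c(-0.05, 0.05), n = 9,
                                liver_f, name = "liver")

    rigid <- list(oesophagus, stomach, wall, liver)
    rigid <- lapply(rigid, function(m) { m$bvh <- build_bvh(m); m })

    ring <- scene_marker("viscerotomy_ring", c(0.205, 0, 0),
                         axis = c(1, 0, 0), radius = 0.015, id = "ring")

    # --- gallbladder ------------------------------------------------------
    centre_gb <- c(0.30, 0, 0.015) + stats::runif(3, -0.002, 0.002)
    gb_mesh <- generate_ellipsoid_tet_mesh(c(0.025, 0.015, 0.012),
                                           resolution = 3,
                                           center = centre_gb)
    gall <- soft_body(gb_mesh$nodes, gb_mesh$tetrahedra, k_base = 0.1,
                      zeta = 0.4, density = 1000, group = "gallbladder",
                      name = "gallbladder", target = TRUE)

    # connective segments anchor the topmost surface nodes to the liver bed
    surf_nodes <- sort(unique(as.vector(gall$surface)))
    top <- surf_nodes[order(gall$positions[surf_nodes, 3],
                            decreasing = TRUE)]
    # spread the 8 attachments: take top nodes with distinct (x, y) cells
    sel <- integer(0)
    for (nd in top) {
      if (length(sel) >= 8) break
      if (all(vapply(sel, function(s) {
        sqrt(sum((gall$positions[nd, 1:2] - gall$positions[s, 1:2])^2)) >
          0.008
      }, logical(1)))) sel <- c(sel, nd)
    }
    b_pts <- gall$positions[sel, , drop = FALSE]
    a_pts <- cbind(b_pts[, 1], b_pts[, 2],
                   vapply(seq_len(nrow(b_pts)), function(i) {
                     liver_f(b_pts[i, 1], b_pts[i, 2]) - 0.002
                   }, 1))
    segments <- connective_segments(a_pts, b_pts, body_node = sel,
                                    burn_radius = 0.015,
                                    burn_threshold = 0.5)
    # intact attachments hold the gallbladder up (released as they burn)
    gall <- pin_nodes(gall, sel, gall$positions[sel, , drop = FALSE])
    # hybrid assistance: a laparoscopic grasper retracts the gallbladder
    # from the +y side until the endoscopic grasper takes over
    retr <- surf_nodes[order(gall$positions[surf_nodes, 2],
                             decreasing = TRUE)][1:2]
    gall <- pin_nodes(gall, retr, gall$positions[retr, , drop = FALSE])

    # --- vessels ----------------------------------------------------------
    make_vessel <- function(x0, name) {
      ys <- seq(-0.035, 0.035, length.out = 8)
      nodes <- cbind(x0, ys, 0)
      chain <- cbind(1:7, 2:8)
      v <- soft_body(nodes, tetrahedra = NULL, springs = chain,
                     k_base = 0.5, node_mass = 5e-4, group = name,
                     name = name, target = TRUE)
      pin_nodes(v, c(1, 8), nodes[c(1, 8), , drop = FALSE])
    }
    vessels <- list(artery = make_vessel(0.26, "artery"),
                    duct = make_vessel(0.29, "duct"))
    clip_markers <- lapply(vessels, function(v) {
      list(scene_marker("clip_point", v$positions[3, ],
                        axis = c(0, 1, 0), radius = 0.004,
                        id = paste0(v$name, "_clip_1")),
           scene_marker("clip_point", v$positions[6, ],
                        axis = c(0, 1, 0), radius = 0.004,
                        id = paste0(v$name, "_clip_2")),
           scene_marker("clip_point",
                        (v$positions[4, ] + v$positions[5, ]) / 2,
                        axis = c(0, 1, 0), radius = 0.004,
                        id = paste0(v$name, "_cut")))
    })
    connective_markers <- lapply(seq_len(nrow(segments)), function(i) {
      scene_marker("connective",
                   c((segments$ax[i] + segments$bx[i]) / 2,
                     (segments$ay[i] + segments$by[i]) / 2,
                     (segments$az[i] + segments$bz[i]) / 2),
                   radius = 0.003, id = paste0("connective_", i))
    })

    # --- rod and solver ---------------------------------------------------
    params <- rod_parameters(
      n_points = 100, rest_length = 0.01, radius = 0.005,
      point_mass = 4e-3, young_modulus = 5e7, shear_modulus = 2.5e7,
      parallelism_stiffness = 50, linear_damping = 3, angular_damping = 10)
    solver <- solver_config(dt = 5e-4, n_iterations = 2,
                            gravity = c(0, 0, -9.81), friction_mu = 0.2)
    state <- straight_rod_state(params,
                                origin = port$position - port$axis *
                                  (params$n_points - 1) * params$rest_length,
                                axis = port$axis)
    state$active_count <- 2L

    list(rod_params = params, solver = solver, rod_state = state,
         port = port, rigid_meshes = rigid, ring = ring,
         gallbladder = gall, vessels = vessels, segments = segments,
         clip_markers = clip_markers,
         connective_markers = connective_markers,
         task_state = new_task_state(c("artery", "duct")),
         retraction_nodes = retr,
         m_tip = 10, kappa_max = NULL, blade_radius = 0.012,
         grasp_radius = 0.02, seed = as.integer(seed))
  })
}

#' Scripted expert control stream for the toy abdomen
#'
#' A keyframed control timeline at the given frame rate that completes the
#' three tasks on the [generate_toy_abdomen()] scene: axial navigation
#' through the ring, clip-clip-cut on the artery then the duct (steering
#' the tip with the thumb wheels between clips), a three-dwell diathermy
#' sweep over the connective segments plus one deliberate second of
#' off-target activation, and grasp-and-retract of the freed gallbladder
#' back through the ring plane.
#'
#' @param rate Control frame rate, Hz.
#' @return A control data frame for [run_scenario()] (columns `t_s`,
#'   `insertion_m`, `roll_rad`, `wheel_ud`, `wheel_lr`, `tool`,
#'   `protrusion_m`, `jaws`, `pedal`).
#' @export
expert_controls <- function(rate = 20) {
  # keyframes: t, insertion, wheel_ud, wheel_lr, tool, protrusion, jaws, pedal
  kf <- list(
    list(0.0,  0.005, 0,     0,     "none",      0,     FALSE, FALSE),
    list(10.0, 0.260, 0,     0,     "none",      0,     FALSE, FALSE),
    list(11.0, 0.260, 0,     0,     "none",      0,     FALSE, FALSE),
    # artery: clip at y<0, clip at y>0, cut at y~0 (wheel_ud steers in y,
    # wheel_lr lifts the drooping tip in z)
    list(12.0, 0.260, 0.06, -0.10, "clipper",   0.010, FALSE, FALSE),
    list(12.5, 0.260, 0.06, -0.10, "clipper",   0.010, TRUE,  FALSE),
    list(13.0, 0.260, 0.06, -0.10, "clipper",   0.010, FALSE, FALSE),
    list(14.0, 0.260, -0.06, -0.10, "clipper",  0.010, FALSE, FALSE),
    list(14.5, 0.260, -0.06, -0.10, "clipper",  0.010, TRUE,  FALSE),
    list(15.0, 0.260, -0.06, -0.10, "clipper",  0.010, FALSE, FALSE),
    list(16.0, 0.260, 0,    -0.10, "scissors",  0.010, FALSE, FALSE),
    list(16.5, 0.260, 0,    -0.10, "scissors",  0.010, TRUE,  FALSE),
    list(17.0, 0.260, 0,    -0.10, "scissors",  0.010, FALSE, FALSE),
    # duct (one reach deeper)
    list(18.0, 0.260, 0.06, -0.10, "clipper",   0.040, FALSE, FALSE),
    list(18.5, 0.260, 0.06, -0.10, "clipper",   0.040, TRUE,  FALSE),
    list(19.0, 0.260, 0.06, -0.10, "clipper",   0.040, FALSE, FALSE),
    list(20.0, 0.260, -0.06, -0.10, "clipper",  0.040, FALSE, FALSE),
    list(20.5, 0.260, -0.06, -0.10, "clipper",  0.040, TRUE,  FALSE),
    list(21.0, 0.260, -0.06, -0.10, "clipper",  0.040, FALSE, FALSE),
    list(22.0, 0.260, 0,    -0.10, "scissors",  0.040, FALSE, FALSE),
    list(22.5, 0.260, 0,    -0.10, "scissors",  0.040, TRUE,  FALSE),
    list(23.0, 0.260, 0,    -0.10, "scissors",  0.040, FALSE, FALSE),
    # diathermy: four pedal-on dwells sweeping the segment cluster in y
    # and x (insertion step reaches the far segments)
    list(24.0, 0.260, 0.045, -0.20, "diathermy", 0.050, FALSE, FALSE),
    list(24.5, 0.260, 0.045, -0.20, "diathermy", 0.050, FALSE, TRUE),
    list(25.0, 0.260, 0.045, -0.20, "diathermy", 0.050, FALSE, FALSE),
    list(27.0, 0.260, 0.020, -0.20, "diathermy", 0.050, FALSE, TRUE),
    list(27.5, 0.260, 0.020, -0.20, "diathermy", 0.050, FALSE, FALSE),
    list(30.0, 0.275, 0.030, -0.20, "diathermy", 0.050, FALSE, FALSE),
    list(30.2, 0.275, 0.030, -0.20, "diathermy", 0.050, FALSE, TRUE),
    list(30.7, 0.275, 0.030, -0.20, "diathermy", 0.050, FALSE, FALSE),
    # deliberate off-target second (tip retracted into empty cavity)
    list(31.2, 0.260, 0,     0,    "diathermy", 0.010, FALSE, TRUE),
    list(32.2, 0.260, 0,     0,    "diathermy", 0.010, FALSE, FALSE),
    # grasp and retract through the ring plane
    list(33.2, 0.260, 0,    -0.10, "grasper",   0.050, FALSE, FALSE),
    list(33.7, 0.260, 0,    -0.10, "grasper",   0.050, TRUE,  FALSE),
    list(34.2, 0.260, 0,    -0.10, "grasper",   0.050, TRUE,  FALSE),
    list(44.0, 0.070, 0,     0,    "grasper",   0.050, TRUE,  FALSE),
    list(45.0, 0.070, 0,     0,    "grasper",   0.050, TRUE,  FALSE))
  kt <- vapply(kf, function(x) x[[1]], 1)
  times <- seq(1 / rate, max(kt), by = 1 / rate)
  interp_num <- function(col) stats::approx(kt, vapply(kf, function(x)
    x[[col]], 1), xout = times, rule = 2)$y
  step_idx <- findInterval(times, kt)
  data.frame(
    t_s = times,
    insertion_m = interp_num(2),
    roll_rad = 0,
    wheel_ud = interp_num(3),
    wheel_lr = interp_num(4),
    tool = vapply(step_idx, function(i) kf[[i]][[5]], ""),
    protrusion_m = interp_num(6),
    jaws = vapply(step_idx, function(i) kf[[i]][[7]], TRUE),
    pedal = vapply(step_idx, function(i) kf[[i]][[8]], TRUE),
    stringsAsFactors = FALSE)
}
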