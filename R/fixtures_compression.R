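## The rod compression benchmark: a 256-point rod is gradually inserted
## into a seeded tortuous rigid channel that forces extensive wall contact,
## and the axial compression of the centreline is measured.  The hard
## distance-constraint rod is compared against the original stretch-penalty
## baseline at the largest numerically stable penalty stiffness.

#' Generate the compression benchmark scenario
#'
#' A rod of `n_points` points with 1 mm elements (255 mm total at the
#' default 256) is scripted to be inserted into a seeded tortuous tube
#' narrow enough (2 mm radial clearance) that gravity and the winding
#' geometry put most inserted points into wall contact at full insertion.
#' A 60 s linear insertion ramp at the 1 ms solver step is used.
#'
#' @param seed Integer seed for the channel geometry.
#' @param n_points Number of rod points.
#' @param variant `"constrained"` (hard distance chain) or `"penalty"`
#'   (stretch-penalty baseline; set `stretch_modulus` before running or use
#'   [max_stable_stretch_modulus()]).
#' @return A `compression_scenario` list: rod parameters, solver config,
#'   channel mesh (BVH built), port pose and the insertion script.
#' @export
generate_compression_scenario <- function(seed, n_points = 256,
                                          variant = c("constrained",
                                                      "penalty")) {
  variant <- match.arg(variant)
  channel <- generate_tube_channel(channel_spec(seed))
  channel$bvh <- build_bvh(channel)
  params <- rod_parameters(
    n_points = n_points, rest_length = 1e-3, radius = 0.002,
    point_mass = 5e-3, young_modulus = 1e6, shear_modulus = 5e5,
    stretch_modulus = NA_real_, parallelism_stiffness = 1.2,
    linear_damping = 30, angular_damping = 20)
  config <- solver_config(dt = 1e-3, n_iterations = 2,
                          distance_tolerance = 1e-6,
                          gravity = c(0, 0, -9.81), friction_mu = 0.025)
  structure(list(
    seed = as.integer(seed), variant = variant,
    rod_params = params, solver = config, channel = channel,
    port = list(position = c(0, 0, 0), axis = c(1, 0, 0)),
    insertion_start = 0.004, insertion_end = 0.250, duration = 60
  ), class = "compression_scenario")
}

#' Percentage axial compression of the rod centreline
#'
#' `100 * (rest length - current polyline length) / rest length` over the
#' active points; a stretched rod reports a negative compression.
#'
#' @param state A `rod_state`.
#' @param params The rod's `rod_parameters`.
#' @return Compression, %.
#' @export
measure_compression <- function(state, params) {
  a0 <- active_first_point(state)
  n <- nrow(state$positions)
  P <- state$positions[a0:n, , drop = FALSE]
  cur <- sum(sqrt(rowSums(diff(P)^2)))
  rest <- (state$active_count - 1) * params$rest_length
  100 * (rest - cur) / rest
}

#' Run the compression benchmark
#'
#' Inserts the rod along the scripted linear ramp with the hybrid solver
#' (or the stretch-penalty baseline) and reports the final compression and
#' contact coverage.
#'
#' @param scenario A `compression_scenario`.
#' @param duration Override of the scripted duration, s.
#' @param stretch_modulus Penalty stiffness override (`"penalty"` variant),
#'   Pa.
#' @param progress Print progress every k steps (0 = silent).
#' @return A list with `compression` (%), `contact_fraction` (fraction of
#'   active points in wall contact at the end), `state`, `params` and the
#'   per-step `max_elongation` of the final step.
#' @export
run_compression <- function(scenario, duration = NULL,
                            stretch_modulus = NULL, progress = 0) {
  params <- scenario$rod_params
  if (!is.null(stretch_modulus)) params$stretch_modulus <- stretch_modulus
  if (scenario$variant == "penalty" && is.na(params$stretch_modulus)) {
    stop("penalty variant requires a stretch_modulus")
  }
  cfg <- scenario$solver
  dur <- duration %||% scenario$duration
  n_steps <- round(dur / cfg$dt)
  rate <- (scenario$insertion_end - scenario$insertion_start) /
    scenario$duration
  state <- straight_rod_state(params, origin = scenario$port$position -
                                scenario$port$axis *
                                (params$n_points - 1) * params$rest_length,
                              axis = scenario$port$axis)
  state$active_count <- 2L
  drive0 <- apply_base_drive(state, list(insertion = scenario$insertion_start,
                                         roll = 0),
                             scenario$port, params)
  state <- drive0$state
  collision <- prepare_collision(list(scenario$channel))
  diag <- NULL
  for (s in seq_len(n_steps)) {
    ins <- scenario$insertion_start + rate * min(s * cfg$dt, scenario$duration)
    drive <- apply_base_drive(state, list(insertion = ins, roll = 0),
                              scenario$port, params)
    state <- drive$state
    state <- rod_step(state, params, cfg, collision = collision,
                      prescribed_points = drive$prescribed_points,
                      prescribed_frames = drive$prescribed_frames,
                      variant = scenario$variant,
                      feed_axis = scenario$port$axis,
                      port = scenario$port$position)
    if (progress > 0 && s %% progress == 0) {
      diag <- attr(state, "diagnostics")
      message(sprintf(
        "step %d/%d ins=%.0fmm contacts=%d compression=%.3f%%",
        s, n_steps, ins * 1000, diag$n_points_in_contact,
        measure_compression(state, params)))
    }
  }
  diag <- attr(state, "diagnostics")
  list(compression = measure_compression(state, params),
       contact_fraction = diag$n_points_in_contact / state$active_count,
       max_elongation = diag$max_rel_elongation,
       state = state, params = params)
}

#' Largest numerically stable stretch-penalty stiffness
#'
#' Bisection (in log space) for the largest stretching Young's modulus E_s
#' that remains stable over the insertion scenario at the scripted 1 ms
#' time step.  Probes run the full insertion schedule by default (short
#' probes admit stiffnesses that only destabilize at deeper insertion).  A
#' probe counts as unstable if the solver detects divergence, any active
#' point exceeds 0.5 m/s at the end, or any element is stretched beyond
#' 50 % (a quietly broken rod that has escaped the channel).
#'
#' @param scenario A `compression_scenario` (any variant; the probe always
#'   runs the penalty dynamics).
#' @param probe_duration Probe simulation length, s (`NULL` = the
#'   scenario's full duration).
#' @param n_bisect Bisection iterations after bracketing.
#' @param lo Initial (assumed stable) stiffness, Pa; far softer penalty
#'   rods stretch so much they leave the channel.
#' @return The largest stable E_s found, Pa.
#' @export
max_stable_stretch_modulus <- function(scenario, probe_duration = NULL,
                                       n_bisect = 8, lo = 1e5) {
  scen <- scenario
  scen$variant <- "penalty"
  stable <- function(Es) {
    res <- tryCatch(
      run_compression(scen, duration = probe_duration %||% scen$duration,
                      stretch_modulus = Es),
      error = function(e) NULL)
    if (is.null(res)) return(FALSE)
    a0 <- res$params$n_points - res$state$active_count + 1
    max(abs(res$state$velocities[a0:res$params$n_points, ])) < 0.5 &&
      res$max_elongation < 0.5
  }
  if (!stable(lo)) stop("probe unstable even at the initial E_s")
  hi <- lo
  repeat {
    hi <- hi * 4
    if (!stable(hi)) break
    lo <- hi
    if (hi > 1e10) return(lo)
  }
  for (k in seq_len(n_bisect)) {
    mid <- sqrt(lo * hi)
    if (stable(mid)) lo <- mid else hi <- mid
  }
  lo
}
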