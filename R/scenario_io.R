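## Declarative scenario configs (JSON) and control streams (JSON Lines).

rod_json_keys <- c(
  n_points = "n_points", rest_length = "rest_length_m",
  radius = "radius_m", point_mass = "point_mass_kg",
  young_modulus = "young_modulus_pa", shear_modulus = "shear_modulus_pa",
  stretch_modulus = "stretch_modulus_pa",
  parallelism_stiffness = "parallelism_stiffness_n",
  linear_damping = "linear_damping", angular_damping = "angular_damping")

rod_params_to_json <- function(params) {
  out <- lapply(names(rod_json_keys), function(f) params[[f]])
  names(out) <- unname(rod_json_keys)
  out
}

rod_params_from_json <- function(lst, base = NULL) {
  args <- list()
  for (f in names(rod_json_keys)) {
    v <- lst[[rod_json_keys[[f]]]]
    # tolerate nulls serialized as empty objects and skip non-scalar junk
    if (!is.null(v) && !is.list(v) && length(v) == 1 && !is.na(v)) {
      args[[f]] <- as.numeric(v)
    }
  }
  if (!is.null(base)) {
    full <- base[names(rod_json_keys)]
    full[names(args)] <- args
    args <- full
  }
  do.call(rod_parameters, args)
}

solver_to_json <- function(cfg) {
  list(dt_s = cfg$dt, n_iterations = cfg$n_iterations,
       distance_tolerance = cfg$distance_tolerance,
       gravity_mps2 = cfg$gravity, friction_mu = cfg$friction_mu)
}

solver_from_json <- function(lst, base = solver_config()) {
  solver_config(
    dt = lst$dt_s %||% base$dt,
    n_iterations = lst$n_iterations %||% base$n_iterations,
    distance_tolerance = lst$distance_tolerance %||% base$distance_tolerance,
    gravity = lst$gravity_mps2 %||% base$gravity,
    friction_mu = lst$friction_mu %||% base$friction_mu)
}

#' Write a scenario config as JSON
#'
#' @param scenario A scene list (from [generate_toy_abdomen()] or
#'   [generate_compression_scenario()]); only the declarative part
#'   (generator name, seed, rod and solver parameters) is serialized — the
#'   geometry is regenerated from the seed on load.
#' @param path Output path.
#' @param generator Generator name (`"toy_abdomen"` or `"compression"`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path, generator = NULL) {
  if (is.null(generator)) {
    generator <- if (inherits(scenario, "compression_scenario"))
      "compression" else "toy_abdomen"
  }
  cfg <- list(schema_version = 1,
              generator = generator,
              seed = scenario$seed,
              variant = scenario$variant %||% NULL,
              rod = rod_params_to_json(scenario$rod_params),
              solver = solver_to_json(scenario$solver))
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                           null = "null", na = "null")),
             path)
  invisible(path)
}

#' Read a scenario config
#'
#' Regenerates the scene from its generator and seed, then applies any rod
#' or solver parameter overrides present in the JSON.
#'
#' @param path A JSON file written by [write_scenario()] (or hand-written
#'   with the same keys).
#' @return A scene list.
#' @export
read_scenario <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop("scenario config must declare a seed")
  scen <- switch(cfg$generator,
    toy_abdomen = generate_toy_abdomen(cfg$seed),
    compression = generate_compression_scenario(
      cfg$seed, variant = cfg$variant %||% "constrained"),
    stop("unknown generator: ", cfg$generator))
  if (!is.null(cfg$rod)) {
    scen$rod_params <- rod_params_from_json(
      as.list(cfg$rod), base = scen$rod_params)
  }
  if (!is.null(cfg$solver)) {
    scen$solver <- solver_from_json(as.list(cfg$solver), base = scen$solver)
  }
  scen
}

controls_cols <- c("t_s", "insertion_m", "roll_rad", "wheel_ud", "wheel_lr",
                   "tool", "protrusion_m", "jaws", "pedal")

#' Write a control stream as JSON Lines
#'
#' One record per control frame with the keys `t_s`, `insertion_m`,
#' `roll_rad`, `wheel_ud`, `wheel_lr`, `tool`, `protrusion_m`, `jaws`,
#' `pedal`.
#'
#' @param controls Control data frame (see [expert_controls()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_controls <- function(controls, path) {
  stopifnot(all(controls_cols %in% names(controls)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(controls))) {
    rec <- as.list(controls[i, controls_cols])
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                             digits = NA, na = "null")), con)
  }
  invisible(path)
}

#' Read a control stream from JSON Lines
#'
#' @param path File written by [write_controls()].
#' @return A control data frame ordered by time.
#' @export
read_controls <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  df <- do.call(rbind, lapply(recs, function(r) {
    as.data.frame(r[controls_cols], stringsAsFactors = FALSE)
  }))
  df[order(df$t_s), , drop = FALSE]
}

#' Task boundaries from a recorded trajectory
#'
#' Reconstructs the per-task time windows from the `tasks_completed` flags
#' recorded with each frame, so metrics computed at record time and at
#' replay time agree exactly.
#'
#' @param trajectory A `trajectory` whose frames carry
#'   `events$tasks_completed`.
#' @return A `task_boundaries` data frame (`task`, `t_start`, `t_end`).
#' @export
boundaries_from_trajectory <- function(trajectory) {
  frames <- trajectory$frames
  times <- vapply(frames, function(fr) fr$t, numeric(1))
  t_end_all <- times[length(times)]
  done_t <- vapply(1:3, function(k) {
    hit <- which(vapply(frames, function(fr) {
      tc <- fr$events$tasks_completed
      !is.null(tc) && isTRUE(as.logical(tc[k]))
    }, logical(1)))
    if (length(hit) > 0) times[hit[1]] else t_end_all
  }, numeric(1))
  data.frame(task = c("task1", "task2", "task3"),
             t_start = c(0, done_t[1], done_t[2]),
             t_end = done_t)
}
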