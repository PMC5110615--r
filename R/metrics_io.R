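## Trajectory recording/replay and the surgical performance-metric suite,
## exported as CSV.

#' New empty trajectory
#'
#' A trajectory is an append-only sequence of per-frame records (time, tip
#' position, commanded shaft motion, base reaction, tissue contact force,
#' controls snapshot and events), serializable as versioned JSON Lines and
#' replayable through the metrics engine.
#'
#' @return An object of class `trajectory`.
#' @export
new_trajectory <- function() {
  structure(list(schema_version = 1L, frames = list()), class = "trajectory")
}

#' Append a frame to a trajectory
#'
#' @param trajectory A `trajectory`.
#' @param t Frame time, s; must exceed the previous frame's time.
#' @param tip Endoscope tip position (3-vector), m.
#' @param insertion Commanded insertion depth, m.
#' @param controls A `scope_controls` snapshot (or plain list).
#' @param reaction List with `axial_force` (N) and `axial_torque` (N m).
#' @param tissue_force Summed tissue contact force this frame, N.
#' @param events List of events this frame (clips, cuts, diathermy dt,
#'   task completions).
#' @return The extended `trajectory`.
#' @export
record_frame <- function(trajectory, t, tip, insertion, controls,
                         reaction = list(axial_force = 0, axial_torque = 0),
                         tissue_force = 0, events = list()) {
  k <- length(trajectory$frames)
  if (k > 0 && t <= trajectory$frames[[k]]$t) {
    stop("time regression: frame times must be strictly increasing")
  }
  trajectory$frames[[k + 1]] <- list(
    t = t, tip = as.numeric(tip), insertion = insertion,
    controls = unclass(controls), reaction = reaction,
    tissue_force = tissue_force, events = events)
  trajectory
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$frames), " frames",
      if (length(x$frames)) sprintf(", t in [%g, %g] s", x$frames[[1]]$t,
                                    x$frames[[length(x$frames)]]$t), "\n",
      sep = "")
  invisible(x)
}

#' Write a trajectory as JSON Lines
#'
#' First line is a header object carrying `schema_version`; each further
#' line is one frame, serialized at full precision so the round trip is
#' lossless.
#'
#' @param trajectory A `trajectory`.
#' @param path Output path (conventionally `*.traj.jsonl`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(
    list(schema_version = trajectory$schema_version), auto_unbox = TRUE)),
    con)
  for (fr in trajectory$frames) {
    writeLines(as.character(jsonlite::toJSON(fr, auto_unbox = TRUE, digits = NA,
                                             null = "null", na = "null")),
               con)
  }
  invisible(path)
}

#' Read a trajectory from JSON Lines
#'
#' @param path File written by [write_trajectory()].
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty trajectory file")
  header <- jsonlite::fromJSON(lines[1])
  traj <- new_trajectory()
  traj$schema_version <- as.integer(header$schema_version)
  traj$frames <- lapply(lines[-1], function(l) {
    jsonlite::fromJSON(l, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  })
  traj
}

#' Tip path length (economy of movement)
#'
#' Total polygonal length of the tip's path, reported in centimetres; the
#' standard economy-of-movement metric (lower is better).
#'
#' @param tip_positions `k x 3` matrix of tip positions, m (k >= 1).
#' @return Path length, cm.
#' @export
path_length <- function(tip_positions) {
  tip_positions <- matrix(tip_positions, ncol = 3)
  k <- nrow(tip_positions)
  if (k < 2) return(0)
  d <- diff(tip_positions)
  sum(sqrt(rowSums(d^2))) * 100
}

metrics_fields <- c(
  "task", "completion_time_s", "tip_path_length_cm",
  "max_tissue_force_n", "avg_tissue_force_n",
  "max_shaft_velocity_mps", "avg_shaft_velocity_mps",
  "max_shaft_accel_mps2", "avg_shaft_accel_mps2",
  "max_haptic_force_n", "avg_haptic_force_n",
  "clip_distance_mm", "clip_angle_deg", "n_clippings", "n_cuttings",
  "protrusion_degree_m", "n_diathermy_activations", "diathermy_total_s",
  "diathermy_on_target_s", "diathermy_off_target_s", "pct_non_target")

zero_metrics_row <- function(task) {
  row <- as.list(setNames(rep(0, length(metrics_fields)), metrics_fields))
  row$task <- task
  as.data.frame(row, stringsAsFactors = FALSE)
}

frame_field <- function(frames, path, default = 0) {
  vapply(frames, function(fr) {
    v <- fr
    for (p in path) {
      v <- v[[p]]
      if (is.null(v)) return(default)
    }
    as.numeric(v)
  }, numeric(1))
}

#' Compute per-task performance metrics
#'
#' Aggregates a recorded trajectory into one metrics row per task:
#' completion time, tip path length (cm), max/average tissue and haptic
#' forces, max/average commanded shaft velocity and acceleration (central
#' differences of the insertion signal), clipping/cutting distance (mm) and
#' angle (deg, averaged over the task's clip events), instrument protrusion,
#' and the diathermy activation/targeting summary
#' (`pct_non_target = 100 off / (on + off)`, 0 when diathermy was never
#' activated).
#'
#' @param trajectory A `trajectory`.
#' @param task_boundaries Data frame with columns `task`, `t_start`,
#'   `t_end` (s), each window within the trajectory's time range.
#' @return A data frame with one row per task (fields in fixed order).
#' @export
compute_metrics <- function(trajectory, task_boundaries) {
  frames <- trajectory$frames
  times <- vapply(frames, function(fr) fr$t, numeric(1))
  rows <- lapply(seq_len(nrow(task_boundaries)), function(ti) {
    tb <- task_boundaries[ti, ]
    sel <- which(times >= tb$t_start - 1e-12 & times <= tb$t_end + 1e-12)
    if (length(sel) == 0) {
      warning("empty task window for task ", tb$task)
      return(zero_metrics_row(tb$task))
    }
    fr <- frames[sel]
    tt <- times[sel]
    row <- zero_metrics_row(tb$task)
    row$completion_time_s <- tb$t_end - tb$t_start
    tips <- do.call(rbind, lapply(fr, function(f) as.numeric(f$tip)))
    row$tip_path_length_cm <- path_length(tips)
    tf <- frame_field(fr, "tissue_force")
    row$max_tissue_force_n <- max(tf)
    row$avg_tissue_force_n <- mean(tf)
    hf <- abs(frame_field(fr, c("reaction", "axial_force")))
    row$max_haptic_force_n <- max(hf)
    row$avg_haptic_force_n <- mean(hf)
    ins <- frame_field(fr, "insertion")
    if (length(sel) >= 3) {
      # central differences on the commanded insertion signal
      h <- diff(tt)
      vc <- (ins[-c(1, 2)] - ins[-c(length(ins) - 1, length(ins))]) /
        (tt[-c(1, 2)] - tt[-c(length(tt) - 1, length(tt))])
      mid_h <- (h[-1] + h[-length(h)])
      ac <- abs(diff(diff(ins) / h) / (mid_h / 2))
      row$max_shaft_velocity_mps <- max(abs(vc))
      row$avg_shaft_velocity_mps <- mean(abs(vc))
      row$max_shaft_accel_mps2 <- max(ac)
      row$avg_shaft_accel_mps2 <- mean(ac)
    }
    clips <- unlist(lapply(fr, function(f) f$events$clips), recursive = FALSE)
    clips <- Filter(function(cl) isTRUE(cl$ok) || is.null(cl$ok), clips)
    if (length(clips) > 0) {
      row$n_clippings <- length(clips)
      row$clip_distance_mm <-
        mean(vapply(clips, function(cl) cl$distance_to_marker, 1)) * 1000
      row$clip_angle_deg <-
        mean(vapply(clips, function(cl) cl$angle_to_vessel, 1))
    }
    row$n_cuttings <- sum(vapply(fr, function(f) {
      length(f$events$cuts %||% list())
    }, numeric(1)))
    tool_active <- vapply(fr, function(f) {
      !identical(f$controls$tool %||% "none", "none")
    }, logical(1))
    if (any(tool_active)) {
      row$protrusion_degree_m <- max(vapply(fr[tool_active], function(f) {
        as.numeric(f$controls$protrusion %||% 0)
      }, numeric(1)))
    }
    pedal <- vapply(fr, function(f) isTRUE(f$controls$pedal), logical(1))
    row$n_diathermy_activations <- sum(diff(c(FALSE, pedal)) == 1)
    on_dt <- frame_field(fr, c("events", "burn_on_dt"))
    off_dt <- frame_field(fr, c("events", "burn_off_dt"))
    row$diathermy_on_target_s <- sum(on_dt)
    row$diathermy_off_target_s <- sum(off_dt)
    row$diathermy_total_s <- sum(on_dt) + sum(off_dt)
    row$pct_non_target <- if (row$diathermy_total_s > 0) {
      100 * row$diathermy_off_target_s / row$diathermy_total_s
    } else 0
    row
  })
  do.call(rbind, rows)
}

#' Write metrics rows as CSV
#'
#' Fixed header order matching the metrics fields, RFC 4180 quoting for
#' text, numbers rendered with 6 significant digits; one row per task.  The
#' output is byte-deterministic for a given input.
#'
#' @param rows Data frame from [compute_metrics()] (0 or more rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(rows, path) {
  quote_field <- function(x) {
    if (grepl('[",\n]', x)) paste0('"', gsub('"', '""', x), '"') else x
  }
  lines <- paste(metrics_fields, collapse = ",")
  if (nrow(rows) > 0) {
    for (i in seq_len(nrow(rows))) {
      vals <- vapply(metrics_fields, function(f) {
        v <- rows[[f]][i]
        if (is.character(v)) quote_field(v) else sprintf("%.6g", v)
      }, character(1))
      lines <- c(lines, paste(vals, collapse = ","))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a metrics CSV
#'
#' @param path File written by [write_metrics_csv()].
#' @return A data frame.
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups: exact permutation p-value
#' when both groups have at most 8 observations, normal approximation with
#' tie correction and continuity correction otherwise.  The reported U is
#' the first group's statistic (`U_a + U_b = n_a n_b`).
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A list with `U` and two-sided `p_value`.
#' @export
mannwhitney_u <- function(group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  Ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (length(unique(pooled)) == 1) {
    return(list(U = Ua, p_value = 1))
  }
  if (max(na, nb) <= 8) {
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2, function(s) sum(rk[s]) - na * (na + 1) / 2)
    p <- mean(abs(us - mu) >= abs(Ua - mu) - 1e-12)
  } else {
    N <- na + nb
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
    z <- (Ua - mu - sign(Ua - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = Ua, p_value = p)
}
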