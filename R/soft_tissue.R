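## Mass-spring tetrahedral deformable bodies (gallbladder, vessels,
## connective tissue) with pinning (grasp/clip), spring severing (scissors)
## and timed diathermy burning.

#' Read a TetGen .node / .ele tetrahedral mesh
#'
#' Parses the TetGen dialect: the `.node` header is
#' `<#points> <dim> <#attrs> <#markers>` followed by `index x y z ...`
#' lines; the `.ele` header is `<#tets> <nodes/tet> <#attrs>`.  The file's
#' declared first index (0 or 1) is honoured; indices are 1-based
#' internally.
#'
#' @param node_path,ele_path Paths to the `.node` and `.ele` files (or
#'   character vectors of lines via `text = TRUE` semantics when the path
#'   does not exist on disk).
#' @return A list with `nodes` (`n x 3` matrix, m) and `tetrahedra`
#'   (`t x 4` integer matrix, 1-based).
#' @export
read_tetgen <- function(node_path, ele_path) {
  read_lines_maybe <- function(x) {
    if (length(x) == 1 && file.exists(x)) readLines(x, warn = FALSE) else x
  }
  strip <- function(lines) {
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines[nzchar(lines)]
  }
  nl <- strip(read_lines_maybe(node_path))
  el <- strip(read_lines_maybe(ele_path))
  toks <- function(l) as.numeric(strsplit(l, "[[:space:]]+")[[1]])
  nh <- toks(nl[1])
  if (length(nh) < 2 || nh[2] != 3) stop("malformed .node header: dimension must be 3")
  n_nodes <- nh[1]
  if (length(nl) - 1 < n_nodes) stop("malformed .node file: too few node lines")
  node_rows <- t(vapply(nl[2:(n_nodes + 1)], toks,
                        numeric(length(toks(nl[2]))), USE.NAMES = FALSE))
  first_index <- node_rows[1, 1]
  if (!first_index %in% c(0, 1)) stop("malformed .node file: first index must be 0 or 1")
  nodes <- node_rows[, 2:4, drop = FALSE]
  eh <- toks(el[1])
  if (length(eh) < 2 || eh[2] != 4) stop("malformed .ele header: need 4 nodes per tetrahedron")
  n_tets <- eh[1]
  if (length(el) - 1 < n_tets) stop("malformed .ele file: too few element lines")
  ele_rows <- t(vapply(el[2:(n_tets + 1)], toks,
                       numeric(length(toks(el[2]))), USE.NAMES = FALSE))
  tets <- ele_rows[, 2:5, drop = FALSE] - first_index + 1
  if (min(tets) < 1 || max(tets) > n_nodes) {
    stop("malformed .ele file: node index out of range")
  }
  list(nodes = nodes, tetrahedra = matrix(as.integer(tets), ncol = 4))
}

#' Write a TetGen .node / .ele mesh pair
#'
#' @param nodes `n x 3` matrix.
#' @param tetrahedra `t x 4` 1-based integer matrix.
#' @param node_path,ele_path Output paths.
#' @return `node_path`, invisibly.
#' @export
write_tetgen <- function(nodes, tetrahedra, node_path, ele_path) {
  nl <- c(sprintf("%d 3 0 0", nrow(nodes)),
          sprintf("%d %.9g %.9g %.9g", seq_len(nrow(nodes)),
                  nodes[, 1], nodes[, 2], nodes[, 3]))
  writeLines(nl, node_path)
  el <- c(sprintf("%d 4 0", nrow(tetrahedra)),
          sprintf("%d %d %d %d %d", seq_len(nrow(tetrahedra)),
                  tetrahedra[, 1], tetrahedra[, 2], tetrahedra[, 3],
                  tetrahedra[, 4]))
  writeLines(el, ele_path)
  invisible(node_path)
}

#' Unique spring edges of a tetrahedral mesh
#'
#' @param tetrahedra `t x 4` 1-based integer matrix.
#' @return A 2-column integer matrix: each undirected tet edge exactly once,
#'   rows sorted.
#' @export
springs_from_tets <- function(tetrahedra) {
  tt <- as.matrix(tetrahedra)
  pairs <- rbind(tt[, c(1, 2)], tt[, c(1, 3)], tt[, c(1, 4)],
                 tt[, c(2, 3)], tt[, c(2, 4)], tt[, c(3, 4)])
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- unique(pairs)
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE]
  c_ <- nodes[tets[, 3], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE]
  u <- b - a; v <- c_ - a; w <- d - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

# boundary faces (appearing in exactly one tet), outward-oriented for
# positive-volume tets
surface_faces <- function(tets) {
  f <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
             tets[, c(1, 4, 3)], tets[, c(2, 3, 4)])
  key <- apply(f, 1, function(x) paste(sort(x), collapse = "-"))
  cnt <- table(key)
  f[key %in% names(cnt)[cnt == 1], , drop = FALSE]
}

#' Mass-spring soft body
#'
#' Builds a tetrahedral mass-spring body.  Springs are the unique tet edges;
#' per-edge stiffness is length-normalized (`k_s = k_base / rest_length`)
#' and damping follows a fixed damping ratio
#' (`k_d = 2 zeta sqrt(k_s m_reduced)`).  Node masses lump the adjacent tet
#' volumes at the given tissue density.
#'
#' @param nodes `n x 3` matrix of node positions, m.
#' @param tetrahedra `t x 4` 1-based integer matrix (positive volumes), or
#'   `NULL` when `springs` are given directly (e.g. vessel chains).
#' @param springs Optional explicit 2-column edge matrix (1-based) used when
#'   `tetrahedra` is `NULL`.
#' @param k_base Base spring stiffness before length normalization, N.
#' @param zeta Spring damping ratio (dimensionless).
#' @param density Tissue density for lumped node masses, kg/m^3.
#' @param node_mass Explicit per-node mass, kg (overrides `density` lumping;
#'   required when no tetrahedra are given).
#' @param group Spring group label (recycled) used by tool filters.
#' @param name Body label for metrics (target vs non-target tissue).
#' @param target Logical: target tissue for diathermy?
#' @return An object of class `soft_body`.
#' @export
soft_body <- function(nodes, tetrahedra = NULL, springs = NULL,
                      k_base = 30, zeta = 0.5, density = 1000,
                      node_mass = NULL, group = "tissue", name = "soft",
                      target = TRUE) {
  nodes <- as.matrix(nodes)
  n <- nrow(nodes)
  if (!is.null(tetrahedra)) {
    tetrahedra <- matrix(as.integer(as.matrix(tetrahedra)), ncol = 4)
    vols <- tet_volumes(nodes, tetrahedra)
    if (any(vols <= 0)) stop("degenerate tetrahedron (non-positive volume)")
    edges <- springs_from_tets(tetrahedra)
    if (is.null(node_mass)) {
      node_mass <- numeric(n)
      for (c_ in 1:4) {
        agg <- tapply(rep(vols / 4, 1), tetrahedra[, c_], sum)
        node_mass[as.integer(names(agg))] <-
          node_mass[as.integer(names(agg))] + agg
      }
      node_mass <- node_mass * density
    }
    surf <- surface_faces(tetrahedra)
  } else {
    if (is.null(springs)) stop("need tetrahedra or explicit springs")
    edges <- matrix(as.integer(as.matrix(springs)), ncol = 2)
    if (is.null(node_mass)) stop("node_mass required without tetrahedra")
    surf <- NULL
    tetrahedra <- matrix(integer(0), 0, 4)
  }
  node_mass <- rep_len(node_mass, n)
  if (any(edges[, 1] == edges[, 2])) stop("spring endpoints must be distinct")
  rest <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                        nodes[edges[, 2], , drop = FALSE])^2))
  if (any(rest <= 0)) stop("zero rest-length spring")
  ks <- k_base / rest
  m_red <- (node_mass[edges[, 1]] * node_mass[edges[, 2]]) /
    (node_mass[edges[, 1]] + node_mass[edges[, 2]])
  kd <- 2 * zeta * sqrt(ks * m_red)
  structure(list(
    positions = nodes,
    velocities = matrix(0, n, 3),
    masses = node_mass,
    pinned = data.frame(node = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0)),
    springs = data.frame(i = edges[, 1], j = edges[, 2], rest = rest,
                         stiffness = ks, damping = kd,
                         group = rep_len(group, nrow(edges)),
                         alive = TRUE),
    tetrahedra = tetrahedra,
    surface = surf,
    name = name, target = isTRUE(target)
  ), class = "soft_body")
}

#' @export
print.soft_body <- function(x, ...) {
  cat("<soft_body '", x$name, "'> ", nrow(x$positions), " nodes, ",
      sum(x$springs$alive), "/", nrow(x$springs), " springs alive, ",
      nrow(x$tetrahedra), " tets\n", sep = "")
  invisible(x)
}

#' Surface mesh view of a soft body
#'
#' @param body A `soft_body` built from tetrahedra.
#' @return A `tri_mesh` over the body's current node positions.
#' @export
soft_body_surface <- function(body) {
  if (is.null(body$surface)) stop("body has no tetrahedral surface")
  tri_mesh(body$positions, body$surface, name = body$name,
           target = body$target)
}

#' Advance a mass-spring body one step
#'
#' Per-spring force `-k_s (len - rest) dir - k_d (relvel . dir) dir`
#' applied equal and opposite; semi-implicit Euler; pinned nodes copy their
#' driver pose exactly with zero relative velocity; dead springs contribute
#' nothing.
#'
#' @param body A `soft_body`.
#' @param dt Time step, s.
#' @param gravity Gravity vector, m/s^2.
#' @return The advanced `soft_body`.
#' @export
msm_step <- function(body, dt, gravity = c(0, 0, -9.81)) {
  sp <- body$springs
  out <- cpp_msm_step(body$positions, body$velocities, body$masses,
                      sp$i, sp$j, sp$rest, sp$stiffness, sp$damping,
                      sp$alive, body$pinned$node,
                      as.matrix(body$pinned[, c("x", "y", "z")]), dt,
                      as.numeric(gravity))
  body$positions <- out$positions
  body$velocities <- out$velocities
  body
}

#' Pin nodes to a driver pose
#'
#' Pinned nodes copy the driver position every step (grasper jaws, clips,
#' laparoscopic retraction).  Pinning an already-pinned node updates its
#' driver.
#'
#' @param body A `soft_body`.
#' @param node_ids Node indices (1-based).
#' @param positions `k x 3` matrix (or 3-vector, recycled) of driver
#'   positions.
#' @return The updated `soft_body`.
#' @export
pin_nodes <- function(body, node_ids, positions) {
  node_ids <- as.integer(node_ids)
  stopifnot(all(node_ids >= 1), all(node_ids <= nrow(body$positions)))
  positions <- matrix(positions, ncol = 3)
  if (nrow(positions) == 1) {
    positions <- positions[rep(1, length(node_ids)), , drop = FALSE]
  }
  keep <- !(body$pinned$node %in% node_ids)
  body$pinned <- rbind(body$pinned[keep, , drop = FALSE],
                       data.frame(node = node_ids, x = positions[, 1],
                                  y = positions[, 2], z = positions[, 3]))
  body$positions[node_ids, ] <- positions
  body$velocities[node_ids, ] <- 0
  body
}

#' Release pinned nodes
#'
#' Restores dynamics without injecting any impulse (released nodes keep zero
#' velocity).
#'
#' @inheritParams pin_nodes
#' @return The updated `soft_body`.
#' @export
release_nodes <- function(body, node_ids) {
  body$pinned <- body$pinned[!(body$pinned$node %in% as.integer(node_ids)),
                             , drop = FALSE]
  body
}

# min distance from point p to segment (a, b)
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

#' Sever springs with a blade
#'
#' Marks dead exactly the alive springs (matching the group filter) whose
#' segment passes within `blade_radius` of `blade_center`.
#'
#' @param body A `soft_body`.
#' @param blade_center Blade position (3-vector).
#' @param blade_radius Capture radius, m.
#' @param group Optional group label filter.
#' @return A list with the updated `body` and `severed` (row indices of the
#'   removed springs).
#' @export
sever_springs <- function(body, blade_center, blade_radius, group = NULL) {
  cand <- if (is.null(group)) which(body$springs$alive) else
    which(body$springs$alive & body$springs$group %in% group)
  hit <- cand[vapply(cand, function(k) {
    point_segment_distance(blade_center,
                           body$positions[body$springs$i[k], ],
                           body$positions[body$springs$j[k], ]) <=
      blade_radius
  }, logical(1))]
  body$springs$alive[hit] <- FALSE
  list(body = body, severed = hit)
}

#' Connective-tissue segments
#'
#' Burnable line segments anchoring the gallbladder to the liver bed.  Each
#' segment tracks accumulated diathermy exposure and dies when it reaches
#' its burn threshold.
#'
#' @param a `k x 3` matrix of fixed anchor points (liver side), m.
#' @param b `k x 3` matrix of gallbladder-side endpoints, m (updated by the
#'   scene as the body deforms), or `body_node` ids.
#' @param body_node Optional integer vector of gallbladder node ids for the
#'   b-side endpoints.
#' @param burn_radius Diathermy capture radius, m.
#' @param burn_threshold Accumulated exposure needed to burn through, s.
#' @return A `data.frame` of class `connective_segments`.
#' @export
connective_segments <- function(a, b, body_node = NA_integer_,
                                burn_radius = 0.008, burn_threshold = 0.5) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  df <- data.frame(ax = a[, 1], ay = a[, 2], az = a[, 3],
                   bx = b[, 1], by = b[, 2], bz = b[, 3],
                   body_node = rep_len(as.integer(body_node), nrow(a)),
                   burn_radius = rep_len(burn_radius, nrow(a)),
                   burn_threshold = rep_len(burn_threshold, nrow(a)),
                   exposure = 0, alive = TRUE)
  class(df) <- c("connective_segments", "data.frame")
  df
}

#' Accumulate diathermy exposure
#'
#' With the pedal active, every alive segment within its burn radius of the
#' tool tip accumulates `dt` of exposure (and dies at its threshold); the
#' frame counts as on-target if at least one segment was in range, else as
#' off-target burning.
#'
#' @param segments A `connective_segments` frame.
#' @param tool_tip Diathermy tip position (3-vector).
#' @param pedal_active Logical: diathermy pedal pressed?
#' @param dt Frame duration, s (> 0).
#' @return A list with updated `segments`, `on_target_dt` and
#'   `off_target_dt`.
#' @export
burn_update <- function(segments, tool_tip, pedal_active, dt) {
  stopifnot(dt > 0)
  if (!isTRUE(pedal_active)) {
    return(list(segments = segments, on_target_dt = 0, off_target_dt = 0))
  }
  alive <- which(segments$alive)
  in_range <- alive[vapply(alive, function(k) {
    point_segment_distance(tool_tip,
                           c(segments$ax[k], segments$ay[k], segments$az[k]),
                           c(segments$bx[k], segments$by[k], segments$bz[k])) <=
      segments$burn_radius[k]
  }, logical(1))]
  if (length(in_range) > 0) {
    segments$exposure[in_range] <- segments$exposure[in_range] + dt
    # tolerance so that exposure accumulated in equal slices of exactly
    # the threshold kills the segment despite floating-point rounding
    segments$alive[in_range] <-
      segments$exposure[in_range] < segments$burn_threshold[in_range] - 1e-9
    list(segments = segments, on_target_dt = dt, off_target_dt = 0)
  } else {
    list(segments = segments, on_target_dt = 0, off_target_dt = dt)
  }
}
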