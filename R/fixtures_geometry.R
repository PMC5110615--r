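## Seeded synthetic geometry: swept-tube channels and programmatic
## tetrahedral meshes.  All generators are deterministic per seed.

# run code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Channel specification
#'
#' Parameters of the seeded tortuous rigid channel used for the rod
#' compression benchmark.
#'
#' @param seed Integer seed.
#' @param n_waypoints Number of random waypoints (>= 3).
#' @param bounding_box Half-extents of the lateral waypoint jitter `(y, z)`,
#'   m.
#' @param length Axial extent of the channel, m.
#' @param tube_radius Inner tube radius, m (must exceed the rod radius).
#' @param samples_per_segment Centreline samples per waypoint segment.
#' @param ring_vertices Vertices per cross-section ring.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(seed, n_waypoints = 7,
                         bounding_box = c(0.018, 0), length = 0.30,
                         tube_radius = 0.005, samples_per_segment = 8,
                         ring_vertices = 12) {
  stopifnot(n_waypoints >= 3, tube_radius > 0, samples_per_segment >= 2)
  structure(list(seed = as.integer(seed), n_waypoints = n_waypoints,
                 bounding_box = bounding_box, length = length,
                 tube_radius = tube_radius,
                 samples_per_segment = samples_per_segment,
                 ring_vertices = ring_vertices),
            class = "channel_spec")
}

# discrete curvature radii of a polyline (Inf at the ends)
polyline_curvature_radius <- function(P) {
  n <- nrow(P)
  if (n < 3) return(Inf)
  r <- rep(Inf, n - 2)
  for (i in 2:(n - 1)) {
    a <- P[i, ] - P[i - 1, ]
    b <- P[i + 1, ] - P[i, ]
    la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2))
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    sin_t <- sqrt(sum(cr^2)) / (la * lb)
    if (sin_t > 1e-12) r[i - 1] <- (la + lb) / 2 / sin_t
  }
  min(r)
}

sweep_tube <- function(centreline, tube_radius, ring_vertices) {
  ns <- nrow(centreline)
  # parallel-transported frames along the centreline
  tangents <- rbind(centreline[2, ] - centreline[1, ],
                    (centreline[3:ns, ] - centreline[1:(ns - 2), ]),
                    centreline[ns, ] - centreline[ns - 1, ])
  tangents <- tangents / sqrt(rowSums(tangents^2))
  u <- pracma_nullvec(tangents[1, ])
  verts <- matrix(0, ns * ring_vertices, 3)
  ang <- 2 * pi * (seq_len(ring_vertices) - 1) / ring_vertices
  for (i in seq_len(ns)) {
    t_i <- tangents[i, ]
    u <- u - sum(u * t_i) * t_i     # transport the frame
    u <- u / sqrt(sum(u^2))
    v <- c(t_i[2] * u[3] - t_i[3] * u[2], t_i[3] * u[1] - t_i[1] * u[3],
           t_i[1] * u[2] - t_i[2] * u[1])
    ring <- centreline[rep(i, ring_vertices), , drop = FALSE] +
      tube_radius * (outer(cos(ang), u) + outer(sin(ang), v))
    verts[((i - 1) * ring_vertices + 1):(i * ring_vertices), ] <- ring
  }
  faces <- matrix(0L, 2 * (ns - 1) * ring_vertices, 3)
  fi <- 1
  for (i in seq_len(ns - 1)) {
    base <- (i - 1) * ring_vertices
    for (k in seq_len(ring_vertices)) {
      k2 <- if (k == ring_vertices) 1L else k + 1L
      a <- base + k; b <- base + k2
      c_ <- base + ring_vertices + k; d <- base + ring_vertices + k2
      faces[fi, ] <- c(a, b, c_); fi <- fi + 1
      faces[fi, ] <- c(b, d, c_); fi <- fi + 1
    }
  }
  list(vertices = verts, faces = faces)
}

#' Generate a tortuous tube channel
#'
#' Sweeps a circular tube of `tube_radius` along a smooth interpolating
#' curve through seeded random waypoints (the first segment is straight
#' along +x so a rod can be fed in axially).  If the sampled centreline's
#' curvature radius falls below the tube radius the waypoints are jittered
#' and regeneration retried a bounded number of times.
#'
#' @param spec A `channel_spec`.
#' @param max_retries Bound on regeneration attempts.
#' @return A `tri_mesh`; the sampled `centreline` and its arc `length` are
#'   attached as attributes.
#' @export
generate_tube_channel <- function(spec, max_retries = 10) {
  mesh <- with_seed(spec$seed, {
    for (attempt in seq_len(max_retries)) {
      nw <- spec$n_waypoints
      x <- c(0, spec$length * 0.15, seq(spec$length * 0.3, spec$length,
                                        length.out = nw - 2))
      # alternating bends of fixed amplitude with seeded jitter: the total
      # tortuosity (and hence the axial load on an inserted rod) is
      # comparable across seeds while the shape itself is random
      sgn <- (-1)^seq_len(nw - 2)
      y <- c(0, 0, sgn * spec$bounding_box[1] *
               stats::runif(nw - 2, 0.85, 1))
      # the channel winds in the horizontal plane only: gravity then loads
      # the rod against the tube floor without a height-dependent axial
      # (Bernoulli) tension term, so sliding friction and bend reactions
      # set the axial load
      z <- c(0, 0, sgn * spec$bounding_box[2] *
               stats::runif(nw - 2, 0.8, 1))
      ns <- spec$samples_per_segment * (nw - 1) + 1
      s <- seq(1, nw, length.out = ns)
      P <- cbind(stats::spline(seq_len(nw), x, xout = s)$y,
                 stats::spline(seq_len(nw), y, xout = s)$y,
                 stats::spline(seq_len(nw), z, xout = s)$y)
      if (polyline_curvature_radius(P) >= spec$tube_radius * 1.2) break
      if (attempt == max_retries) {
        stop("self-intersecting centreline after ", max_retries, " retries")
      }
    }
    sw <- sweep_tube(P, spec$tube_radius, spec$ring_vertices)
    m <- tri_mesh(sw$vertices, sw$faces, name = "channel")
    attr(m, "centreline") <- P
    attr(m, "length") <- sum(sqrt(rowSums(diff(P)^2)))
    m
  })
  mesh
}

# 6-tetrahedra (Kuhn) decomposition of the unit cube, corners indexed
# (i, j, k) in {0,1}^3 -> 1 + i + 2 j + 4 k
kuhn_tets <- matrix(c(
  1, 2, 4, 8,
  1, 4, 3, 8,
  1, 3, 7, 8,
  1, 7, 5, 8,
  1, 5, 6, 8,
  1, 6, 2, 8), ncol = 4, byrow = TRUE)

#' Generate an ellipsoidal tetrahedral mesh
#'
#' Fills the ellipsoid with a regular cube grid (Kuhn 6-tet decomposition),
#' keeping the tetrahedra whose four corners lie inside the ellipsoid and
#' projecting nothing (all nodes remain strictly inside).
#'
#' @param semi_axes Ellipsoid semi-axes `(a, b, c)`, m.
#' @param resolution Grid cells per semi-axis (>= 2).
#' @param center Ellipsoid centre, m.
#' @return A list with `nodes` (`n x 3`) and `tetrahedra` (`t x 4`,
#'   positive volumes).
#' @export
generate_ellipsoid_tet_mesh <- function(semi_axes, resolution = 3,
                                        center = c(0, 0, 0)) {
  stopifnot(resolution >= 2, length(semi_axes) == 3, all(semi_axes > 0))
  h <- 1 / resolution
  g <- seq(-1, 1, by = h)
  ng <- length(g)
  idx <- function(i, j, k) (k - 1) * ng * ng + (j - 1) * ng + i
  # grid nodes in the unit ball coordinates
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  inside <- rowSums(grid^2) <= 1 + 1e-12
  tets <- list()
  for (k in seq_len(ng - 1)) for (j in seq_len(ng - 1)) {
    for (i in seq_len(ng - 1)) {
      corners <- c(idx(i, j, k), idx(i + 1, j, k), idx(i, j + 1, k),
                   idx(i + 1, j + 1, k), idx(i, j, k + 1),
                   idx(i + 1, j, k + 1), idx(i, j + 1, k + 1),
                   idx(i + 1, j + 1, k + 1))
      if (!all(inside[corners])) next
      tets[[length(tets) + 1]] <- matrix(corners[kuhn_tets], ncol = 4)
    }
  }
  if (length(tets) == 0) stop("resolution too coarse for this ellipsoid")
  tt <- do.call(rbind, tets)
  used <- sort(unique(as.vector(tt)))
  remap <- match(tt, used)
  tt <- matrix(remap, ncol = 4)
  nodes <- grid[used, , drop = FALSE]
  nodes <- sweep(nodes, 2, semi_axes, `*`)
  nodes <- sweep(nodes, 2, center, `+`)
  # enforce positive orientation
  vols <- tet_volumes(nodes, tt)
  flip <- vols < 0
  if (any(flip)) tt[flip, c(3, 4)] <- tt[flip, c(4, 3)]
  list(nodes = nodes, tetrahedra = tt)
}

# open UV-sphere shell with circular holes around the given directions
sphere_shell_mesh <- function(center, radius, n_theta = 16, n_phi = 24,
                              holes = list(), name = "shell",
                              target = FALSE) {
  th <- seq(0, pi, length.out = n_theta + 1)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  verts <- matrix(0, 0, 3)
  vid <- matrix(0L, n_theta + 1, n_phi)
  for (i in seq_len(n_theta + 1)) {
    for (j in seq_len(n_phi)) {
      p <- center + radius * c(sin(th[i]) * cos(ph[j]),
                               sin(th[i]) * sin(ph[j]), cos(th[i]))
      verts <- rbind(verts, p)
      vid[i, j] <- nrow(verts)
    }
  }
  faces <- matrix(0L, 0, 3)
  for (i in seq_len(n_theta)) {
    for (j in seq_len(n_phi)) {
      j2 <- if (j == n_phi) 1L else j + 1L
      a <- vid[i, j]; b <- vid[i, j2]
      c_ <- vid[i + 1, j]; d <- vid[i + 1, j2]
      if (i > 1) faces <- rbind(faces, c(a, b, c_))
      if (i < n_theta) faces <- rbind(faces, c(b, d, c_))
    }
  }
  # drop degenerate pole slivers and faces inside the holes
  keep <- vapply(seq_len(nrow(faces)), function(f) {
    tri <- verts[faces[f, ], , drop = FALSE]
    cen <- colMeans(tri)
    dirn <- (cen - center) / sqrt(sum((cen - center)^2))
    for (h in holes) {
      if (sum(dirn * h$axis) > cos(h$half_angle)) return(FALSE)
    }
    ab <- tri[2, ] - tri[1, ]; ac <- tri[3, ] - tri[1, ]
    cr <- c(ab[2] * ac[3] - ab[3] * ac[2], ab[3] * ac[1] - ab[1] * ac[3],
            ab[1] * ac[2] - ab[2] * ac[1])
    sqrt(sum(cr^2)) > 1e-12
  }, logical(1))
  faces <- faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  faces <- matrix(match(faces, used), ncol = 3)
  tri_mesh(verts[used, , drop = FALSE], faces, name = name, target = target)
}

# rectangular concave patch z = f(x, y) triangulated on a grid
surface_patch_mesh <- function(x_range, y_range, n = 10, f, name = "patch") {
  xs <- seq(x_range[1], x_range[2], length.out = n)
  ys <- seq(y_range[1], y_range[2], length.out = n)
  verts <- matrix(0, 0, 3)
  vid <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    verts <- rbind(verts, c(xs[i], ys[j], f(xs[i], ys[j])))
    vid[i, j] <- nrow(verts)
  }
  faces <- matrix(0L, 0, 3)
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    faces <- rbind(faces,
                   c(vid[i, j], vid[i + 1, j], vid[i, j + 1]),
                   c(vid[i + 1, j], vid[i + 1, j + 1], vid[i, j + 1]))
  }
  tri_mesh(verts, faces, name = name)
}
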