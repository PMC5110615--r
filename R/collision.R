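## Broad- and narrow-phase collision detection between rod points (spheres)
## and triangle meshes via a dynamic AABB bounding volume hierarchy.

#' Triangle mesh
#'
#' @param vertices `V x 3` numeric matrix of vertex positions, m.
#' @param faces `F x 3` integer matrix of 1-based vertex indices; the face
#'   winding defines the outward normal (right-handed).
#' @param name Label used by the metrics layer (e.g. target vs non-target
#'   tissue).
#' @param target Logical flag: is this a target tissue for diathermy?
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, name = "mesh", target = FALSE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices)) {
      stop("face indices out of range")
    }
    a <- vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 2], , drop = FALSE]
    c_ <- vertices[faces[, 3], , drop = FALSE]
    cr <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) -
                (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
                (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) -
                (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
                (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
                (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
    area2 <- sqrt(rowSums(cr^2))
    if (any(area2 < 1e-16)) stop("degenerate (zero-area) face in mesh")
  }
  structure(list(vertices = vertices, faces = faces, name = name,
                 target = isTRUE(target), bvh = NULL),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh '", x$name, "'> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

mesh_aabb <- function(mesh) {
  list(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

#' Build an AABB bounding volume hierarchy over a mesh
#'
#' Deterministic construction: recursive median split of the face list along
#' the longest axis of the node's AABB, ties broken by face index; leaves
#' hold at most `leaf_size` faces.
#'
#' @param mesh A `tri_mesh` with at least one face.
#' @param leaf_size Maximum faces per leaf.
#' @return A BVH object (opaque list of flat node arrays) of class
#'   `rod_bvh`.
#' @export
build_bvh <- function(mesh, leaf_size = 4) {
  if (nrow(mesh$faces) < 1) stop("empty mesh: cannot build BVH")
  structure(cpp_bvh_build(mesh$vertices, mesh$faces, as.integer(leaf_size)),
            class = "rod_bvh")
}

#' Refit a BVH after vertex motion
#'
#' Recomputes all node AABBs bottom-up for moved vertices without
#' re-partitioning; topology must be unchanged.
#'
#' @param bvh A `rod_bvh`.
#' @param mesh The mesh with updated `vertices` (same faces).
#' @return The refitted `rod_bvh`.
#' @export
refit_bvh <- function(bvh, mesh) {
  if (bvh$n_faces != nrow(mesh$faces)) {
    stop("face count mismatch: BVH was built for a different mesh")
  }
  structure(cpp_bvh_refit(unclass(bvh), mesh$vertices, mesh$faces),
            class = "rod_bvh")
}

#' Broad-phase sphere query against a BVH
#'
#' Returns the ids of faces whose AABB intersects the query sphere — a
#' deterministic superset of the faces within `radius` of `center`.
#'
#' @param bvh A `rod_bvh`.
#' @param center Query sphere centre (3-vector).
#' @param radius Query sphere radius, m (>= 0).
#' @return Sorted integer vector of candidate face ids (1-based).
#' @export
query_sphere <- function(bvh, center, radius) {
  stopifnot(radius >= 0)
  cpp_bvh_query_sphere(unclass(bvh), as.numeric(center), radius)
}

#' Closest point on a triangle
#'
#' Exact Euclidean closest point among the face, edge and vertex regions.
#'
#' @param p Query point (3-vector).
#' @param a,b,c Triangle vertices (3-vectors); must be non-degenerate.
#' @return A list with `point` (3-vector) and `distance`.
#' @export
closest_point_triangle <- function(p, a, b, c) {
  cpp_closest_point_triangle(as.numeric(p), as.numeric(a), as.numeric(b),
                             as.numeric(c))
}

#' Generate rod-point contacts against meshes
#'
#' Treats every active rod point as a sphere of the rod radius; for each
#' (point, mesh) pair whose nearest surface point lies closer than the
#' radius, emits one contact with depth `radius - distance` and normal from
#' the closest surface point toward the rod point.
#'
#' @param state A `rod_state`.
#' @param meshes List of `tri_mesh` objects (BVHs built on demand).
#' @param rod_radius Rod cross-section radius, m.
#' @param mu Friction coefficient stored on the contacts.
#' @return A contact `data.frame` (see [contact_constraints()]) with an
#'   extra `mesh` column.
#' @export
generate_rod_contacts <- function(state, meshes, rod_radius, mu = 0.3) {
  if (length(meshes) == 0) {
    return(cbind(contact_constraints(integer(0), matrix(0, 0, 3),
                                     numeric(0)), mesh = integer(0)))
  }
  ml <- lapply(meshes, function(m) {
    if (is.null(m$bvh)) m$bvh <- build_bvh(m)
    list(vertices = m$vertices, faces = m$faces, bvh = unclass(m$bvh))
  })
  a0 <- active_first_point(state)
  n <- nrow(state$positions)
  act <- state$positions[a0:n, , drop = FALSE]
  res <- cpp_mesh_contacts(act, act, rod_radius, ml)
  df <- data.frame(point_index = as.integer(res$point_index) + a0 - 1L,
                   nx = res$nx, ny = res$ny, nz = res$nz,
                   depth = res$depth,
                   mu = rep_len(mu, length(res$point_index)),
                   mesh = as.integer(res$mesh))
  df[order(df$point_index, df$mesh), , drop = FALSE]
}

#' Region-of-interest mesh filter
#'
#' Keeps only meshes reachable by the endoscope: those whose AABB intersects
#' the closed sphere centred at the entry port with radius equal to the
#' remaining insertable length.
#'
#' @param meshes List of `tri_mesh` objects.
#' @param port_position Entry port position (3-vector).
#' @param remaining_insertable_length Reach radius, m.
#' @return The subset of `meshes` within reach (boundary contact counts as
#'   reachable).
#' @export
roi_filter <- function(meshes, port_position, remaining_insertable_length) {
  keep <- vapply(meshes, function(m) {
    bb <- mesh_aabb(m)
    d <- pmax(bb$min - port_position, 0, port_position - bb$max)
    sqrt(sum(d^2)) <= remaining_insertable_length
  }, logical(1))
  meshes[keep]
}

#' Read a Wavefront OBJ triangle mesh
#'
#' Minimal OBJ support: `v` and `f` records, polygonal faces fan-triangulated,
#' `v/vt/vn` index syntax accepted, coordinates in metres.
#'
#' @param path File path.
#' @param name Mesh label; defaults to the file name.
#' @return A `tri_mesh`.
#' @export
read_obj <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v[[:space:]]", lines, value = TRUE)
  flines <- grep("^f[[:space:]]", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)),
                                          "[[:space:]]+"), function(x) {
    as.numeric(x[1:3])
  }))
  faces <- do.call(rbind, lapply(flines, function(l) {
    toks <- strsplit(trimws(sub("^f", "", l)), "[[:space:]]+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1))
    if (length(idx) < 3) stop("OBJ face with fewer than 3 vertices")
    # fan triangulation of polygons
    do.call(rbind, lapply(seq_len(length(idx) - 2), function(k) {
      c(idx[1], idx[k + 1], idx[k + 2])
    }))
  }))
  tri_mesh(verts, faces, name = name)
}

#' Write a Wavefront OBJ triangle mesh
#'
#' @param mesh A `tri_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read an STL triangle mesh (ASCII or binary)
#'
#' Vertices are merged exactly (bitwise equality) so shared edges are
#' recovered; coordinates in metres.
#'
#' @param path File path.
#' @param name Mesh label; defaults to the file name.
#' @return A `tri_mesh`.
#' @export
read_stl <- function(path, name = basename(path)) {
  head_raw <- readBin(path, "raw", n = 80)
  is_ascii <- identical(rawToChar(head_raw[1:5]), "solid") &&
    length(grep("facet", readLines(path, n = 20, warn = FALSE))) > 0
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^[[:space:]]*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"),
                                    function(x) as.numeric(x[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    coords <- matrix(NA_real_, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      coords[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      invisible(readBin(con, "raw", n = 2))
    }
  }
  key <- apply(coords, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces, name = name)
}
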