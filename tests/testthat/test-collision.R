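# AABB BVH construction, refit, queries, narrow phase, contacts, ROI.

test_that("BVH construction partitions faces and bounds them", {
  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  rbind(c(1, 2, 3)))
  b1 <- build_bvh(tri)
  expect_equal(as.numeric(b1$node_min[1, ]), c(0, 0, 0))
  expect_equal(as.numeric(b1$node_max[1, ]), c(1, 1, 0))
  expect_equal(b1$face_order, 1L)

  set.seed(41)
  mesh <- random_mesh(1000)
  bvh <- build_bvh(mesh)
  leaves <- which(bvh$left < 0)
  ids <- unlist(lapply(leaves, function(i) {
    bvh$face_order[(bvh$start[i] + 1):(bvh$start[i] + bvh$count[i])]
  }))
  expect_equal(sort(ids), 1:1000)   # every face in exactly one leaf

  # parent AABBs contain both children
  internal <- which(bvh$left >= 0)
  for (i in internal) {
    for (ch in c(bvh$left[i], bvh$right[i]) + 1) {
      expect_true(all(bvh$node_min[i, ] <= bvh$node_min[ch, ] + 1e-15))
      expect_true(all(bvh$node_max[i, ] >= bvh$node_max[ch, ] - 1e-15))
    }
  }

  # balanced median split keeps the depth logarithmic
  depth <- function(i, d) {
    if (bvh$left[i + 1] < 0) return(d)
    max(depth(bvh$left[i + 1], d + 1), depth(bvh$right[i + 1], d + 1))
  }
  expect_lte(depth(0, 0), ceiling(log2(1000 / bvh$leaf_size)) + 2)

  expect_error(build_bvh(tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))),
               "empty mesh")
})

test_that("refit keeps containment after deformation", {
  set.seed(42)
  mesh <- random_mesh(200)
  bvh <- build_bvh(mesh)

  same <- refit_bvh(bvh, mesh)
  expect_equal(same$node_min, bvh$node_min)
  expect_equal(same$node_max, bvh$node_max)

  # uniform translation translates every box
  mesh_t <- mesh
  mesh_t$vertices <- mesh$vertices +
    matrix(c(0.3, -0.2, 0.1), nrow(mesh$vertices), 3, byrow = TRUE)
  bt <- refit_bvh(bvh, mesh_t)
  expect_equal(bt$node_min, bvh$node_min +
                 matrix(c(0.3, -0.2, 0.1), nrow(bvh$node_min), 3,
                        byrow = TRUE), tolerance = 1e-12)

  # random deformation: brute-force containment check at the leaves
  mesh_d <- mesh
  mesh_d$vertices <- mesh$vertices +
    matrix(stats::runif(length(mesh$vertices), -0.2, 0.2),
           nrow(mesh$vertices), 3)
  bd <- refit_bvh(bvh, mesh_d)
  leaves <- which(bd$left < 0)
  for (i in leaves) {
    ids <- bd$face_order[(bd$start[i] + 1):(bd$start[i] + bd$count[i])]
    vs <- mesh_d$vertices[as.vector(mesh_d$faces[ids, , drop = FALSE]), ,
                          drop = FALSE]
    expect_true(all(apply(vs, 2, min) >= bd$node_min[i, ] - 1e-12))
    expect_true(all(apply(vs, 2, max) <= bd$node_max[i, ] + 1e-12))
  }

  mesh_bad <- mesh
  mesh_bad$faces <- mesh$faces[-1, , drop = FALSE]
  expect_error(refit_bvh(bvh, mesh_bad), "mismatch")
})

test_that("sphere queries never miss a face within the radius", {
  set.seed(43)
  mesh <- random_mesh(300)
  bvh <- build_bvh(mesh)

  bb_lo <- apply(mesh$vertices, 2, min)
  bb_hi <- apply(mesh$vertices, 2, max)
  # far outside the root box
  expect_length(query_sphere(bvh, bb_hi + 10, 0.5), 0)
  # radius beyond the scene diameter returns everything
  expect_equal(query_sphere(bvh, colMeans(mesh$vertices),
                            10 * max(bb_hi - bb_lo)),
               1:nrow(mesh$faces))

  for (k in 1:200) {
    p <- stats::runif(3, bb_lo - 0.2, bb_hi + 0.2)
    r <- stats::runif(1, 0.01, 0.5)
    cand <- query_sphere(bvh, p, r)
    truth <- which(brute_force_face_distances(mesh, p) <= r)
    expect_true(all(truth %in% cand))
  }
})

test_that("closest point on triangle is exact in all regions", {
  a <- c(0, 0, 0); b <- c(1, 0, 0); c_ <- c(0, 1, 0)

  inside <- closest_point_triangle(c(0.2, 0.2, 0), a, b, c_)
  expect_equal(inside$point, c(0.2, 0.2, 0))
  expect_equal(inside$distance, 0)

  centroid <- (a + b + c_) / 3
  above <- closest_point_triangle(centroid + c(0, 0, 0.7), a, b, c_)
  expect_equal(above$point, centroid, tolerance = 1e-12)
  expect_equal(above$distance, 0.7)

  beyond <- closest_point_triangle(c(2, -1, 0.5), a, b, c_)
  expect_equal(beyond$point, b)

  # randomized cross-check against dense barycentric sampling
  set.seed(44)
  u <- seq(0, 1, length.out = 100)
  grid <- expand.grid(u = u, v = u)
  grid <- grid[grid$u + grid$v <= 1, ]
  for (k in 1:20) {
    p <- stats::rnorm(3)
    res <- closest_point_triangle(p, a, b, c_)
    samp <- cbind(grid$u, grid$v) %*% rbind(b - a, c_ - a)
    samp <- sweep(samp, 2, -a)
    dmin <- min(sqrt(rowSums(sweep(samp, 2, p)^2)))
    expect_lte(res$distance, dmin + 1e-9)
  }

  expect_error(closest_point_triangle(c(0, 0, 0), a, b, a + (b - a) * 0.5),
               "degenerate")
})

test_that("rod contacts match the brute-force narrow phase", {
  p <- rod_parameters(n_points = 12, rest_length = 0.01, radius = 0.004,
                      point_mass = 1e-3, young_modulus = 1e6,
                      shear_modulus = 5e5)
  st <- straight_rod_state(p, origin = c(10, 10, 10))
  set.seed(45)
  mesh <- random_mesh(500, scale = 0.06)

  # far from everything: no contacts
  far <- generate_rod_contacts(st, list(mesh), p$radius)
  expect_equal(nrow(far), 0)

  # point hovering above a large flat triangle: plane-distance contact
  flat <- tri_mesh(rbind(c(-1, -1, 0), c(1, -1, 0), c(0, 2, 0)),
                   rbind(c(1, 2, 3)))
  st2 <- st
  st2$positions[5, ] <- c(0, 0, 0.002)  # radius/2 above the plane
  con <- generate_rod_contacts(st2, list(flat), p$radius)
  expect_equal(nrow(con), 1)
  expect_equal(con$point_index, 5L)
  expect_equal(con$depth, 0.002, tolerance = 1e-12)
  expect_equal(c(con$nx, con$ny, con$nz), c(0, 0, 1), tolerance = 1e-12)

  # randomized rod inside the soup: contact set equals brute force
  st3 <- st
  st3$positions <- matrix(stats::runif(36, -0.06, 0.06), 12, 3)
  con3 <- generate_rod_contacts(st3, list(mesh), p$radius)
  for (i in 1:12) {
    dmin <- min(brute_force_face_distances(mesh, st3$positions[i, ]))
    if (dmin < p$radius) {
      row <- con3[con3$point_index == i, ]
      expect_equal(nrow(row), 1)
      expect_equal(row$depth, p$radius - dmin, tolerance = 1e-9)
    } else {
      expect_false(i %in% con3$point_index)
    }
  }
})

test_that("region-of-interest filter keeps exactly the reachable meshes", {
  near <- tri_mesh(rbind(c(0.1, 0, 0), c(0.2, 0, 0), c(0.1, 0.1, 0)),
                   rbind(c(1, 2, 3)), name = "near")
  far <- tri_mesh(rbind(c(5, 0, 0), c(5.1, 0, 0), c(5, 0.1, 0)),
                  rbind(c(1, 2, 3)), name = "far")
  # AABB just touching the reach sphere (closed-sphere convention)
  touch <- tri_mesh(rbind(c(1, 0, 0), c(1.1, 0, 0), c(1, 0.1, 0)),
                    rbind(c(1, 2, 3)), name = "touch")
  kept <- roi_filter(list(near, far, touch), c(0, 0, 0), 1)
  expect_equal(vapply(kept, function(m) m$name, ""), c("near", "touch"))
  all_in <- roi_filter(list(near, far), c(0, 0, 0), 100)
  expect_length(all_in, 2)
})

test_that("OBJ and STL round trips preserve the mesh", {
  set.seed(46)
  mesh <- random_mesh(20)
  path <- tempfile(fileext = ".obj")
  write_obj(mesh, path)
  back <- read_obj(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$faces, mesh$faces, ignore_attr = TRUE)

  # minimal ASCII STL
  stl <- tempfile(fileext = ".stl")
  writeLines(c(
    "solid demo",
    " facet normal 0 0 1",
    "  outer loop",
    "   vertex 0 0 0", "   vertex 1 0 0", "   vertex 0 1 0",
    "  endloop", " endfacet",
    " facet normal 0 0 1",
    "  outer loop",
    "   vertex 1 0 0", "   vertex 1 1 0", "   vertex 0 1 0",
    "  endloop", " endfacet",
    "endsolid demo"), stl)
  ms <- read_stl(stl)
  expect_equal(nrow(ms$vertices), 4)  # shared vertices merged
  expect_equal(nrow(ms$faces), 2)
})
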