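test_that("icosphere has the expected combinatorics and geometry", {
  m0 <- make_icosphere(c(0, 0, 0), 1, 0)
  expect_identical(nrow(m0$vertices), 12L)
  expect_identical(nrow(m0$faces), 20L)
  expect_identical(nrow(activemesh:::mesh_edges(m0)), 30L)

  for (s in 0:2) {
    m <- make_icosphere(c(1, -2, 3), 2.5, s)
    expect_identical(nrow(m$faces), as.integer(20 * 4^s))
    expect_closed_genus0(m)
    r <- sqrt(rowSums(sweep(m$vertices, 2, c(1, -2, 3))^2))
    expect_lt(max(abs(r - 2.5)), 1e-12)
  }
  expect_error(make_icosphere(c(0, 0, 0), -1, 1), "positive")
})

test_that("vertex normals are unit, outward, and match face-average oracle", {
  m <- make_icosphere(c(5, 5, 5), 2, 2)
  n <- vertex_normals(m)
  expect_equal(sqrt(rowSums(n^2)), rep(1, nrow(n)), tolerance = 1e-12)
  radial <- sweep(m$vertices, 2, c(5, 5, 5))
  radial <- radial / sqrt(rowSums(radial^2))
  expect_gt(min(rowSums(n * radial)), 0.99)

  # axis-aligned box: corner normals match an independent average of
  # incident face unit normals, and align with the corner diagonal
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5),   # x = 0
    c(2, 8, 4), c(2, 6, 8),   # x = 1
    c(1, 5, 6), c(1, 6, 2),   # y = 0
    c(3, 4, 8), c(3, 8, 7),   # y = 1
    c(1, 4, 3), c(1, 2, 4),   # z = 0
    c(5, 7, 8), c(5, 8, 6)    # z = 1
  )
  box <- activemesh:::ensure_outward(tri_mesh(v, f))
  expect_closed_genus0(box)
  n_box <- vertex_normals(box)
  for (vi in seq_len(8)) {
    rows <- which(apply(box$faces, 1, function(fr) vi %in% fr))
    fn <- t(vapply(rows, function(r) {
      a <- box$vertices[box$faces[r, 1], ]
      e1 <- box$vertices[box$faces[r, 2], ] - a
      e2 <- box$vertices[box$faces[r, 3], ] - a
      cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      cr / sqrt(sum(cr^2))
    }, numeric(3)))
    expected <- colSums(fn)
    expected <- expected / sqrt(sum(expected^2))
    expect_equal(unname(n_box[vi, ]), unname(expected), tolerance = 1e-12)
    diag_dir <- sign(box$vertices[vi, ] - 0.5) / sqrt(3)
    expect_gt(sum(n_box[vi, ] * diag_dir), 0.9)
  }
})

test_that("raycasting from a single sphere reproduces the sphere", {
  ss <- sphere_set(c(2, 3, 4), 1.5)
  m <- raycast_from_spheres(ss, 2)
  expect_closed_genus0(m)
  r <- sqrt(rowSums(sweep(m$vertices, 2, c(2, 3, 4))^2))
  expect_lt(max(abs(r - 1.5)), 1e-9)
})

test_that("raycasting from sphere unions matches the closed-form oracle", {
  # worked two-sphere case: radius r, centers 1.5 r apart; the on-axis
  # vertex sits at 1.5 r / 2 + r from the mid-centroid (0.75 r, 0, 0), so
  # the union extends to x = 2.5 r on one side and x = -r on the other
  r <- 2
  ss <- sphere_set(rbind(c(0, 0, 0), c(1.5 * r, 0, 0)), c(r, r))
  m <- raycast_from_spheres(ss, 3)
  expect_closed_genus0(m)
  expect_equal(max(m$vertices[, 1]) - 0.75 * r, 1.5 * r / 2 + r,
               tolerance = 1e-9)
  expect_equal(max(m$vertices[, 1]), 2.5 * r, tolerance = 1e-9)
  expect_equal(min(m$vertices[, 1]), -r, tolerance = 1e-9)

  set.seed(42)
  for (case in 1:100) {
    k <- sample(1:3, 1)
    centers <- matrix(runif(3 * k, -1, 1), ncol = 3)
    centers[1, ] <- 0            # keep the centroid inside sphere 1
    radii <- runif(k, 1.5, 2.5)  # radii large enough to stay connected
    ss <- try(sphere_set(centers, radii), silent = TRUE)
    if (inherits(ss, "try-error")) next
    m <- raycast_from_spheres(ss, 1)
    c0 <- colMeans(centers)
    for (vi in seq_len(nrow(m$vertices))) {
      d <- m$vertices[vi, ] - c0
      t_impl <- sqrt(sum(d^2))
      t_oracle <- ray_union_exit_oracle(c0, d / t_impl, centers, radii)
      expect_lt(abs(t_impl - t_oracle), 1e-6)
    }
  }
})

test_that("raycasting from sphere sets rejects invalid geometry", {
  expect_error(sphere_set(rbind(c(0, 0, 0), c(10, 0, 0)), c(1, 1)),
               "not connected")
  # centroid of centers outside every sphere
  ss <- structure(list(centers = rbind(c(-3, 0, 0), c(3, 0, 0)),
                       radii = c(2.9, 2.9)), class = "sphere_set")
  expect_error(raycast_from_spheres(ss), "outside the union")
})

test_that("raycasting from a voxel region lands on the region surface", {
  reg <- volume(ball_mask(28, 10), 1)
  m <- raycast_from_region(reg, 2)
  expect_closed_genus0(m)
  r <- sqrt(rowSums(sweep(m$vertices, 2, rep(13.5, 3))^2))
  expect_gte(mean(r), 9)
  expect_lte(mean(r), 11)

  # round trip: the mesh recovers at least 90% of the region
  bv <- binarize(m, reg)
  expect_gte(sum(bv$data == 1 & reg$data) / sum(reg$data), 0.9)

  # single-voxel region: all vertices inside that voxel's bounds
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  m1 <- raycast_from_region(volume(one, 1), 1)
  expect_true(all(abs(m1$vertices - 2) <= 0.5 + 1e-9))

  expect_error(raycast_from_region(volume(array(FALSE, c(4, 4, 4)), 1)),
               "empty region")
  # center of mass outside a hollow region
  hollow <- ball_mask(24, 9) & !ball_mask(24, 6)
  expect_error(raycast_from_region(volume(hollow, 1)), "outside the region")
})

test_that("binarize counts voxels inside the surface", {
  g <- volume(array(0, c(28, 28, 28)), 1)
  m <- make_icosphere(rep(13.5, 3), 10, 3)
  count <- sum(binarize(m, g)$data)
  expect_lt(abs(count - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)

  # a mesh smaller than half a voxel centered between voxel centers
  tiny <- make_icosphere(c(5.5, 5.5, 5.5), 0.4, 1)
  expect_identical(sum(binarize(tiny, volume(array(0, c(12, 12, 12)), 1))$data), 0L)

  open_mesh <- tri_mesh(m$vertices, m$faces[-1, , drop = FALSE])
  expect_error(binarize(open_mesh, g), "not closed")
})

test_that("binarize is resolution-consistent", {
  m <- make_icosphere(rep(10, 3), 6, 3)
  v1 <- sum(binarize(m, volume(array(0, c(21, 21, 21)), 1))$data) * 1^3
  v2 <- sum(binarize(m, volume(array(0, c(41, 41, 41)), 0.5))$data) * 0.5^3
  expect_lt(abs(v1 - v2) / v2, 0.02)
})

test_that("bounding boxes are tight and translation-equivariant", {
  m <- make_icosphere(c(2, -1, 4), 3, 2)
  bb <- bounding_box(m)
  expect_equal(unname(bb$min), c(-1, -4, 1), tolerance = 1e-9)
  expect_equal(unname(bb$max), c(5, 2, 7), tolerance = 1e-9)

  tr <- m; tr$vertices <- sweep(tr$vertices, 2, c(1, 2, 3), "+")
  bt <- bounding_box(tr)
  expect_equal(unname(bt$min), unname(bb$min) + c(1, 2, 3), tolerance = 1e-12)
  expect_equal(unname(bt$max), unname(bb$max) + c(1, 2, 3), tolerance = 1e-12)

  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 2, 0), c(0, 1, 3)),
                  rbind(c(1, 2, 3)))
  bb3 <- bounding_box(tri)
  expect_equal(unname(bb3$min), c(0, 0, 0))
  expect_equal(unname(bb3$max), c(1, 2, 3))
})

test_that("remesh conforms edges while preserving topology and volume", {
  m <- make_icosphere(c(0, 0, 0), 5, 2)
  rng <- mesh_edge_range(m)
  same <- remesh(m, rng[1] * 0.9, rng[2] * 1.1)
  expect_identical(same$vertices, m$vertices)

  pulled <- m
  pulled$vertices[1, ] <- pulled$vertices[1, ] * 4  # one vertex 3 l_max out
  out <- remesh(pulled, 0.5, 1.5)
  expect_closed_genus0(out)
  expect_lte(mesh_edge_range(out)[2], 1.5 * 1.001)

  # volume preserved on a conforming-band remesh of a smooth sphere
  fine <- remesh(m, 0.8, 1.6)
  expect_closed_genus0(fine)
  expect_lt(abs(mesh_volume(fine) - mesh_volume(m)) / mesh_volume(m), 0.02)

  expect_error(remesh(m, 2, 1), "l_min < l_max")
})
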