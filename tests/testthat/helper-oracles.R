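# Independent oracles and small fixture builders used across the suite.

# --- fixtures ---------------------------------------------------------------

# digitized ball mask (array) of given radius in voxels, grid n^3, spacing 1
ball_mask <- function(n, radius, center = rep((n - 1) / 2, 3)) {
  ax <- 0:(n - 1)
  d2 <- outer(outer((ax - center[3])^2, (ax - center[2])^2, "+"),
              (ax - center[1])^2, "+")
  array(d2 <= radius^2, c(n, n, n))
}

# blurred solid ball intensity volume
ball_volume <- function(n, radius, blur_sigma = 1.5) {
  m <- array(as.numeric(ball_mask(n, radius)), c(n, n, n))
  if (blur_sigma > 0)
    m <- array(activemesh:::cpp_gaussian_blur3d(m, rep(as.integer(n), 3),
                                                rep(blur_sigma, 3)),
               c(n, n, n))
  volume(m, 1)
}

# bright spherical shell intensity volume
shell_volume <- function(n, radius, thickness = 1, blur_sigma = 1.5) {
  ax <- 0:(n - 1); c0 <- (n - 1) / 2
  r <- sqrt(outer(outer((ax - c0)^2, (ax - c0)^2, "+"), (ax - c0)^2, "+"))
  m <- array(as.numeric(abs(r - radius) <= thickness), c(n, n, n))
  if (blur_sigma > 0)
    m <- array(activemesh:::cpp_gaussian_blur3d(m, rep(as.integer(n), 3),
                                                rep(blur_sigma, 3)),
               c(n, n, n))
  volume(m, 1)
}

# random blob mask: union of a few random balls, guaranteed non-empty
random_blob <- function(n, n_balls = 3, seed = 1) {
  set.seed(seed)
  m <- array(FALSE, c(n, n, n))
  for (b in seq_len(n_balls)) {
    ctr <- runif(3, n * 0.25, n * 0.75)
    rad <- runif(1, n * 0.08, n * 0.25)
    m <- m | ball_mask(n, rad, ctr)
  }
  m
}

# --- oracles ----------------------------------------------------------------

# one 6-connected erosion step (outside the grid counts as background)
erode6_once <- function(mask) {
  d <- dim(mask)
  sh <- function(a, ax, s) {
    out <- array(FALSE, d)
    if (ax == 1) { if (s > 0) out[2:d[1], , ] <- a[1:(d[1] - 1), , ]
                   else out[1:(d[1] - 1), , ] <- a[2:d[1], , ] }
    if (ax == 2) { if (s > 0) out[, 2:d[2], ] <- a[, 1:(d[2] - 1), ]
                   else out[, 1:(d[2] - 1), ] <- a[, 2:d[2], ] }
    if (ax == 3) { if (s > 0) out[, , 2:d[3]] <- a[, , 1:(d[3] - 1)]
                   else out[, , 1:(d[3] - 1)] <- a[, , 2:d[3]] }
    out
  }
  mask & sh(mask, 1, 1) & sh(mask, 1, -1) & sh(mask, 2, 1) &
    sh(mask, 2, -1) & sh(mask, 3, 1) & sh(mask, 3, -1)
}

# brute-force erosion-depth distance transform (border = depth 0)
dt_oracle <- function(mask, cap = 32L) {
  depth <- array(0L, dim(mask))
  cur <- mask
  k <- 0L
  while (any(cur)) {
    if (k >= cap) { depth[cur] <- cap; break }
    nxt <- erode6_once(cur)
    depth[cur & !nxt] <- k
    cur <- nxt
    k <- k + 1L
  }
  depth[!mask] <- 0L
  depth
}

# all-pairs brute-force best JI per ground-truth label
best_ji_oracle <- function(gt_arr, pred_arr) {
  glabs <- sort(unique(gt_arr[gt_arr > 0]))
  plabs <- sort(unique(pred_arr[pred_arr > 0]))
  vapply(glabs, function(g) {
    Ti <- gt_arr == g
    if (!length(plabs)) return(0)
    max(vapply(plabs, function(p) {
      Pj <- pred_arr == p
      sum(Ti & Pj) / sum(Ti | Pj)
    }, numeric(1)))
  }, numeric(1))
}

# farthest intersection of a ray (origin o, unit dir d) with a union of
# spheres, by independent closed-form root finding
ray_union_exit_oracle <- function(o, d, centers, radii) {
  tmax <- 0
  for (s in seq_len(nrow(centers))) {
    m <- centers[s, ] - o
    b <- sum(d * m)
    disc <- b^2 - (sum(m^2) - radii[s]^2)
    if (disc >= 0) tmax <- max(tmax, b + sqrt(disc))
  }
  tmax
}

# mean edge length helpers
mesh_edge_range <- function(mesh) {
  e <- activemesh:::mesh_edges(mesh)
  range(activemesh:::edge_lengths(mesh$vertices, e))
}

expect_closed_genus0 <- function(mesh) {
  expect_true(activemesh:::is_closed_mesh(mesh))
  e <- activemesh:::mesh_edges(mesh)
  expect_identical(nrow(mesh$vertices) - nrow(e) + nrow(mesh$faces), 2L)
  expect_gt(mesh_volume(mesh), 0)
}

# small noiseless phantom used by several tests
noiseless_phantom <- function(n_cells = 5, n = 96, seed = 1) {
  generate_frame(phantom_spec(
    n_cells = n_cells, dims = rep(as.integer(n), 3),
    aggregate_radius = 7 * n_cells^(1 / 3),
    psf_sigma_px = 0, noise_gaussian_sd = 0, noise_poisson_scale = 0,
    seed = seed))
}
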