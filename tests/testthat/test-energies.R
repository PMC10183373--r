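test_that("derivative-of-Gaussian kernel matches its closed form", {
  k <- gaussian_derivative_kernel(2, 5)
  expect_identical(k$k[k$offsets == 0], 0)
  expect_equal(k$k[k$offsets < 0], -rev(k$k[k$offsets > 0]), tolerance = 1e-15)
  # independent evaluation of the closed form at sigma = 2, w = 5
  for (i in -5:5)
    expect_equal(k$k[k$offsets == i],
                 -i / (sqrt(2 * pi) * 8) * exp(-i^2 / 8), tolerance = 1e-15)
  expect_gt(sum(abs(k$k)), 0)
  expect_error(gaussian_derivative_kernel(-1), "positive")
  expect_error(gaussian_derivative_kernel(2, 0), "w must")
})

test_that("trilinear sampling is exact on voxel centers, midpoints and ramps", {
  set.seed(3)
  arr <- array(runif(5 * 6 * 7), c(5, 6, 7))
  I <- volume(arr, c(0.5, 1, 2))
  # voxel centers
  expect_equal(sample_intensity(I, c(2 * 2, 1 * 3, 0.5 * 1)), arr[2, 4, 3])
  # midpoint along x: arithmetic mean of the two centers
  expect_equal(sample_intensity(I, c(2 * 2 + 1, 1 * 3, 0.5)),
               (arr[2, 4, 3] + arr[2, 4, 4]) / 2)
  # linear ramp is reproduced exactly everywhere inside
  ramp <- volume(outer(outer(rep(1, 8), rep(1, 8)), 0:7) * 1.5, 1)
  pts <- cbind(runif(50, 0, 7), runif(50, 0, 7), runif(50, 0, 7))
  expect_equal(sample_intensity(ramp, pts), 1.5 * pts[, 1], tolerance = 1e-12)
  # clamping outside the grid
  expect_equal(sample_intensity(ramp, c(100, 3, 3)), 1.5 * 7)
})

test_that("gradient energy localizes a step edge and is never positive", {
  uni <- volume(array(7, c(16, 16, 16)), 1)
  n <- rbind(c(1, 0, 0))
  expect_equal(perpendicular_gradient_energy(uni, c(8, 8, 8), n), 0)

  # step edge at x = 8.5 (half-way between voxel centers 8 and 9)
  step <- array(0, c(20, 20, 20)); step[, , 10:20] <- 1
  I <- volume(step, 1)
  xs <- seq(4, 14, by = 0.5)
  E <- perpendicular_gradient_energy(I, cbind(xs, 9, 9),
                                     matrix(c(1, 0, 0), length(xs), 3,
                                            byrow = TRUE))
  expect_true(all(E <= 0))
  expect_lt(abs(xs[which.min(E)] - 8.5), 0.5 + 1e-9)

  set.seed(4)
  noisy <- volume(array(runif(16^3), c(16, 16, 16)), 1)
  pts <- cbind(runif(20, 3, 13), runif(20, 3, 13), runif(20, 3, 13))
  nn <- matrix(rnorm(60), 20, 3); nn <- nn / sqrt(rowSums(nn^2))
  expect_true(all(perpendicular_gradient_energy(noisy, pts, nn) <= 0))
})

test_that("gradient-energy force pulls a node onto a bright ball's edge", {
  uni <- volume(array(3, c(16, 16, 16)), 1)
  p <- deform_params(w_img = 1)
  expect_equal(gradient_energy_force(uni, c(8, 8, 8), rbind(c(0, 0, 1)), p),
               matrix(0, 1, 3))

  I <- ball_volume(32, 10)
  ctr <- rep(15.5, 3)
  x_in <- ctr + c(8, 0, 0)         # just inside the edge at radius 10
  n_out <- rbind(c(1, 0, 0))
  f <- gradient_energy_force(I, x_in, n_out, p)
  expect_gt(sum(f * n_out), 0)     # pulled outward, toward the edge
  # force is parallel to the normal
  expect_lt(abs(f[2]), 1e-12); expect_lt(abs(f[3]), 1e-12)
  # linear in w_img
  p2 <- deform_params(w_img = -1)
  expect_equal(gradient_energy_force(I, x_in, n_out, p2), -f,
               tolerance = 1e-12)
})

test_that("intensity energy is the negated smoothed mean along the normal", {
  uni <- volume(array(4.5, c(12, 12, 12)), 1)
  expect_equal(perpendicular_intensity_energy(uni, c(6, 6, 6),
                                              rbind(c(0, 1, 0))), -4.5)
  # bright plane: energy minimal on the plane among half-pixel offsets
  pl <- array(0, c(20, 20, 20)); pl[, , 10] <- 1  # plane at x = 9
  I <- volume(pl, 1)
  xs <- seq(5, 13, by = 0.5)
  E <- perpendicular_intensity_energy(I, cbind(xs, 9, 9),
                                      matrix(c(1, 0, 0), length(xs), 3,
                                             byrow = TRUE))
  expect_equal(xs[which.min(E)], 9)
  # linearity in the intensity
  I2 <- volume(2 * pl, 1)
  E2 <- perpendicular_intensity_energy(I2, cbind(xs, 9, 9),
                                       matrix(c(1, 0, 0), length(xs), 3,
                                              byrow = TRUE))
  expect_equal(E2, 2 * E, tolerance = 1e-12)
})

test_that("intensity force climbs toward bright planes and flips with w_img", {
  uni <- volume(array(2, c(12, 12, 12)), 1)
  p <- deform_params(w_img = 1)
  expect_equal(intensity_force(uni, c(6, 6, 6), rbind(c(1, 0, 0)), p),
               matrix(0, 1, 3))

  pl <- array(0, c(20, 20, 20)); pl[, , 12] <- 1  # bright plane at x = 11
  I <- volume(pl, 1)
  x <- c(9, 9, 9)                  # 2 px below the plane
  n <- rbind(c(1, 0, 0))           # normal toward the plane
  f <- intensity_force(I, x, n, p)
  expect_gt(sum(f * n), 0)
  expect_lt(abs(f[2]) + abs(f[3]), 1e-12)
  # reversing the normal on a ramp reverses the direction of travel:
  # the force must still point up the ramp
  ramp <- volume(outer(outer(rep(1, 16), rep(1, 16)), 0:15) * 1.0, 1)
  f_up <- intensity_force(ramp, c(7, 7, 7), rbind(c(1, 0, 0)), p)
  f_dn <- intensity_force(ramp, c(7, 7, 7), rbind(c(-1, 0, 0)), p)
  expect_gt(f_up[1], 0)
  expect_gt(f_dn[1], 0)            # -n with negative magnitude: still +x
  expect_equal(f_up, f_dn, tolerance = 1e-12)
  # negative weight descends
  pneg <- deform_params(w_img = -1)
  expect_equal(intensity_force(I, x, n, pneg), -f, tolerance = 1e-12)
})

test_that("image forces stay parallel to the supplied normal", {
  set.seed(5)
  I <- volume(array(runif(18^3), c(18, 18, 18)), 1)
  p <- deform_params(w_img = 2)
  pts <- cbind(runif(30, 4, 14), runif(30, 4, 14), runif(30, 4, 14))
  nn <- matrix(rnorm(90), 30, 3); nn <- nn / sqrt(rowSums(nn^2))
  for (fn in list(gradient_energy_force, intensity_force)) {
    f <- fn(I, pts, nn, p)
    cross_mag <- abs(f[, 1] * nn[, 2] - f[, 2] * nn[, 1]) +
      abs(f[, 2] * nn[, 3] - f[, 3] * nn[, 2]) +
      abs(f[, 1] * nn[, 3] - f[, 3] * nn[, 1])
    expect_lt(max(cross_mag), 1e-12)
  }
})

test_that("intrinsic forces vanish on flat patches and in translation", {
  m <- make_icosphere(c(0, 0, 0), 3, 2)
  expect_equal(intrinsic_forces(m, 0, 0), matrix(0, nrow(m$vertices), 3))

  f1 <- intrinsic_forces(m, 0.7, 0.3)
  m2 <- m; m2$vertices <- sweep(m2$vertices, 2, c(10, -4, 2), "+")
  expect_equal(intrinsic_forces(m2, 0.7, 0.3), f1, tolerance = 1e-9)

  # a vertex whose neighbours average to itself feels no first-order force:
  # pyramid-free flat octahedron equator point test via a linear position
  # field x' = A x keeps L(x') = A L(x), so forces stay parallel
  A <- diag(c(2, 0.5, 1))
  m3 <- m; m3$vertices <- m$vertices %*% A
  expect_equal(intrinsic_forces(m3, 1, 0), intrinsic_forces(m, 1, 0) %*% A,
               tolerance = 1e-9)
})

test_that("a free mesh under alpha shrinks monotonically", {
  m <- make_icosphere(c(0, 0, 0), 5, 1)
  vols <- numeric(100)
  for (i in 1:100) {
    f <- intrinsic_forces(m, 0.5, 0)
    m$vertices <- m$vertices + 0.5 * f
    vols[i] <- mesh_volume(m)
  }
  expect_true(all(diff(c(mesh_volume(make_icosphere(c(0, 0, 0), 5, 1)),
                         vols)) < 0))
})

test_that("finite-difference force converges to the analytic energy gradient", {
  kern <- gaussian_derivative_kernel(2, 5)
  Kn <- sum(abs(kern$k))
  # closed-form energy of a 1D Gaussian blob profile along the normal
  S <- function(x, c0, s) sum(kern$k * exp(-(x + kern$offsets - c0)^2 /
                                             (2 * s^2)))
  Sp <- function(x, c0, s) sum(kern$k * (-(x + kern$offsets - c0) / s^2) *
                                 exp(-(x + kern$offsets - c0)^2 / (2 * s^2)))
  E_true <- function(x, c0, s) -(S(x, c0, s) / Kn)^2
  dE_true <- function(x, c0, s) -2 * S(x, c0, s) * Sp(x, c0, s) / Kn^2

  # the implemented energy equals the closed form when samples land on
  # voxel centers (trilinear is exact there)
  n <- 65; c0 <- 32; s <- 5
  ax <- 0:(n - 1)
  blob <- exp(-outer(outer((ax - c0)^2, (ax - c0)^2, "+"),
                     (ax - c0)^2, "+") / (2 * s^2))
  I <- volume(blob, 1)
  for (x0 in c(c0 + 3, c0 + 5, c0 + 8))
    expect_equal(
      perpendicular_gradient_energy(I, c(x0, c0, c0), rbind(c(1, 0, 0)), kern),
      E_true(x0, c0, s), tolerance = 1e-10)

  # the unit-step central difference of the closed-form energy converges to
  # its analytic derivative as the blob gets smoother
  # evaluate on the energy's slope (x = c0 + 1.6 s); at x = c0 + s the
  # energy is near its extremum and the relative error is ill-defined
  rel_err <- vapply(c(3, 6, 12), function(s) {
    x0 <- c0 + 1.6 * s
    cd <- (E_true(x0 + 1, c0, s) - E_true(x0 - 1, c0, s)) / 2
    abs(cd - dE_true(x0, c0, s)) / abs(dE_true(x0, c0, s))
  }, numeric(1))
  expect_lt(rel_err[2], rel_err[1])
  expect_lt(rel_err[3], rel_err[2])
  expect_lt(rel_err[3], 0.01)
})

test_that("integrating the intensity force recovers the energy drop", {
  n <- 48
  ax <- 0:(n - 1); c0 <- (n - 1) / 2
  blob <- exp(-outer(outer((ax - c0)^2, (ax - c0)^2, "+"),
                     (ax - c0)^2, "+") / (2 * 5^2))
  I <- volume(blob, 1)
  p <- deform_params(w_img = 1, sigma = 2, w = 5)
  nvec <- rbind(c(1, 0, 0))
  a <- c(c0 - 8, c0, c0); b <- c(c0, c0, c0)
  h <- 0.02
  xs <- seq(a[1], b[1], by = h)
  fs <- intensity_force(I, cbind(xs, c0, c0),
                        matrix(c(1, 0, 0), length(xs), 3, byrow = TRUE), p)[, 1]
  work <- sum((fs[-1] + fs[-length(fs)]) / 2 * h)
  Ea <- perpendicular_intensity_energy(I, a, nvec, p$kernel$sigma, p$kernel$w)
  Eb <- perpendicular_intensity_energy(I, b, nvec, p$kernel$sigma, p$kernel$w)
  # the force taps are the derivative of the energy's Gaussian taps up to
  # the factor C below (k_i = g'_i / (sqrt(2 pi) sigma), and the energy
  # normalizes by sum(g) while the force normalizes by sum(|k|)):
  # F = -w C dE/dn, so the integrated force must equal -w C (E(b) - E(a))
  g <- exp(-(-p$kernel$w:p$kernel$w)^2 / (2 * p$kernel$sigma^2))
  C <- sum(g) / (sqrt(2 * pi) * p$kernel$sigma * sum(abs(p$kernel$k)))
  expect_equal(work, -p$w_img * C * (Eb - Ea),
               tolerance = 0.05 * abs(C * (Eb - Ea)))
})
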