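#' Derivative-of-Gaussian sampling kernel
#'
#' One-dimensional kernel whose taps `k_i = -i / (sqrt(2*pi) * sigma^3) *
#' exp(-i^2 / (2*sigma^2))`, for integer offsets `i` in `[-w, w]`, estimate
#' the intensity derivative along a mesh normal. Antisymmetric with
#' `k_0 = 0`; the energies normalise by `sum(|k_i|)`, so any positive
#' prefactor cancels and only the kernel shape matters.
#'
#' @param sigma kernel standard deviation in pixels (default 2).
#' @param w half-width in pixels (default 5).
#' @return An object of class `kernel_spec` with elements `sigma`, `w`,
#'   `offsets` and `k`.
#' @export
gaussian_derivative_kernel <- function(sigma = 2, w = 5L) {
  if (sigma <= 0) stop("sigma must be positive")
  if (w < 1) stop("w must be >= 1")
  i <- seq.int(-w, w)
  k <- -i / (sqrt(2 * pi) * sigma^3) * exp(-i^2 / (2 * sigma^2))
  structure(list(sigma = sigma, w = as.integer(w), offsets = i, k = k),
            class = "kernel_spec")
}

#' Mesh deformation parameters
#'
#' @param alpha weight of the first-order intrinsic (area/stretch) force;
#'   positive values make a free mesh shrink and smooth.
#' @param beta weight of the second-order intrinsic (bending) force.
#' @param w_img signed weight of the image force relative to the intrinsic
#'   forces; the sign selects climbing toward bright structures (`> 0`) or
#'   descending toward dark ones (`< 0`).
#' @param sigma,w derivative-of-Gaussian kernel parameters in pixels.
#' @param max_iters iteration cap for the deformation loop.
#' @param step_size explicit-Euler step (dimensionless force multiplier).
#' @param tol convergence tolerance: maximum per-vertex displacement (µm)
#'   that must be sustained over a 10-iteration window.
#' @param remesh_every remesh cadence in iterations (0 disables remeshing).
#' @param l_min,l_max remeshing edge-length band in pixels (converted to µm
#'   via the smallest spacing of the target volume).
#' @param steric_strength weight of the repulsive force between meshes.
#' @param max_step_px cap on per-vertex displacement per iteration, in pixels.
#' @return An object of class `deform_params`.
#' @export
deform_params <- function(alpha = 0.1, beta = 0, w_img = 1,
                          sigma = 2, w = 5L,
                          max_iters = 1000L, step_size = 0.1, tol = 0.01,
                          remesh_every = 50L, l_min = 1, l_max = 3,
                          steric_strength = 1, max_step_px = 0.5) {
  if (max_iters <= 0) stop("max_iters must be positive")
  if (tol <= 0) stop("tol must be positive")
  structure(list(alpha = alpha, beta = beta, w_img = w_img,
                 kernel = gaussian_derivative_kernel(sigma, w),
                 max_iters = as.integer(max_iters), step_size = step_size,
                 tol = tol, remesh_every = as.integer(remesh_every),
                 l_min = l_min, l_max = l_max,
                 steric_strength = steric_strength,
                 max_step_px = max_step_px),
            class = "deform_params")
}

# sample I at x + i * px * n for all kernel offsets; returns matrix
# (points x offsets)
profile_samples <- function(I, x, n, offsets) {
  x <- rbind(x); n <- rbind(n)
  px <- min(I$spacing)
  np <- nrow(x)
  pts <- do.call(rbind, lapply(offsets, function(i) x + i * px * n))
  vals <- sample_intensity(I, pts)
  matrix(vals, nrow = np, ncol = length(offsets))
}

#' Perpendicular gradient energy
#'
#' Squared directional-derivative estimate of the intensity along a node
#' normal, negated: `E = -( sum_i k_i I(x + i n) / sum_i |k_i| )^2`, with the
#' profile sampled at unit-pixel steps (one pixel = the smallest spacing
#' component) by trilinear interpolation. Always `<= 0`; most negative where
#' the intensity edge is sharpest, which is what attracts nucleus meshes to
#' nuclear boundaries.
#'
#' @param I a [volume].
#' @param x sample point(s), rows of `(x, y, z)` µm.
#' @param n unit normal(s), same shape as `x`.
#' @param kernel a `kernel_spec` from [gaussian_derivative_kernel()].
#' @return numeric vector of energies (one per point).
#' @export
perpendicular_gradient_energy <- function(I, x, n, kernel = gaussian_derivative_kernel()) {
  s <- profile_samples(I, x, n, kernel$offsets)
  -(as.vector(s %*% kernel$k) / sum(abs(kernel$k)))^2
}

#' Finite-difference force of the gradient energy
#'
#' `F = -(w_img / 2) * (E(x + n) - E(x - n)) * n`, the discrete gradient of
#' [perpendicular_gradient_energy()] along the normal (steps of one pixel).
#'
#' @inheritParams perpendicular_gradient_energy
#' @param params a [deform_params] (supplies `w_img` and the kernel).
#' @return matrix of 3-vector forces, one row per point, parallel to `n`.
#' @export
gradient_energy_force <- function(I, x, n, params) {
  x <- rbind(x); n <- rbind(n)
  px <- min(I$spacing)
  ep <- perpendicular_gradient_energy(I, x + px * n, n, params$kernel)
  em <- perpendicular_gradient_energy(I, x - px * n, n, params$kernel)
  n * (-(params$w_img / 2) * (ep - em))
}

#' Perpendicular intensity energy
#'
#' Negated Gaussian-weighted mean intensity along the node normal:
#' `E = -sum_u G_sigma(u) I(x + u n) / sum_u G_sigma(u)` over integer pixel
#' offsets `u` in `[-w, w]`. Most negative on bright sheets (membranes); on a
#' distance-transform volume with a negative image weight the corresponding
#' force drives nodes toward the transform's minima, i.e. object boundaries.
#'
#' @inheritParams perpendicular_gradient_energy
#' @param sigma Gaussian standard deviation in pixels.
#' @param w half-width of the truncated kernel in pixels.
#' @return numeric vector of energies (one per point).
#' @export
perpendicular_intensity_energy <- function(I, x, n, sigma = 2, w = 5L) {
  u <- seq.int(-w, w)
  g <- exp(-u^2 / (2 * sigma^2))
  s <- profile_samples(I, x, n, u)
  -as.vector(s %*% g) / sum(g)
}

#' Intensity force along the normal
#'
#' `F = w_img * ( sum_i k_i I(x - i n) / sum_i |k_i| ) * n`: the convolution
#' of the derivative-of-Gaussian taps with the intensity profile, i.e. the
#' derivative of the Gaussian-smoothed intensity along the normal — the
#' discretised gradient of the perpendicular intensity energy. With
#' `w_img > 0` a node climbs toward bright structures; with `w_img < 0` it
#' descends (on a distance transform: toward the transform's minima at
#' object boundaries).
#'
#' @inheritParams gradient_energy_force
#' @return matrix of 3-vector forces, one row per point, parallel to `n`.
#' @export
intensity_force <- function(I, x, n, params) {
  x <- rbind(x); n <- rbind(n)
  kernel <- params$kernel
  s <- profile_samples(I, x, n, kernel$offsets)
  # convolution (not correlation) of the derivative-of-Gaussian taps with the
  # profile: this is the derivative of the Gaussian-smoothed intensity along
  # n, so a positive weight climbs toward bright structures
  mag <- as.vector(s %*% rev(kernel$k)) / sum(abs(kernel$k))
  n * (params$w_img * mag)
}

# row-normalized adjacency (neighbor mean) operator as a function
neighbor_mean_op <- function(mesh) {
  e <- mesh_edges(mesh)
  from <- c(e[, 1], e[, 2])
  to <- c(e[, 2], e[, 1])
  deg <- tabulate(from, nbins = nrow(mesh$vertices))
  function(x) {
    acc <- rowsum(x[to, , drop = FALSE], from)
    acc / deg
  }
}

#' Intrinsic mesh forces
#'
#' Smoothing/shrinking regularisation `F = -alpha * L(x) - beta * L(L(x))`
#' where `L` is the uniform graph Laplacian of vertex positions
#' (`L(x)_v = x_v - mean(neighbours of v)`). The first-order term penalises
#' surface area (a free mesh shrinks monotonically), the second-order term
#' penalises bending. Translation-invariant by construction.
#'
#' @param mesh a [tri_mesh].
#' @param alpha,beta nonnegative weights.
#' @return matrix of 3-vector forces, one row per vertex.
#' @export
intrinsic_forces <- function(mesh, alpha, beta) {
  if (alpha == 0 && beta == 0)
    return(matrix(0, nrow(mesh$vertices), 3))
  nbm <- neighbor_mean_op(mesh)
  x <- mesh$vertices
  L1 <- x - nbm(x)
  out <- -alpha * L1
  if (beta != 0) out <- out - beta * (L1 - nbm(L1))
  out
}
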