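#' Result of an active-mesh deformation
#'
#' @param mesh final [tri_mesh].
#' @param converged logical: did the per-vertex displacement stay below the
#'   tolerance for a full 10-iteration window.
#' @param iterations_used iterations actually executed.
#' @param final_max_displacement largest per-vertex displacement (µm) in the
#'   last iteration.
#' @return An object of class `deform_result`.
#' @keywords internal
deform_result <- function(mesh, converged, iterations_used,
                          final_max_displacement) {
  structure(list(mesh = mesh, converged = converged,
                 iterations_used = as.integer(iterations_used),
                 final_max_displacement = final_max_displacement,
                 volume = mesh_volume(mesh)),
            class = "deform_result")
}

#' @export
print.deform_result <- function(x, ...) {
  cat(sprintf("deform_result: %s after %d iterations (last max step %.3g um), volume %.4g um^3\n",
              if (x$converged) "converged" else "not converged",
              x$iterations_used, x$final_max_displacement, x$volume))
  invisible(x)
}

#' Repulsive steric forces between meshes
#'
#' Each vertex of `mesh` that lies inside another mesh receives a force along
#' its own outward normal reversed (pushing it back out), with magnitude
#' `strength` times an estimate of the penetration depth (distance to the
#' nearest vertex of the penetrated mesh). Non-penetrating vertices get zero.
#'
#' @param mesh a closed [tri_mesh].
#' @param others list of closed [tri_mesh] neighbours.
#' @param strength force per µm of penetration.
#' @param normals optional precomputed vertex normals of `mesh`.
#' @return matrix of 3-vector forces, one row per vertex of `mesh`.
#' @export
steric_forces <- function(mesh, others, strength = 1, normals = NULL) {
  out <- matrix(0, nrow(mesh$vertices), 3)
  if (!length(others)) return(out)
  if (is.null(normals)) normals <- vertex_normals(mesh)
  v <- mesh$vertices
  for (other in others) {
    # cheap bounding-box prefilter: only vertices inside the other's box
    # can penetrate it
    ob <- bounding_box(other)
    cand <- which(v[, 1] >= ob$min[1] & v[, 1] <= ob$max[1] &
                    v[, 2] >= ob$min[2] & v[, 2] <= ob$max[2] &
                    v[, 3] >= ob$min[3] & v[, 3] <= ob$max[3])
    if (!length(cand)) next
    inside_cand <- points_in_mesh(v[cand, , drop = FALSE], other)
    inside <- rep(FALSE, nrow(v))
    inside[cand[inside_cand]] <- TRUE
    if (!any(inside)) next
    vi <- v[inside, , drop = FALSE]
    ov <- other$vertices
    depth <- vapply(seq_len(nrow(vi)), function(r) {
      sqrt(min(rowSums(sweep(ov, 2, vi[r, ])^2)))
    }, numeric(1))
    out[inside, ] <- out[inside, , drop = FALSE] -
      normals[inside, , drop = FALSE] * (strength * depth)
  }
  out
}

# Penetration-depth field of a set of fixed meshes on a voxel grid:
# erosion depth (in voxels) inside the union, converted to µm, zero outside.
# Sampled trilinearly this gives a smooth repulsion magnitude for vertices
# penetrating a neighbour.
steric_depth_field <- function(others, grid) {
  d <- vol_dims(grid)
  occ <- array(0L, dim = d)
  for (other in others) {
    inside <- cpp_voxelize(other$vertices, other$faces, d, grid$spacing,
                           grid$origin)
    occ[inside] <- 1L
  }
  depth <- array(cpp_erosion_depth(as.integer(occ), d, 100000L), dim = d)
  px <- min(grid$spacing)
  volume(ifelse(depth < 0L, 0, (depth + 0.5) * px), grid$spacing,
         grid$origin)
}

#' Deform a mesh to steady state under image and intrinsic forces
#'
#' Explicit per-vertex Euler updates
#' `x <- x + step_size * (F_img + F_intrinsic + F_steric)` with the image
#' force given by the gradient energy (nuclei on raw intensity) or the
#' intensity energy (membranes, or distance-transform volumes with a
#' negative image weight). Displacements are capped per iteration for
#' stability, the mesh is remeshed on a fixed cadence, and convergence is
#' declared when the maximum per-vertex displacement stays below `params$tol`
#' for 10 consecutive iterations.
#'
#' @param mesh initial closed [tri_mesh].
#' @param I a [volume] (image intensity or distance transform).
#' @param energy_mode `"gradient"` or `"intensity"`.
#' @param params a [deform_params].
#' @param others optional list of neighbouring meshes for steric repulsion.
#' @param v_stop early-exit volume floor (µm³): a mesh that shrinks below it
#'   is reported unconverged immediately (shrinkage indicates there was no
#'   structure to wrap, and flags false-positive seeds).
#' @return a `deform_result`.
#' @export
deform <- function(mesh, I, energy_mode = c("gradient", "intensity"),
                   params = deform_params(), others = NULL, v_stop = 0) {
  energy_mode <- match.arg(energy_mode)
  stopifnot(is_tri_mesh(mesh), is_volume(I), inherits(params, "deform_params"))
  validate_mesh(mesh)
  px <- min(I$spacing)
  cap <- params$max_step_px * px
  steric_field <- if (!is.null(others) && length(others))
    steric_depth_field(others, I)
  window <- numeric(0)
  last_max <- Inf
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(params$max_iters)) {
    iters <- it
    n <- vertex_normals(mesh)
    x <- mesh$vertices
    f_img <- if (params$w_img != 0) {
      if (energy_mode == "gradient") gradient_energy_force(I, x, n, params)
      else intensity_force(I, x, n, params)
    } else matrix(0, nrow(x), 3)
    f_tot <- f_img + intrinsic_forces(mesh, params$alpha, params$beta)
    if (!is.null(steric_field)) {
      pen <- sample_intensity(steric_field, x)
      f_tot <- f_tot - n * (params$steric_strength * pen)
    }
    disp <- params$step_size * f_tot
    dn <- sqrt(rowSums(disp^2))
    over <- dn > cap
    if (any(over)) disp[over, ] <- disp[over, , drop = FALSE] * (cap / dn[over])
    mesh$vertices <- x + disp
    last_max <- max(sqrt(rowSums(disp^2)))
    window <- c(window, last_max)
    if (length(window) > 10L) window <- window[-1L]
    if (length(window) == 10L && max(window) < params$tol) {
      converged <- TRUE
      break
    }
    if (v_stop > 0 && abs(mesh_volume(mesh)) < v_stop) break
    if (params$remesh_every > 0 && it %% params$remesh_every == 0L) {
      res <- try(remesh(mesh, params$l_min * px, params$l_max * px),
                 silent = TRUE)
      if (inherits(res, "try-error"))
        stop("deformation failure at iteration ", it, ": ",
             attr(res, "condition")$message)
      if (!identical(res$faces, mesh$faces)) window <- numeric(0)
      mesh <- res
    }
  }
  deform_result(ensure_outward(mesh), converged, iters, last_max)
}

#' Partition deformation results by minimal volume
#'
#' Meshes that shrank below `v_min` failed to find a structure to wrap: this
#' doubles as the false-positive filter for spurious seeds.
#'
#' @param results list of `deform_result`.
#' @param v_min volume floor in µm³ (default: a 1.5 µm-radius ball).
#' @return list with elements `kept` and `removed` (both lists of
#'   `deform_result`).
#' @export
filter_small <- function(results, v_min = 4 / 3 * pi * 1.5^3) {
  vols <- vapply(results, function(r) r$volume, numeric(1))
  keep <- vols >= v_min
  list(kept = results[keep], removed = results[!keep])
}
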