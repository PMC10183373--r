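# Two-channel 3D(+t) phantoms of cell aggregates with mesh ground truth.
# Nuclei are randomly oriented ellipsoids (so meshes must genuinely deform),
# cells are the Voronoi partition of a ball around the nucleus centers,
# membranes are bright shells on cell-cell and cell-exterior boundaries.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Geometry, optics and noise parameters of the synthetic aggregate
#' generator. Defaults emulate a small organoid imaged at half resolution:
#' a 128^3 grid of 0.35 µm voxels holding about ten tightly packed cells
#' whose nuclei (mean diameter 8 µm) nearly fill them — cell radii run about
#' 1.4x the nucleus radius, as in epithelial aggregates. Keep that ratio
#' when changing `n_cells`: `aggregate_radius ~ 6.5 * n_cells^(1/3)` µm for
#' 4 µm nuclei, or membrane meshes will start far from their basin of
#' attraction on the distance transform.
#'
#' @param n_cells number of cells in the aggregate.
#' @param aggregate_radius aggregate ball radius, µm.
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus mean semi-axis (µm).
#' @param axis_ratio_max maximal ellipsoid axis ratio (>= 1).
#' @param membrane_thickness_px membrane shell thickness in voxels.
#' @param dims volume dimensions `(nz, ny, nx)`.
#' @param spacing voxel spacing, scalar or `(sz, sy, sx)` µm.
#' @param psf_sigma_px Gaussian PSF sigma in voxels (0 = no blur).
#' @param noise_gaussian_sd additive read-noise sigma (image units).
#' @param noise_poisson_scale photon scale for shot noise (0 = off; larger
#'   values mean more photons, hence less relative noise).
#' @param drift_um_per_frame whole-aggregate drift speed, µm/frame.
#' @param jitter_um_sd per-frame per-cell positional jitter sigma, µm.
#' @param divisions data frame with columns `frame`, `cell_id`: scheduled
#'   divisions (the cell splits into two daughters at that frame).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_cells = 10L, aggregate_radius = 14,
                         nucleus_radius_mean = 4, nucleus_radius_sd = 0.3,
                         axis_ratio_max = 1.5, membrane_thickness_px = 1L,
                         dims = c(128L, 128L, 128L), spacing = 0.35,
                         psf_sigma_px = 1, noise_gaussian_sd = 0.02,
                         noise_poisson_scale = 100,
                         drift_um_per_frame = 0.3, jitter_um_sd = 0.02,
                         divisions = NULL, seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(
    n_cells = as.integer(n_cells), aggregate_radius = aggregate_radius,
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    axis_ratio_max = axis_ratio_max,
    membrane_thickness_px = as.integer(membrane_thickness_px),
    dims = as.integer(dims), spacing = as.numeric(spacing),
    psf_sigma_px = psf_sigma_px, noise_gaussian_sd = noise_gaussian_sd,
    noise_poisson_scale = noise_poisson_scale,
    drift_um_per_frame = drift_um_per_frame, jitter_um_sd = jitter_um_sd,
    divisions = divisions, seed = as.integer(seed)
  ), class = "phantom_spec")
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# sample non-overlapping ellipsoidal nuclei inside the aggregate ball
sample_cells <- function(spec, center) {
  n <- spec$n_cells
  d_min <- 2.05 * spec$nucleus_radius_mean
  r_place <- spec$aggregate_radius - 1.1 * spec$nucleus_radius_mean
  if (r_place <= 0) stop("generation error: aggregate too small for nuclei")
  # best-candidate (Mitchell) sampling reaches tighter packings than plain
  # dart throwing, which jams near the density of real aggregates
  centers <- matrix(NA_real_, 0, 3)
  fails <- 0L
  while (nrow(centers) < n) {
    if (fails > 200L)
      stop("generation error: cannot place ", n, " cells at this density")
    best_p <- NULL; best_d <- -1
    for (cand in 1:400) {
      p <- stats::runif(3, -1, 1) * r_place
      if (sum(p^2) > r_place^2) next
      p <- p + center
      dmin <- if (nrow(centers))
        min(sqrt(rowSums(sweep(centers, 2, p)^2))) else Inf
      if (dmin > best_d) { best_d <- dmin; best_p <- p }
    }
    if (best_d < d_min) { fails <- fails + 1L; next }
    centers <- rbind(centers, best_p)
  }
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    r <- max(0.5 * spec$nucleus_radius_mean,
             stats::rnorm(1, spec$nucleus_radius_mean, spec$nucleus_radius_sd))
    q <- stats::runif(1, 1, sqrt(spec$axis_ratio_max))
    axes <- r * c(q, 1, 1 / q)
    # nuclei must stay inside their Voronoi cell and the aggregate
    if (n > 1) {
      nn <- min(sqrt(rowSums(sweep(centers[-i, , drop = FALSE], 2,
                                   centers[i, ])^2)))
      amax <- 0.45 * nn
    } else amax <- Inf
    amax <- min(amax, spec$aggregate_radius -
                  sqrt(sum((centers[i, ] - center)^2)) - 0.2)
    if (max(axes) > amax) axes <- axes * (amax / max(axes))
    cells[[i]] <- list(id = i, center = centers[i, ], axes = axes,
                       rot = random_rotation())
  }
  cells
}

axis_coords <- function(spec) {
  d <- spec$dims; s <- spec$spacing
  list(z = (seq_len(d[1]) - 1) * s[1],
       y = (seq_len(d[2]) - 1) * s[2],
       x = (seq_len(d[3]) - 1) * s[3])
}

# squared distance array to a point (x, y, z), dims (nz, ny, nx)
dist2_array <- function(ax, p) {
  dz2 <- (ax$z - p[3])^2; dy2 <- (ax$y - p[2])^2; dx2 <- (ax$x - p[1])^2
  outer(outer(dz2, dy2, "+"), dx2, "+")
}

boundary_6 <- function(lab, within) {
  d <- dim(lab)
  pad <- function(a, k) {
    # shift along axis k by +1/-1 with 0 (outside) padding
    out_p <- array(0L, d); out_m <- array(0L, d)
    if (k == 1) { out_p[2:d[1], , ] <- a[1:(d[1] - 1), , ]
                  out_m[1:(d[1] - 1), , ] <- a[2:d[1], , ] }
    if (k == 2) { out_p[, 2:d[2], ] <- a[, 1:(d[2] - 1), ]
                  out_m[, 1:(d[2] - 1), ] <- a[, 2:d[2], ] }
    if (k == 3) { out_p[, , 2:d[3]] <- a[, , 1:(d[3] - 1)]
                  out_m[, , 1:(d[3] - 1)] <- a[, , 2:d[3]] }
    list(out_p, out_m)
  }
  b <- array(FALSE, d)
  for (k in 1:3) {
    sh <- pad(lab, k)
    b <- b | (lab != sh[[1]]) | (lab != sh[[2]])
  }
  b & within
}

dilate_6 <- function(mask, times) {
  d <- dim(mask)
  for (t in seq_len(times)) {
    m2 <- mask
    m2[2:d[1], , ] <- m2[2:d[1], , ] | mask[1:(d[1] - 1), , ]
    m2[1:(d[1] - 1), , ] <- m2[1:(d[1] - 1), , ] | mask[2:d[1], , ]
    m2[, 2:d[2], ] <- m2[, 2:d[2], ] | mask[, 1:(d[2] - 1), ]
    m2[, 1:(d[2] - 1), ] <- m2[, 1:(d[2] - 1), ] | mask[, 2:d[2], ]
    m2[, , 2:d[3]] <- m2[, , 2:d[3]] | mask[, , 1:(d[3] - 1)]
    m2[, , 1:(d[3] - 1)] <- m2[, , 1:(d[3] - 1)] | mask[, , 2:d[3]]
    mask <- m2
  }
  mask
}

ellipsoid_mesh <- function(cell, subdivisions = 3L, frame_index = 0L) {
  sph <- make_icosphere(c(0, 0, 0), 1, subdivisions)
  v <- sph$vertices %*% diag(cell$axes) %*% t(cell$rot)
  v <- sweep(v, 2, cell$center, "+")
  ensure_outward(tri_mesh(v, sph$faces, frame_index, cell$id))
}

render_frame <- function(spec, cells, agg_center, frame_index = 0L,
                         noise_seed = spec$seed) {
  d <- spec$dims
  ax <- axis_coords(spec)
  agg <- dist2_array(ax, agg_center) <= spec$aggregate_radius^2
  # Voronoi cell labels inside the aggregate
  best <- array(Inf, d)
  lab <- array(0L, d)
  for (cl in cells) {
    d2 <- dist2_array(ax, cl$center)
    take <- agg & (d2 < best)
    best[take] <- d2[take]
    lab[take] <- cl$id
  }
  # nucleus labels: ellipsoid membership, computed inside each bbox
  nuc <- array(0L, d)
  for (cl in cells) {
    amax <- max(cl$axes)
    kr <- range(which(abs(ax$z - cl$center[3]) <= amax + spec$spacing[1]))
    jr <- range(which(abs(ax$y - cl$center[2]) <= amax + spec$spacing[2]))
    ir <- range(which(abs(ax$x - cl$center[1]) <= amax + spec$spacing[3]))
    grid <- expand.grid(k = kr[1]:kr[2], j = jr[1]:jr[2], i = ir[1]:ir[2])
    pts <- cbind(ax$x[grid$i], ax$y[grid$j], ax$z[grid$k])
    rel <- sweep(pts, 2, cl$center) %*% cl$rot %*% diag(1 / cl$axes)
    inside <- rowSums(rel^2) <= 1
    idx <- cbind(grid$k, grid$j, grid$i)[inside, , drop = FALSE]
    nuc[idx] <- cl$id
  }
  memb <- boundary_6(lab, agg | dilate_6(lab > 0L, 1L))
  if (spec$membrane_thickness_px > 1L)
    memb <- dilate_6(memb, spec$membrane_thickness_px - 1L)
  nuclear <- array(as.numeric(nuc > 0L), d)
  membrane <- array(as.numeric(memb), d)
  if (spec$psf_sigma_px > 0) {
    sig <- rep(spec$psf_sigma_px, 3)
    nuclear <- array(cpp_gaussian_blur3d(nuclear, d, sig), d)
    membrane <- array(cpp_gaussian_blur3d(membrane, d, sig), d)
  }
  if (spec$noise_poisson_scale > 0 || spec$noise_gaussian_sd > 0) {
    with_seed(noise_seed, {
      for (nm in c("nuclear", "membrane")) {
        img <- get(nm)
        if (spec$noise_poisson_scale > 0)
          img <- array(stats::rpois(length(img),
                                    img * spec$noise_poisson_scale) /
                         spec$noise_poisson_scale, d)
        if (spec$noise_gaussian_sd > 0)
          img <- img + array(stats::rnorm(length(img), 0,
                                          spec$noise_gaussian_sd), d)
        assign(nm, pmax(img, 0))
      }
    })
  }
  s <- spec$spacing
  nucleus_meshes <- lapply(cells, ellipsoid_mesh, frame_index = frame_index)
  cell_meshes <- lapply(cells, function(cl) {
    reg <- volume(lab == cl$id, s)
    raycast_from_region(reg, 3L, frame_index, cl$id)
  })
  structure(list(
    nuclear = volume(nuclear, s), membrane = volume(membrane, s),
    nucleus_meshes = nucleus_meshes, cell_meshes = cell_meshes,
    nucleus_labels = volume(nuc, s), cell_labels = volume(lab, s),
    cells = cells, aggregate_center = agg_center, frame_index = frame_index
  ), class = "phantom_frame")
}

#' Generate one synthetic two-channel frame
#'
#' Samples non-overlapping ellipsoidal nuclei inside an aggregate ball,
#' partitions the ball into cells (Voronoi around the nucleus centers),
#' renders a filled-nucleus channel and a membrane-shell channel with
#' Gaussian PSF blur and mild Poisson + Gaussian noise, and returns the
#' noiseless geometry as ground-truth meshes and label volumes.
#'
#' @param spec a [phantom_spec].
#' @return A `phantom_frame`: volumes `nuclear` and `membrane`, lists
#'   `nucleus_meshes` and `cell_meshes`, label volumes `nucleus_labels` and
#'   `cell_labels`, and the generating `cells` state.
#' @export
generate_frame <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims; s <- spec$spacing
  center <- c((d[3] - 1) * s[3], (d[2] - 1) * s[2], (d[1] - 1) * s[1]) / 2
  cells <- with_seed(spec$seed, sample_cells(spec, center))
  render_frame(spec, cells, center, 0L, spec$seed)
}

divide_cell <- function(cell, next_id, others = list()) {
  # daughters are born small (as after mitosis), strictly disjoint from one
  # another, and the division axis is chosen (among random candidates) to
  # maximise clearance from the neighbouring nuclei
  axes <- cell$axes * 0.62
  off_len <- 1.15 * max(axes)
  best_u <- NULL; best_score <- -Inf
  for (cand in 1:50) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    score <- Inf
    for (ot in others) {
      for (s in c(1, -1)) {
        ctr <- cell$center + s * off_len * u
        clear <- sqrt(sum((ctr - ot$center)^2)) - max(axes) - max(ot$axes)
        score <- min(score, clear)
      }
    }
    if (score > best_score) { best_score <- score; best_u <- u }
  }
  off <- off_len * best_u
  d1 <- list(id = next_id, center = cell$center + off, axes = axes,
             rot = random_rotation())
  d2 <- list(id = next_id + 1L, center = cell$center - off, axes = axes,
             rot = random_rotation())
  list(d1, d2)
}

#' Generate a synthetic time-lapse with drift and divisions
#'
#' The whole aggregate drifts at `drift_um_per_frame` along a fixed random
#' direction with small per-cell jitter; scheduled divisions replace a cell
#' by two smaller disjoint daughters. The ground-truth track table records
#' every cell center per frame with its parent lineage.
#'
#' @param spec a [phantom_spec].
#' @param n_frames number of frames (>= 1).
#' @return list with `frames` (list of `phantom_frame`) and `tracks` (data
#'   frame: `frame`, `cell_id`, `x`, `y`, `z`, `parent_id`).
#' @export
generate_timelapse <- function(spec, n_frames) {
  stopifnot(inherits(spec, "phantom_spec"), n_frames >= 1)
  d <- spec$dims; s <- spec$spacing
  center <- c((d[3] - 1) * s[3], (d[2] - 1) * s[2], (d[1] - 1) * s[1]) / 2
  # place the aggregate so that the drift stays inside the field of view
  drift_total <- spec$drift_um_per_frame * (n_frames - 1)
  state <- with_seed(spec$seed, {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    start <- center - dir * drift_total / 2
    list(cells = sample_cells(spec, start), dir = dir, start = start)
  })
  cells <- state$cells
  frames <- vector("list", n_frames)
  tracks <- NULL
  parent_of <- integer(0)
  for (t in seq_len(n_frames)) {
    offset <- state$dir * spec$drift_um_per_frame * (t - 1)
    if (t > 1) {
      cells <- with_seed(spec$seed + 7919L * t, {
        moved <- lapply(cells, function(cl) {
          cl$center <- cl$center + state$dir * spec$drift_um_per_frame +
            stats::rnorm(3, 0, spec$jitter_um_sd)
          cl
        })
        if (!is.null(spec$divisions)) {
          due <- spec$divisions[spec$divisions$frame == t, , drop = FALSE]
          for (r in seq_len(nrow(due))) {
            i <- which(vapply(moved, function(cl) cl$id, 1L) == due$cell_id[r])
            if (!length(i)) next
            next_id <- max(vapply(moved, function(cl) cl$id, 1L)) + 1L
            daughters <- divide_cell(moved[[i]], next_id, moved[-i])
            parent_of[as.character(next_id)] <- due$cell_id[r]
            parent_of[as.character(next_id + 1L)] <- due$cell_id[r]
            moved <- c(moved[-i], daughters)
          }
        }
        moved
      })
    }
    frames[[t]] <- render_frame(spec, cells, state$start + offset, t,
                                spec$seed + 104729L * t)
    tracks <- rbind(tracks, do.call(rbind, lapply(cells, function(cl) {
      pid <- parent_of[as.character(cl$id)]
      data.frame(frame = t, cell_id = cl$id, x = cl$center[1],
                 y = cl$center[2], z = cl$center[3],
                 parent_id = if (length(pid) && !is.na(pid)) pid else NA_integer_)
    })))
  }
  list(frames = frames, tracks = tracks)
}
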