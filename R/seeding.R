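#' Seed region extracted from a distance transform
#'
#' @keywords internal
seed_region <- function(label, voxels, center_of_mass, size) {
  structure(list(label = as.integer(label), voxels = voxels,
                 center_of_mass = center_of_mass, size = as.integer(size)),
            class = "seed_region")
}

regions_from_label_array <- function(lab, vol) {
  labs <- sort(unique(lab[lab > 0L]))
  out <- vector("list", length(labs))
  for (s in seq_along(labs)) {
    idx <- which(lab == labs[s], arr.ind = TRUE)
    com <- colMeans(voxel_centers(vol, idx))
    out[[s]] <- seed_region(labs[s], idx, com, nrow(idx))
  }
  out
}

#' Threshold a distance transform into candidate seed regions
#'
#' Connected components (26-connectivity) of `{dt >= theta}`, filtered to
#' voxel counts inside `[s_min, s_max]`, labelled deterministically in array
#' scan order. A threshold of 1 keeps everything strictly interior; the
#' working default of 3 additionally separates nuclei whose interiors come
#' close to touching.
#'
#' @param dt a [volume] holding the (predicted) distance transform.
#' @param theta threshold; voxels with `dt >= theta` are kept.
#' @param s_min,s_max region size bounds in voxels.
#' @return list of `seed_region` (possibly empty).
#' @export
threshold_regions <- function(dt, theta = 3, s_min = 1L, s_max = Inf) {
  stopifnot(is_volume(dt), theta >= 0)
  d <- vol_dims(dt)
  mask <- dt$data >= theta
  lab <- array(cpp_label_components(as.logical(mask), d, 26L), dim = d)
  regs <- regions_from_label_array(lab, dt)
  regs <- Filter(function(r) r$size >= s_min && r$size <= s_max, regs)
  # relabel sequentially, preserving scan order
  for (s in seq_along(regs)) regs[[s]]$label <- s
  regs
}

#' Expand seed regions over the distance transform
#'
#' Marker-based watershed on the negated distance transform, restricted to
#' `{dt >= theta_floor}` (default 1, i.e. strictly interior voxels): voxels
#' are flooded from the seeds in decreasing dt order, so the grown regions
#' partition the interior and each contains its seed. Ties are resolved
#' toward the lower label for determinism.
#'
#' @param seeds list of disjoint `seed_region` (markers).
#' @param dt a [volume] holding the distance transform.
#' @param theta_floor growth floor; voxels below it are never claimed.
#' @return list of `seed_region`, same labels as the seeds.
#' @export
grow_regions <- function(seeds, dt, theta_floor = 1) {
  stopifnot(is_volume(dt))
  if (!length(seeds)) return(list())
  d <- vol_dims(dt)
  markers <- array(0L, dim = d)
  total <- 0L
  for (s in seeds) {
    markers[s$voxels] <- s$label
    total <- total + s$size
  }
  if (sum(markers > 0L) != total) stop("seed regions overlap")
  lab <- array(cpp_watershed(as.numeric(dt$data), as.integer(markers), d,
                             theta_floor), dim = d)
  regions_from_label_array(lab, dt)
}

#' Initialise meshes inside seed regions by raycasting
#'
#' One mesh per region via [raycast_from_region()]; the region label becomes
#' the mesh `instance_id`. Regions on which raycasting fails (e.g. a center
#' of mass outside a pathological region) are skipped with a warning; the
#' skipped labels are attached as the `"skipped"` attribute.
#'
#' @param regions list of `seed_region`.
#' @param grid a [volume] supplying the geometry.
#' @param subdivisions icosphere subdivision level.
#' @param frame_index time index stamped on the meshes.
#' @return list of [tri_mesh].
#' @export
seed_meshes <- function(regions, grid, subdivisions = 2L, frame_index = 0L) {
  out <- list()
  skipped <- integer(0)
  d <- vol_dims(grid)
  for (r in regions) {
    mask <- array(FALSE, dim = d)
    mask[r$voxels] <- TRUE
    reg <- volume(mask, grid$spacing, grid$origin)
    m <- tryCatch(
      raycast_from_region(reg, subdivisions, frame_index, r$label),
      error = function(e) {
        warning("skipping region ", r$label, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(m)) skipped <- c(skipped, r$label) else out[[length(out) + 1L]] <- m
  }
  attr(out, "skipped") <- skipped
  out
}

#' Segment nuclei from a distance-transform volume
#'
#' Threshold, grow by watershed, seed meshes by raycasting, deform each mesh
#' with the perpendicular intensity energy of the distance transform under a
#' negative image weight (the mesh descends to the transform's minima, i.e.
#' the nucleus boundary) balanced by a positive `alpha` shrinkage, then drop
#' meshes that collapsed below `v_min` — shrinkage marks false-positive
#' seeds.
#'
#' @param dt a nonnegative [volume] (predicted or oracle distance transform).
#' @param params a [deform_params]; `w_img` should be negative and `alpha`
#'   positive.
#' @param theta seed threshold (default 3).
#' @param s_min,s_max seed size bounds in voxels.
#' @param v_min volume floor in µm³ for the shrinkage filter.
#' @param theta_floor watershed growth floor.
#' @param subdivisions icosphere subdivision level for seeding.
#' @param frame_index time index stamped on the meshes.
#' @return list of kept `deform_result`; the number of filtered meshes is in
#'   the `"n_removed"` attribute.
#' @export
segment_nuclei <- function(dt, params = nucleus_dt_params(), theta = 3,
                           s_min = NULL, s_max = Inf,
                           v_min = 4 / 3 * pi * 1.5^3, theta_floor = 1,
                           subdivisions = 2L, frame_index = 0L) {
  stopifnot(is_volume(dt))
  if (is.null(s_min))
    s_min <- max(1, round(4 / 3 * pi / prod(dt$spacing)))  # 1 um-radius ball
  seeds <- threshold_regions(dt, theta, s_min, s_max)
  if (!length(seeds)) return(structure(list(), n_removed = 0L))
  regions <- grow_regions(seeds, dt, theta_floor)
  meshes <- seed_meshes(regions, dt, subdivisions, frame_index)
  results <- lapply(meshes, function(m)
    deform(m, dt, "intensity", params, v_stop = v_min / 4))
  part <- filter_small(results, v_min)
  structure(part$kept, n_removed = length(part$removed))
}

#' Default deformation parameters for meshes on distance transforms
#'
#' Negative image weight (descend to dt minima) with a shrinking `alpha`;
#' used for both nucleus and membrane segmentation on dt volumes.
#'
#' @param w_img negative image weight.
#' @param alpha shrinkage weight.
#' @param ... passed to [deform_params()].
#' @return a [deform_params].
#' @export
nucleus_dt_params <- function(w_img = -2, alpha = 5, sigma = 1, w = 3L, ...) {
  deform_params(alpha = alpha, w_img = w_img, sigma = sigma, w = w, ...)
}

#' Segment cell membranes starting from nucleus meshes
#'
#' Each nucleus mesh is copied and deformed on the membrane distance
#' transform with the perpendicular intensity energy under a negative image
#' weight, with steric repulsion between the growing membrane meshes so that
#' neighbours cannot interpenetrate. Instance ids are inherited from the
#' nuclei. Two sweeps are run so every mesh also feels the final shapes of
#' meshes deformed after it.
#'
#' @param nucleus_meshes list of closed [tri_mesh].
#' @param membrane_dt a nonnegative [volume].
#' @param params a [deform_params] with negative `w_img`.
#' @return list of `deform_result`, one per nucleus mesh, same order.
#' @export
segment_membranes <- function(nucleus_meshes, membrane_dt,
                              params = membrane_dt_params()) {
  stopifnot(is_volume(membrane_dt))
  if (!length(nucleus_meshes)) return(list())
  current <- nucleus_meshes
  results <- vector("list", length(current))
  for (sweep in 1:2) {
    for (i in seq_along(current)) {
      res <- deform(current[[i]], membrane_dt, "intensity", params,
                    others = current[-i])
      current[[i]] <- res$mesh
      results[[i]] <- res
    }
  }
  results
}

#' Default deformation parameters for membrane meshes on distance transforms
#'
#' Like [nucleus_dt_params()] but with a slightly weaker shrinkage so meshes
#' expand from the nucleus out to the cell boundary against steric repulsion.
#'
#' @inheritParams nucleus_dt_params
#' @return a [deform_params].
#' @export
membrane_dt_params <- function(w_img = -2, alpha = 1.5, sigma = 1, w = 3L, ...) {
  deform_params(alpha = alpha, w_img = w_img, sigma = sigma, w = w, ...)
}
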