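#' 3D voxel volume with anisotropic spacing
#'
#' A `volume` wraps a 3D array indexed `(z, y, x)` together with the physical
#' voxel spacing and the physical position of the first voxel center. All
#' physical coordinates in the package are micrometres; points are `(x, y, z)`
#' while `spacing` and `origin` follow the array axis order `(z, y, x)`.
#'
#' @param data 3D numeric/integer/logical array, dimensions `(nz, ny, nx)`.
#' @param spacing voxel spacing in µm, either a scalar (isotropic) or a
#'   length-3 vector `(sz, sy, sx)`.
#' @param origin physical position (µm) of the center of voxel `[1, 1, 1]`,
#'   in `(z, y, x)` order.
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = 1, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be a positive scalar or length-3 vector")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "volume"
  )
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume: %d x %d x %d voxels (z,y,x), spacing %.4g x %.4g x %.4g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "volume")

vol_dims <- function(vol) dim(vol$data)

#' Physical coordinates of voxel centers
#'
#' Converts 1-based array indices `(k, j, i)` (z, y, x order) to physical
#' `(x, y, z)` points in µm.
#'
#' @param vol a [volume].
#' @param kji integer matrix with columns `(k, j, i)`.
#' @return numeric matrix with columns `(x, y, z)`.
#' @keywords internal
voxel_centers <- function(vol, kji) {
  kji <- rbind(kji)
  cbind(
    x = vol$origin[3] + (kji[, 3] - 1) * vol$spacing[3],
    y = vol$origin[2] + (kji[, 2] - 1) * vol$spacing[2],
    z = vol$origin[1] + (kji[, 1] - 1) * vol$spacing[1]
  )
}

#' Nearest voxel index of physical points
#'
#' @param vol a [volume].
#' @param pts numeric matrix with columns `(x, y, z)` (µm).
#' @return integer matrix with columns `(k, j, i)`, 1-based; may fall outside
#'   the grid (caller checks).
#' @keywords internal
nearest_voxel <- function(vol, pts) {
  pts <- rbind(pts)
  cbind(
    k = as.integer(round((pts[, 3] - vol$origin[1]) / vol$spacing[1])) + 1L,
    j = as.integer(round((pts[, 2] - vol$origin[2]) / vol$spacing[2])) + 1L,
    i = as.integer(round((pts[, 1] - vol$origin[3]) / vol$spacing[3])) + 1L
  )
}

#' Trilinear intensity sampling
#'
#' Samples a volume at arbitrary physical points by trilinear interpolation of
#' the eight surrounding voxel centers. Points outside the grid are clamped to
#' the border voxel centers, so sampling never extrapolates.
#'
#' @param I a [volume].
#' @param x numeric matrix with columns `(x, y, z)` in µm (a single point may
#'   be given as a length-3 vector).
#' @return numeric vector of sampled intensities, one per point.
#' @export
sample_intensity <- function(I, x) {
  stopifnot(is_volume(I))
  x <- rbind(x)
  cpp_trilinear(as.numeric(I$data), dim(I$data), I$spacing, I$origin, x)
}

#' Resample a volume to isotropic voxels
#'
#' Linearly interpolates along z so that the z spacing equals the in-plane
#' spacing (which must itself be isotropic in x/y). The physical extent is
#' preserved to within one voxel. Already-isotropic volumes are returned
#' unchanged.
#'
#' @param vol a [volume].
#' @return a [volume] with isotropic spacing.
#' @export
resample_isotropic <- function(vol) {
  stopifnot(is_volume(vol))
  s <- vol$spacing
  if (abs(s[2] - s[3]) > 1e-9 * s[3])
    stop("in-plane (y, x) spacing must be isotropic")
  if (abs(s[1] - s[3]) <= 1e-9 * s[3]) return(vol)
  d <- dim(vol$data)
  target <- s[3]
  extent_z <- (d[1] - 1) * s[1]
  nz_new <- as.integer(round(extent_z / target)) + 1L
  z_new <- seq(0, by = target, length.out = nz_new)
  z_old <- seq(0, by = s[1], length.out = d[1])
  # position each new slice between its bracketing old slices
  idx <- findInterval(z_new, z_old, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), d[1] - 1L)
  frac <- (z_new - z_old[idx]) / s[1]
  frac <- pmin(pmax(frac, 0), 1)
  out <- array(0, dim = c(nz_new, d[2], d[3]))
  for (k in seq_len(nz_new)) {
    out[k, , ] <- (1 - frac[k]) * vol$data[idx[k], , ] +
      frac[k] * vol$data[idx[k] + 1L, , ]
  }
  volume(out, spacing = c(target, s[2], s[3]), origin = vol$origin)
}
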