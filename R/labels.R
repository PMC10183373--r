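#' Training label triplet: mask, border, saturated distance transform
#'
#' @param mask binary [volume]: voxels inside any mesh.
#' @param border binary [volume]: mask voxels with a face-adjacent neighbour
#'   outside their own instance.
#' @param dt integer [volume]: erosion depth (0 on the border, 1 on the next
#'   shell, ...), saturated at 32, zero outside the mask.
#' @return An object of class `label_triplet`.
#' @keywords internal
label_triplet <- function(mask, border, dt) {
  structure(list(mask = mask, border = border, dt = dt),
            class = "label_triplet")
}

#' @export
print.label_triplet <- function(x, ...) {
  cat(sprintf("label_triplet: %d mask voxels, %d border voxels, max dt %d\n",
              sum(x$mask$data), sum(x$border$data), max(x$dt$data)))
  invisible(x)
}

DT_SATURATION <- 32L

#' Generate training labels from segmentation meshes
#'
#' Voxelizes the meshes into an instance-label image (earlier meshes claim
#' contested voxels first), then iteratively erodes each instance with the
#' 6-connected structuring element: voxels removed at depth 0 are the border,
#' the next shell has distance-transform value 1, and so on, saturated at 32.
#' Erosion depth is computed per instance, so the border and the
#' distance-transform zeros trace cell-cell interfaces as well as the outer
#' surface — which is what lets membrane meshes later converge onto
#' interfaces between touching cells.
#'
#' `meshes` may also be given directly as an integer instance-label (or
#' binary) array/volume, in which case voxelization is skipped.
#'
#' By default the erosion runs on the union of all instances, exactly the
#' printed label-generation procedure (all meshes binarized into one image).
#' With `per_instance = TRUE` each instance is eroded against its own
#' boundary, so touching instances keep border voxels and distance-transform
#' zeros along their shared interface — the structure membrane meshes later
#' converge to. On disjoint instances the two settings agree voxel for
#' voxel.
#'
#' @param meshes list of closed [tri_mesh], or a [volume]/array of instance
#'   labels.
#' @param grid a [volume] supplying the target geometry.
#' @param cap saturation value for the distance transform.
#' @param per_instance erode each instance separately instead of the union.
#' @return a `label_triplet`.
#' @export
make_labels <- function(meshes, grid = NULL, cap = DT_SATURATION,
                        per_instance = FALSE) {
  if (is_volume(meshes) || is.array(meshes)) {
    if (is.array(meshes)) {
      stopifnot(is_volume(grid))
      labels <- array(as.integer(meshes), dim = dim(meshes))
    } else {
      grid <- meshes
      labels <- array(as.integer(meshes$data), dim = dim(meshes$data))
    }
  } else {
    stopifnot(is.list(meshes), is_volume(grid))
    labels <- voxelize_instances(meshes, grid)$data
  }
  d <- dim(labels)
  if (!per_instance) labels <- array(as.integer(labels != 0L), dim = d)
  depth <- cpp_erosion_depth(as.integer(labels), d, as.integer(cap))
  depth <- array(depth, dim = d)
  mask <- array(as.integer(labels != 0L), dim = d)
  border <- array(as.integer(labels != 0L & depth == 0L), dim = d)
  dt <- array(ifelse(depth < 0L, 0L, depth), dim = d)
  label_triplet(
    mask = volume(mask, grid$spacing, grid$origin),
    border = volume(border, grid$spacing, grid$origin),
    dt = volume(dt, grid$spacing, grid$origin)
  )
}

#' Voxelize a set of meshes into an instance-label volume
#'
#' Each mesh claims the voxels whose centers it contains; contested voxels go
#' to the earlier mesh in the list. Labels are the meshes' `instance_id`s
#' (falling back to sequence position when unset).
#'
#' @param meshes list of closed [tri_mesh].
#' @param grid a [volume] supplying the geometry.
#' @return an integer-label [volume].
#' @export
voxelize_instances <- function(meshes, grid) {
  d <- vol_dims(grid)
  labels <- array(0L, dim = d)
  for (s in seq_along(meshes)) {
    m <- meshes[[s]]
    if (!is_closed_mesh(m)) stop("invalid mesh: not closed")
    inside <- cpp_voxelize(m$vertices, m$faces, d, grid$spacing, grid$origin)
    claim <- inside & (labels == 0L)
    labels[claim] <- if (m$instance_id > 0L) m$instance_id else s
  }
  volume(labels, grid$spacing, grid$origin)
}

as_num_array <- function(x) {
  if (is_volume(x)) as.numeric(x$data) else as.numeric(x)
}

#' Sorensen-Dice coefficient loss (as printed)
#'
#' `L = (|T.P| + 1) / (|T| + |P| + 1)` with soft intersection `sum(T*P)` and
#' soft sizes `sum(T)`, `sum(P)`. Note this form evaluates to about 0.5 on a
#' perfect large match and to 1 on two empty sets; the conventional Dice
#' complement `1 - 2|T.P| / (|T| + |P| + 1)` is available behind
#' `form = "complement"`.
#'
#' @param truth binary volume/array.
#' @param pred real-valued volume/array in `[0, 1]`, same shape.
#' @param form `"printed"` (default) or `"complement"`.
#' @return scalar loss.
#' @export
dice_loss <- function(truth, pred, form = c("printed", "complement")) {
  form <- match.arg(form)
  t_ <- as_num_array(truth); p_ <- as_num_array(pred)
  if (length(t_) != length(p_)) stop("shape mismatch between truth and prediction")
  inter <- sum(t_ * p_)
  if (form == "printed") (inter + 1) / (sum(t_) + sum(p_) + 1)
  else 1 - 2 * inter / (sum(t_) + sum(p_) + 1)
}

#' Log mean-square error loss
#'
#' `log(mean((T - P)^2) + 1e-8)`; the epsilon keeps the perfect-match case
#' finite.
#'
#' @inheritParams dice_loss
#' @return scalar loss.
#' @export
log_mse_loss <- function(truth, pred) {
  t_ <- as_num_array(truth); p_ <- as_num_array(pred)
  if (length(t_) != length(p_)) stop("shape mismatch between truth and prediction")
  log(mean((t_ - p_)^2) + 1e-8)
}

#' Loss weights for the three label heads
#'
#' @param w_e,w_k,w_d nonnegative weights for the border, mask and
#'   distance-transform losses (defaults 1, 1, 1).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(w_e = 1, w_k = 1, w_d = 1) {
  if (any(c(w_e, w_k, w_d) < 0)) stop("weights must be nonnegative")
  if (w_e + w_k + w_d == 0) stop("at least one weight must be positive")
  structure(list(w_e = w_e, w_k = w_k, w_d = w_d), class = "loss_weights")
}

#' Composite three-label training loss
#'
#' `L = w_e L_e(border) + w_k L_k(mask) + w_d L_d(dt)`: Dice-form losses for
#' the border and mask heads, log-MSE for the distance-transform head.
#'
#' @param pred list with elements `mask`, `border`, `dt` (volumes or arrays).
#' @param truth a `label_triplet` (or a list of the same shape).
#' @param weights a [loss_weights].
#' @param dice_form passed through to [dice_loss()].
#' @return scalar loss.
#' @export
total_loss <- function(pred, truth, weights = loss_weights(),
                       dice_form = "printed") {
  weights$w_e * dice_loss(truth$border, pred$border, dice_form) +
    weights$w_k * dice_loss(truth$mask, pred$mask, dice_form) +
    weights$w_d * log_mse_loss(truth$dt, pred$dt)
}
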