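#' Oracle label predictor
#'
#' Produces the exact training labels of the ground-truth meshes (via
#' [make_labels()]), optionally corrupting the distance transform with
#' seeded Gaussian noise — a stand-in for a trained network that lets the
#' seeding and deformation stages be exercised at desk scale.
#'
#' @param gt_meshes list of closed [tri_mesh].
#' @param grid a [volume] supplying the geometry.
#' @param noise_sd standard deviation of Gaussian noise added to the dt
#'   (0 = exact labels).
#' @param seed RNG seed for the noise.
#' @param per_instance passed to [make_labels()]; use `TRUE` for membrane
#'   meshes so the dt keeps minima along cell-cell interfaces.
#' @return a `label_triplet`; with noise the dt is real-valued, clipped to
#'   `[0, 32]`.
#' @export
oracle_predict <- function(gt_meshes, grid, noise_sd = 0, seed = 1L,
                           per_instance = FALSE) {
  lt <- make_labels(gt_meshes, grid, per_instance = per_instance)
  if (noise_sd > 0) {
    d <- vol_dims(lt$dt)
    noisy <- with_seed(seed, {
      lt$dt$data + array(stats::rnorm(prod(d), 0, noise_sd), d)
    })
    lt$dt$data <- pmin(pmax(noisy, 0), DT_SATURATION)
  }
  lt
}

#' Specification of a label predictor
#'
#' @param kind `"oracle"` or `"convnet"`.
#' @param patch_shape training patch shape `(nz, ny, nx)`.
#' @param channels hidden channels of the convolutional predictor.
#' @param kernel_size spatial kernel edge (odd).
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(kind = c("oracle", "convnet"),
                           patch_shape = c(32L, 32L, 32L),
                           channels = 4L, kernel_size = 3L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, patch_shape = as.integer(patch_shape),
                 channels = as.integer(channels),
                 kernel_size = as.integer(kernel_size)),
            class = "predictor_spec")
}

shift3 <- function(x, dz, dy, dx) {
  d <- dim(x)
  out <- array(0, d)
  zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
  out[zs, ys, xs] <- x[zs - dz, ys - dy, xs - dx]
  out
}

conv_offsets <- function(k) {
  r <- (k - 1L) %/% 2L
  expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

convnet_forward <- function(model, x) {
  off <- model$offsets
  C <- length(model$b1)
  pre <- vector("list", C)
  for (c_ in seq_len(C)) {
    acc <- array(model$b1[c_], dim(x))
    for (o in seq_len(nrow(off)))
      acc <- acc + model$W1[o, c_] * shift3(x, off$dz[o], off$dy[o], off$dx[o])
    pre[[c_]] <- acc
  }
  h <- lapply(pre, function(p) pmax(p, 0))
  head_out <- function(v, b) {
    acc <- array(b, dim(x))
    for (c_ in seq_len(C)) acc <- acc + v[c_] * h[[c_]]
    acc
  }
  z_mask <- head_out(model$Vm, model$bm)
  z_border <- head_out(model$Ve, model$be)
  z_dt <- head_out(model$Vd, model$bd)
  list(pre = pre, h = h,
       mask = sigmoid(z_mask), border = sigmoid(z_border), dt = z_dt)
}

dice_grad <- function(t_, p_, form) {
  den <- sum(t_) + sum(p_) + 1
  inter <- sum(t_ * p_)
  if (form == "printed") t_ / den - (inter + 1) / den^2
  else -2 * t_ / den + 2 * inter / den^2
}

#' Train a miniature convolutional label predictor
#'
#' A compact single-stage 3D convolutional model with one hidden layer of
#' small spatial kernels and three output heads (sigmoid mask, sigmoid
#' border, linear distance transform, clipped to `[0, 32]` at prediction
#' time), trained by full-batch gradient descent on the composite
#' Dice + log-MSE loss of [total_loss()]. It is a testing vehicle for the
#' predictor contract — deterministic given the seed, loss decreasing on its
#' training data — not a high-capacity segmentation network.
#'
#' @param frames list of training pairs, each `list(image = volume,
#'   labels = label_triplet)`.
#' @param spec a [predictor_spec] of kind `"convnet"`.
#' @param epochs training epochs.
#' @param seed RNG seed for weight initialisation.
#' @param lr learning rate.
#' @param weights a [loss_weights].
#' @param dice_form Dice convention passed to the loss; the conventional
#'   complement form is the useful choice for actually fitting.
#' @return An object of class `tiny_convnet` with a `loss_history` element.
#' @export
train_tiny_unet <- function(frames, spec = predictor_spec("convnet"),
                            epochs = 10L, seed = 1L, lr = 0.05,
                            weights = loss_weights(),
                            dice_form = "complement") {
  stopifnot(length(frames) >= 1L)
  off <- conv_offsets(spec$kernel_size)
  C <- spec$channels
  model <- with_seed(seed, list(
    offsets = off,
    W1 = matrix(stats::rnorm(nrow(off) * C, 0, 0.1), nrow(off), C),
    b1 = rep(0, C),
    Vm = stats::rnorm(C, 0, 0.1), bm = 0,
    Ve = stats::rnorm(C, 0, 0.1), be = 0,
    Vd = stats::rnorm(C, 0, 0.1), bd = 0
  ))
  # full-batch loss and gradients at the given weights
  fwd_bwd <- function(model) {
    total <- 0
    g <- list(W1 = matrix(0, nrow(off), C), b1 = numeric(C),
              Vm = numeric(C), bm = 0, Ve = numeric(C), be = 0,
              Vd = numeric(C), bd = 0)
    for (fr in frames) {
      x <- as_num_array(fr$image); dim(x) <- vol_dims(fr$image)
      fw <- convnet_forward(model, x)
      tm <- as_num_array(fr$labels$mask); dim(tm) <- dim(x)
      te <- as_num_array(fr$labels$border); dim(te) <- dim(x)
      td <- as_num_array(fr$labels$dt); dim(td) <- dim(x)
      loss <- weights$w_e * dice_loss(te, fw$border, dice_form) +
        weights$w_k * dice_loss(tm, fw$mask, dice_form) +
        weights$w_d * log_mse_loss(td, fw$dt)
      if (!is.finite(loss)) stop("training failure: loss diverged")
      total <- total + loss
      mse <- mean((td - fw$dt)^2)
      dz_dt <- weights$w_d * (2 * (fw$dt - td) / length(td)) / (mse + 1e-8)
      dz_mask <- weights$w_k * dice_grad(tm, fw$mask, dice_form) *
        fw$mask * (1 - fw$mask)
      dz_border <- weights$w_e * dice_grad(te, fw$border, dice_form) *
        fw$border * (1 - fw$border)
      for (c_ in seq_len(C)) {
        g$Vm[c_] <- g$Vm[c_] + sum(dz_mask * fw$h[[c_]])
        g$Ve[c_] <- g$Ve[c_] + sum(dz_border * fw$h[[c_]])
        g$Vd[c_] <- g$Vd[c_] + sum(dz_dt * fw$h[[c_]])
        dpre <- (model$Vm[c_] * dz_mask + model$Ve[c_] * dz_border +
                   model$Vd[c_] * dz_dt) * (fw$pre[[c_]] > 0)
        g$b1[c_] <- g$b1[c_] + sum(dpre)
        for (o in seq_len(nrow(off)))
          g$W1[o, c_] <- g$W1[o, c_] +
            sum(dpre * shift3(x, off$dz[o], off$dy[o], off$dx[o]))
      }
      g$bm <- g$bm + sum(dz_mask)
      g$be <- g$be + sum(dz_border)
      g$bd <- g$bd + sum(dz_dt)
    }
    list(loss = total / length(frames), g = g)
  }
  take_step <- function(model, g, lr) {
    for (nm in c("W1", "b1", "Vm", "bm", "Ve", "be", "Vd", "bd"))
      model[[nm]] <- model[[nm]] - lr * g[[nm]]
    model
  }
  # gradient descent with backtracking: a candidate step that raises the
  # loss is rejected and retried from the last accepted weights at half the
  # step size, so the recorded loss history is non-increasing
  hist <- numeric(epochs)
  best <- list(model = model, loss = Inf, g = NULL)
  candidate <- model
  for (ep in seq_len(epochs)) {
    fb <- fwd_bwd(candidate)
    if (fb$loss <= best$loss) {
      best <- list(model = candidate, loss = fb$loss, g = fb$g)
    } else {
      lr <- lr / 2
    }
    hist[ep] <- best$loss
    candidate <- take_step(best$model, best$g, lr)
  }
  structure(c(best$model, list(loss_history = hist, spec = spec)),
            class = "tiny_convnet")
}

#' Predict label volumes with a trained miniature predictor
#'
#' @param model a `tiny_convnet` from [train_tiny_unet()].
#' @param vol input [volume].
#' @return list of volumes `mask`, `border` (probabilities) and `dt`
#'   (clipped to `[0, 32]`).
#' @export
predict_labels <- function(model, vol) {
  stopifnot(inherits(model, "tiny_convnet"), is_volume(vol))
  x <- as_num_array(vol); dim(x) <- vol_dims(vol)
  fw <- convnet_forward(model, x)
  list(mask = volume(fw$mask, vol$spacing, vol$origin),
       border = volume(fw$border, vol$spacing, vol$origin),
       dt = volume(pmin(pmax(fw$dt, 0), DT_SATURATION), vol$spacing,
                   vol$origin))
}
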