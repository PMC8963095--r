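#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with its standard
#' hyper-parameters, 120 epochs, 40 augmented copies per training or
#' validation image, rigid rotations within +/-10 degrees and shifts
#' within +/-10 voxels on randomly chosen axes, batch size 1 (one 3D
#' volume per step), soft-Dice loss. `target` selects which label map of
#' the triplet the model learns: `"fissures"`, `"tissue"` or `"whole"`.
#'
#' @param epochs number of epochs (default 120).
#' @param loss `"dice"` (soft Dice, default) or `"bce"` (binary
#'   cross-entropy).
#' @param learning_rate Adam step size (default 1e-3, Adam's default).
#' @param batch_size volumes per gradient step; only 1 is supported.
#' @param augment_per_image augmented copies per image (default 40; 0
#'   disables augmentation).
#' @param rotation_range symmetric rotation limits in degrees.
#' @param shift_range symmetric shift limits in voxels.
#' @param target one of `"fissures"`, `"tissue"`, `"whole"`.
#' @param seed integer seeding initialization, augmentation and shuffling.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 120,
                            loss = c("dice", "bce"),
                            learning_rate = 1e-3,
                            batch_size = 1,
                            augment_per_image = 40,
                            rotation_range = c(-10, 10),
                            shift_range = c(-10, 10),
                            target = c("fissures", "tissue", "whole"),
                            seed = 1L) {
  loss <- match.arg(loss)
  target <- match.arg(target)
  if (epochs <= 0) stop("epochs must be positive")
  if (augment_per_image < 0) stop("augment_per_image must be >= 0")
  if (batch_size != 1) stop("only batch_size = 1 is supported")
  stopifnot(length(rotation_range) == 2, length(shift_range) == 2)
  structure(list(epochs = as.integer(epochs), loss = loss,
                 learning_rate = learning_rate, batch_size = 1L,
                 augment_per_image = as.integer(augment_per_image),
                 rotation_range = as.numeric(rotation_range),
                 shift_range = as.numeric(shift_range),
                 target = target, seed = as.integer(seed)),
            class = "training_config")
}

#' Draw one random rigid transform
#'
#' Angles are uniform within `rotation_range` for each of the three axes;
#' shifts are uniform within `shift_range` but applied only on a randomly
#' chosen nonempty subset of axes (the others are zero).
#'
#' @param config a [training_config()].
#' @param seed optional integer; when given, draws come from a private RNG
#'   stream, otherwise from the current one.
#' @return List with `angles` (degrees, length 3), `shift` (voxels,
#'   length 3) and `axes` (the shifted axes).
#' @export
random_rigid_params <- function(config, seed = NULL) {
  draw <- function() {
    angles <- runif(3, config$rotation_range[1], config$rotation_range[2])
    axes <- which(runif(3) < 0.5)
    if (length(axes) == 0) axes <- sample.int(3, 1)
    shift <- rep(0, 3)
    shift[axes] <- runif(length(axes), config$shift_range[1],
                         config$shift_range[2])
    list(angles = angles, shift = shift, axes = axes)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

#' Apply a rigid transform to a 3D array
#'
#' Rotates about the grid center and then shifts. Images are resampled
#' with trilinear interpolation, masks with nearest neighbor (which keeps
#' them binary and keeps congruent masks congruent). Voxels sampled from
#' outside the grid take `fill`.
#'
#' @param a 3D array.
#' @param angles rotation angles in degrees (x, y, z).
#' @param shift voxel shifts (x, y, z).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill out-of-grid fill value (default `min(a)`).
#' @return The transformed 3D array.
#' @export
apply_rigid <- function(a, angles, shift,
                        interpolation = c("linear", "nearest"),
                        fill = NULL) {
  interpolation <- match.arg(interpolation)
  if (is.null(fill)) fill <- min(a)
  dims <- dim(a)
  r <- rotation_matrix(angles)
  co <- grid_coords(dims)  # centered voxel coordinates
  # source coordinate of each output voxel (pull resampling)
  src <- sweep(co, 2, shift) %*% r  # co %*% t(solve(r)) == co %*% r (rotation)
  ctr <- (dims + 1) / 2
  src <- sweep(src, 2, ctr, `+`)
  sample_at <- function(ix, iy, iz) {
    ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] &
      iz >= 1 & iz <= dims[3]
    v <- rep(fill, length(ix))
    if (any(ok)) {
      v[ok] <- a[cbind(ix[ok], iy[ok], iz[ok])]
    }
    v
  }
  out <- if (interpolation == "nearest") {
    sample_at(round(src[, 1]), round(src[, 2]), round(src[, 3]))
  } else {
    f <- floor(src)
    w <- src - f
    acc <- numeric(nrow(src))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
        (if (dy) w[, 2] else 1 - w[, 2]) *
        (if (dz) w[, 3] else 1 - w[, 3])
      acc <- acc + wt * sample_at(f[, 1] + dx, f[, 2] + dy, f[, 3] + dz)
    }
    acc
  }
  array(out, dim = dims)
}

#' Augment an image and its label triplet
#'
#' Draws `config$augment_per_image` rigid transforms and applies each one
#' identically to the image (trilinear) and to the three label maps
#' (nearest neighbor, re-binarized). Because all three masks are resampled
#' with the same nearest-neighbor lookup, the triplet invariants survive
#' augmentation exactly.
#'
#' @param volume `intensity_volume` (or 3D array).
#' @param labels a `mask_triplet` on the same grid.
#' @param config a [training_config()].
#' @param seed integer for the transform draws.
#' @return List of `augment_per_image` lists, each with `volume` (array)
#'   and `labels` (`mask_triplet`).
#' @export
augment_image <- function(volume, labels, config, seed = 1L) {
  img <- vol_data(volume)
  stop_if_mismatch(img, labels$whole, "image and labels")
  with_seed(seed, {
    lapply(seq_len(config$augment_per_image), function(i) {
      tr <- random_rigid_params(config)
      timg <- apply_rigid(img, tr$angles, tr$shift, "linear")
      tmask <- function(m) {
        d <- apply_rigid(vol_data(m), tr$angles, tr$shift, "nearest",
                         fill = 0)
        binary_mask(array(as.integer(d > 0.5), dim = dim(d)),
                    m$spacing, m$affine)
      }
      list(volume = timg,
           labels = mask_triplet(tmask(labels$whole), tmask(labels$fissures),
                                 tmask(labels$tissue)))
    })
  })
}

#' Soft Dice loss
#'
#' `1 - 2 * sum(p * g) / (sum(p^2) + sum(g^2))`, the squared-denominator
#' Dice evaluated on soft predictions; 0 for a perfect binary prediction.
#'
#' @param prediction array of probabilities in `[0, 1]`.
#' @param truth `binary_mask` or 0/1 array of the same shape.
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(prediction, truth) {
  soft_dice(prediction, truth)$loss
}

soft_dice <- function(prediction, truth) {
  praw <- if (is.array(prediction)) prediction else vol_data(prediction)
  g <- vol_data(truth)
  if (!identical(unname(dim(praw)[1:3]), unname(dim(g)[1:3]))) {
    stop("prediction and truth shapes differ")
  }
  p <- as.numeric(praw)
  g <- as.numeric(g)
  num <- 2 * sum(p * g)
  den <- sum(p^2) + sum(g^2)
  if (den == 0) return(list(loss = 0, grad = array(0, dim = dim(praw))))
  dsc <- num / den
  grad <- -(2 * g * den - num * 2 * p) / den^2
  list(loss = 1 - dsc, grad = array(grad, dim = dim(praw)))
}

bce <- function(prediction, truth, eps = 1e-7) {
  praw <- if (is.array(prediction)) prediction else vol_data(prediction)
  p <- pmin(pmax(praw, eps), 1 - eps)
  g <- vol_data(truth)
  n <- length(p)
  list(loss = -mean(g * log(p) + (1 - g) * log(1 - p)),
       grad = array((p - g) / (p * (1 - p)) / n, dim = dim(praw)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# pull the target label array out of a sample, scale input to [0, 1]
prepare_sample <- function(sample, target) {
  x <- vol_data(sample$volume) / 255
  g <- vol_data(sample$labels[[target]])
  list(x = x, g = g)
}

#' Train one segmentation model
#'
#' Trains an inception U-Net on a set of phantom or real samples for one
#' target label map, with batch size 1 and Adam. Each sample is a list
#' with `volume` (contrast-enhanced, range `[1, 255]`) and `labels` (a
#' `mask_triplet`). When `config$augment_per_image > 0` the rigid
#' augmentation is materialized for both partitions before training. The
#' run is deterministic for a fixed `config$seed`.
#'
#' @param spec an [arch_spec()] (a fresh model is initialized from it).
#' @param dataset list with elements `train` and `val`, each a list of
#'   samples.
#' @param config a [training_config()].
#' @param verbose print a line per epoch?
#' @return List with `model` (final weights), `best_model` (weights at the
#'   best validation Dice), `history` (data frame with per-epoch
#'   `train_loss`, `train_dice`, `val_loss`, `val_dice`).
#' @export
train_model <- function(spec, dataset, config, verbose = FALSE) {
  if (length(dataset$train) == 0 || length(dataset$val) == 0) {
    stop("train and validation partitions must both be nonempty")
  }
  loss_fn <- if (config$loss == "dice") soft_dice else bce
  target <- config$target
  with_seed(config$seed, {
    model <- build_unet(spec)
    expand <- function(samples, seed0) {
      if (config$augment_per_image == 0) return(samples)
      out <- samples
      for (i in seq_along(samples)) {
        aug <- augment_image(samples[[i]]$volume, samples[[i]]$labels,
                             config, seed = seed0 + i)
        out <- c(out, aug)
      }
      out
    }
    train <- lapply(expand(dataset$train, 1000L), prepare_sample,
                    target = target)
    val <- lapply(expand(dataset$val, 2000L), prepare_sample,
                  target = target)
    state <- adam_init(model$params)
    hist <- vector("list", config$epochs)
    best <- list(dice = -Inf, params = NULL)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(train))
      tl <- td <- 0
      for (i in ord) {
        s <- train[[i]]
        fw <- unet_forward(model, s$x, training = TRUE)
        lf <- loss_fn(fw$out, s$g)
        if (!is.finite(lf$loss)) {
          stop(sprintf("training aborted: non-finite loss at epoch %d", ep))
        }
        grads <- unet_backward(model, fw$cache, lf$grad)
        upd <- adam_step(model$params, grads, state,
                         lr = config$learning_rate)
        model$params <- upd$params
        state <- upd$state
        tl <- tl + lf$loss
        td <- td + hard_dice(fw$out, s$g)
      }
      vl <- vd <- 0
      for (s in val) {
        prob <- unet_forward(model, s$x, training = FALSE)
        vl <- vl + loss_fn(prob, s$g)$loss
        vd <- vd + hard_dice(prob, s$g)
      }
      hist[[ep]] <- data.frame(epoch = ep,
                               train_loss = tl / length(train),
                               train_dice = td / length(train),
                               val_loss = vl / length(val),
                               val_dice = vd / length(val))
      if (hist[[ep]]$val_dice > best$dice) {
        best <- list(dice = hist[[ep]]$val_dice, params = model$params)
      }
      if (verbose) {
        message(sprintf("epoch %3d  train loss %.4f  val dice %.4f",
                        ep, hist[[ep]]$train_loss, hist[[ep]]$val_dice))
      }
    }
    best_model <- model
    best_model$params <- best$params
    list(model = model, best_model = best_model,
         history = do.call(rbind, hist))
  })
}

hard_dice <- function(prob, g) {
  p <- as.numeric(prob > 0.5)
  den <- sum(p) + sum(g)
  if (den == 0) return(1)
  2 * sum(p * g) / den
}
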