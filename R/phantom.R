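#' Parameters for the synthetic cerebellum phantom
#'
#' The phantom emulates a cropped, bias-corrected, registered T1-weighted
#' view of the cerebellum: an ellipsoid of bright tissue on a dark
#' background, cut by a small number of thin dark sheets standing in for
#' CSF-filled fissures. Fissure sheets are level-set slabs of smooth scalar
#' functions: planes with an optional sinusoidal warp, clipped to the
#' ellipsoid. Intensities are in arbitrary units; downstream contrast
#' enhancement removes the absolute scale.
#'
#' Defaults give a 48^3 grid with tissue at 150, fissures at 30 and
#' background at 10 -- well-separated classes comparable to the contrast of
#' a real enhanced T1 crop -- three fissures of width 2 voxels, and no bias
#' or noise (corruptions are opt-in so that label-construction ground truth
#' stays exact by default).
#'
#' @param grid_shape integer triple, volume dimensions in voxels.
#' @param ellipsoid_semi_axes numeric triple, semi-axes in voxels; must fit
#'   inside the grid.
#' @param tissue_intensity,fissure_intensity,background_intensity scalars in
#'   arbitrary units; fissure and background must be darker than tissue.
#' @param n_fissures number of fissure sheets (>= 0).
#' @param fissure_width sheet thickness in voxels (>= 1).
#' @param warp_amplitude amplitude (voxels) of the sinusoidal warp applied
#'   to each sheet; 0 gives flat planes.
#' @param bias_field_amplitude multiplicative bias range; 0 disables.
#' @param noise_sigma additive Gaussian noise SD in intensity units; 0
#'   disables.
#' @param seed integer driving fissure orientations, bias and noise.
#' @param fissure_normals optional n x 3 matrix of sheet normals (rows are
#'   normalized internally); overrides the random orientations.
#' @param fissure_offsets optional numeric vector of signed distances (in
#'   voxels) of each sheet plane from the ellipsoid center.
#' @return A `phantom_params` list.
#' @seealso [generate_phantom()]
#' @export
phantom_params <- function(grid_shape = c(48, 48, 48),
                           ellipsoid_semi_axes = c(18, 15, 12),
                           tissue_intensity = 150,
                           fissure_intensity = 30,
                           background_intensity = 10,
                           n_fissures = 3,
                           fissure_width = 2,
                           warp_amplitude = 2,
                           bias_field_amplitude = 0,
                           noise_sigma = 0,
                           seed = 1L,
                           fissure_normals = NULL,
                           fissure_offsets = NULL) {
  p <- list(grid_shape = as.integer(grid_shape),
            ellipsoid_semi_axes = as.numeric(ellipsoid_semi_axes),
            tissue_intensity = tissue_intensity,
            fissure_intensity = fissure_intensity,
            background_intensity = background_intensity,
            n_fissures = as.integer(n_fissures),
            fissure_width = fissure_width,
            warp_amplitude = warp_amplitude,
            bias_field_amplitude = bias_field_amplitude,
            noise_sigma = noise_sigma,
            seed = as.integer(seed),
            fissure_normals = fissure_normals,
            fissure_offsets = fissure_offsets)
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  if (length(p$grid_shape) != 3 || any(p$grid_shape < 8)) {
    stop("grid_shape must be a triple of at least 8 voxels")
  }
  if (length(p$ellipsoid_semi_axes) != 3 || any(p$ellipsoid_semi_axes <= 0)) {
    stop("ellipsoid_semi_axes must be positive")
  }
  if (any(2 * p$ellipsoid_semi_axes >= p$grid_shape)) {
    stop("ellipsoid semi-axes must fit inside the grid")
  }
  if (p$fissure_intensity >= p$tissue_intensity) {
    stop("fissure_intensity must be below tissue_intensity")
  }
  if (p$background_intensity >= p$tissue_intensity) {
    stop("background_intensity must be below tissue_intensity")
  }
  if (p$n_fissures < 0) stop("n_fissures must be >= 0")
  if (p$fissure_width < 1) stop("fissure_width must be >= 1")
  if (p$bias_field_amplitude < 0) stop("bias_field_amplitude must be >= 0")
  if (p$noise_sigma < 0) stop("noise_sigma must be >= 0")
  invisible(TRUE)
}

# voxel-center coordinates relative to the grid center, as an n x 3 matrix
grid_coords <- function(shape) {
  ctr <- (shape + 1) / 2
  cbind(rep(seq_len(shape[1]) - ctr[1], times = shape[2] * shape[3]),
        rep(rep(seq_len(shape[2]) - ctr[2], each = shape[1]),
            times = shape[3]),
        rep(seq_len(shape[3]) - ctr[3], each = shape[1] * shape[2]))
}

#' Generate a synthetic cerebellum phantom
#'
#' Builds the intensity volume and the ground-truth label triplet (whole
#' ellipsoid, fissure sheets, tissue = whole minus fissures). Deterministic
#' for a fixed `params$seed`. Bias field and noise, when enabled, are
#' applied after the noiseless intensities are assembled, so the returned
#' `truth` always refers to the uncorrupted geometry.
#'
#' @param params a [phantom_params()] object.
#' @return A `phantom_sample`: list with `volume` (`intensity_volume`),
#'   `truth` (`mask_triplet`) and `params`.
#' @examples
#' s <- generate_phantom(phantom_params(seed = 7))
#' sum(s$truth$fissures$data)
#' @export
generate_phantom <- function(params) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  validate_phantom_params(params)
  shape <- params$grid_shape
  co <- grid_coords(shape)
  ax <- params$ellipsoid_semi_axes
  inside <- (co[, 1] / ax[1])^2 + (co[, 2] / ax[2])^2 + (co[, 3] / ax[3])^2 <= 1

  fiss <- with_seed(params$seed, {
    f <- rep(FALSE, nrow(co))
    n <- params$n_fissures
    if (n > 0) {
      normals <- params$fissure_normals
      if (is.null(normals)) {
        normals <- matrix(rnorm(3 * n), ncol = 3)
      } else {
        normals <- matrix(normals, ncol = 3)
      }
      normals <- normals / sqrt(rowSums(normals^2))
      offsets <- params$fissure_offsets
      if (is.null(offsets)) {
        offsets <- runif(n, -min(ax) / 3, min(ax) / 3)
      }
      for (k in seq_len(n)) {
        nk <- normals[k, ]
        # tangent direction for the sinusoidal warp
        tk <- c(-nk[2], nk[1], 0)
        if (sum(tk^2) < 1e-8) tk <- c(1, 0, 0)
        tk <- tk / sqrt(sum(tk^2))
        phase <- if (params$warp_amplitude > 0) runif(1, 0, 2 * pi) else 0
        s <- co %*% nk - offsets[k]
        if (params$warp_amplitude > 0) {
          s <- s + params$warp_amplitude *
            sin(2 * pi * (co %*% tk) / (0.8 * min(shape)) + phase)
        }
        f <- f | (abs(s) < params$fissure_width / 2)
      }
    }
    f & inside
  })

  whole <- array(as.integer(inside), dim = shape)
  fissures <- array(as.integer(fiss), dim = shape)
  tissue <- array(as.integer(inside & !fiss), dim = shape)

  img <- array(params$background_intensity, dim = shape)
  img[tissue == 1L] <- params$tissue_intensity
  img[fissures == 1L] <- params$fissure_intensity

  vol <- intensity_volume(img)
  if (params$bias_field_amplitude > 0) {
    vol <- apply_bias_field(vol, params$bias_field_amplitude,
                            seed = params$seed + 1L)
  }
  if (params$noise_sigma > 0) {
    vol <- add_noise(vol, params$noise_sigma, seed = params$seed + 2L)
  }

  structure(list(volume = vol,
                 truth = mask_triplet(binary_mask(whole),
                                      binary_mask(fissures),
                                      binary_mask(tissue)),
                 params = params),
            class = "phantom_sample")
}

#' Corrupt a volume with a smooth multiplicative bias field
#'
#' Emulates the slowly varying intensity inhomogeneity of MR coils with a
#' random second-order polynomial of the voxel coordinates, linearly
#' rescaled to the range `[1 - amplitude, 1 + amplitude]` and multiplied
#' into the image. `amplitude = 0` is the identity.
#'
#' @param volume an `intensity_volume`.
#' @param amplitude non-negative half-range of the field.
#' @param seed integer controlling the polynomial coefficients.
#' @return A corrupted `intensity_volume`.
#' @export
apply_bias_field <- function(volume, amplitude, seed = 1L) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(volume)
  shape <- dim(vol_data(volume))
  co <- grid_coords(shape) / max(shape)  # roughly [-0.5, 0.5]
  field <- with_seed(seed, {
    b <- rnorm(9)
    drop(co %*% b[1:3]) + co[, 1] * co[, 2] * b[4] +
      co[, 1] * co[, 3] * b[5] + co[, 2] * co[, 3] * b[6] +
      co[, 1]^2 * b[7] + co[, 2]^2 * b[8] + co[, 3]^2 * b[9]
  })
  rng <- range(field)
  field <- if (diff(rng) > 0) {
    1 - amplitude + 2 * amplitude * (field - rng[1]) / diff(rng)
  } else {
    rep(1, length(field))
  }
  with_data(volume, array(vol_data(volume) * field, dim = shape))
}

#' Add Gaussian noise to a volume
#'
#' Zero-mean additive Gaussian noise, a simplification of the Rician noise
#' of magnitude MR images; `sigma = 0` is the identity.
#'
#' @param volume an `intensity_volume`.
#' @param sigma non-negative noise SD in intensity units.
#' @param seed integer for reproducible draws.
#' @return A noisy `intensity_volume`.
#' @export
add_noise <- function(volume, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(volume)
  shape <- dim(vol_data(volume))
  noise <- with_seed(seed, rnorm(prod(shape), sd = sigma))
  with_data(volume, array(vol_data(volume) + noise, dim = shape))
}
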