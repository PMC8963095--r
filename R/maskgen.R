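#' Otsu threshold of a volume
#'
#' Picks the threshold maximizing the between-class variance of the
#' intensity histogram. When the volume has at most `n_bins` distinct
#' values the candidates are exactly those values (so the result matches an
#' exhaustive search over the discrete histogram); otherwise a `n_bins`-bin
#' histogram over the observed range is used and candidates are the bin
#' centers. Ties are broken toward the lowest maximizing threshold. A voxel
#' belongs to the lower class iff its intensity is <= the returned value.
#'
#' @param volume an `intensity_volume` with at least two distinct values.
#' @param n_bins histogram resolution (default 256).
#' @return The scalar threshold.
#' @seealso [binarize()]
#' @export
otsu_threshold <- function(volume, n_bins = 256) {
  x <- as.numeric(vol_data(volume))
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("Otsu threshold requires at least two distinct values")
  if (length(ux) <= n_bins) {
    levels <- ux
    counts <- tabulate(match(x, ux), nbins = length(ux))
  } else {
    breaks <- seq(min(x), max(x), length.out = n_bins + 1)
    bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(bin, nbins = n_bins)
    levels <- (breaks[-1] + breaks[-length(breaks)]) / 2
  }
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[length(mu)]
  # between-class variance for split after each level (last split is void)
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, length(levels))
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  i <- which.max(sigma_b)
  # report the midpoint of the optimal split so the threshold separates the
  # two classes strictly; binarization (> threshold) is unaffected
  (levels[i] + levels[i + 1]) / 2
}

#' Threshold a volume into a binary mask
#'
#' A voxel is foreground iff its intensity is strictly greater than the
#' threshold ("kept only those voxels with an intensity higher").
#'
#' @param volume an `intensity_volume`.
#' @param threshold scalar cut.
#' @return A `binary_mask`.
#' @export
binarize <- function(volume, threshold) {
  with_data(volume, vol_data(volume) > threshold, mask = TRUE)
}

shift3 <- function(a, d, fill) {
  dims <- dim(a)
  out <- array(fill, dim = dims)
  src <- dst <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  for (k in 1:3) {
    if (d[k] > 0) {
      dst[[k]] <- (d[k] + 1):dims[k]; src[[k]] <- 1:(dims[k] - d[k])
    } else if (d[k] < 0) {
      dst[[k]] <- 1:(dims[k] + d[k]); src[[k]] <- (1 - d[k]):dims[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

cross6 <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

dilate6 <- function(a) {
  out <- a
  for (d in cross6) out <- pmax(out, shift3(a, d, 0L))
  out
}

erode6 <- function(a) {
  out <- a
  for (d in cross6) out <- pmin(out, shift3(a, d, 1L))
  out
}

#' Smooth a binary mask with a morphological active contour
#'
#' Morphological Chan-Vese evolution initialized at the input mask: each
#' iteration applies the region-competition update driven by the inside and
#' outside mean intensities, followed by `smoothing` passes of the
#' curvature operator, implemented as alternating morphological
#' opening/closing with a 6-neighborhood cross element. With the default
#' `image = NULL` the mask itself plays the role of the image, so the
#' update reduces to pure border smoothing: one-voxel spikes and pits are
#' removed while large regions are preserved. `iterations = 0` returns the
#' input unchanged.
#'
#' @param mask a nonempty `binary_mask`.
#' @param iterations number of evolution steps (default 10).
#' @param smoothing curvature-smoothing passes per step (default 1).
#' @param image optional `intensity_volume` guiding the region terms.
#' @return The smoothed `binary_mask`.
#' @export
smooth_mask <- function(mask, iterations = 10, smoothing = 1, image = NULL) {
  m <- vol_data(mask)
  if (sum(m) == 0) stop("cannot smooth an empty mask")
  if (iterations == 0) return(mask)
  img <- if (is.null(image)) m else vol_data(image)
  stop_if_mismatch(m, img, "mask and image")
  u <- m
  for (it in seq_len(iterations)) {
    inside <- u == 1L
    if (!any(inside) || all(inside)) break
    c1 <- mean(img[inside])
    c0 <- mean(img[!inside])
    grad <- dilate6(u) - erode6(u)
    aux <- grad * ((img - c1)^2 - (img - c0)^2)
    u[aux < 0] <- 1L
    u[aux > 0] <- 0L
    for (s in seq_len(smoothing)) {
      u <- if ((it + s) %% 2 == 0) {
        dilate6(erode6(u))  # opening: shaves spikes
      } else {
        erode6(dilate6(u))  # closing: fills pits
      }
    }
  }
  with_data(mask, u, mask = TRUE)
}

#' Derive the fissure mask
#'
#' Fissures are the dark voxels inside the cerebellum: the XOR of the
#' binarized bright-tissue image with the whole-cerebellum mask, restricted
#' to the mask support, i.e. `whole AND NOT binary`. The restriction keeps
#' bright voxels outside the cerebellum from being labelled as fissures.
#'
#' @param binary `binary_mask` of bright (above-Otsu) voxels.
#' @param whole `binary_mask` of the whole cerebellum, same grid.
#' @return A `binary_mask` of fissures, a subset of `whole`.
#' @export
derive_fissure_mask <- function(binary, whole) {
  stop_if_mismatch(binary, whole, "binary and whole masks")
  with_data(whole, vol_data(whole) == 1L & vol_data(binary) == 0L, mask = TRUE)
}

#' Derive the tissue mask
#'
#' Tissue is the whole-cerebellum mask with the fissures carved out:
#' `whole AND NOT fissures`. Together with the fissure mask this partitions
#' the whole mask exactly.
#'
#' @param whole `binary_mask` of the whole cerebellum.
#' @param fissures `binary_mask` of fissures, must be a subset of `whole`.
#' @return A `binary_mask` of fissure-free tissue.
#' @export
derive_tissue_mask <- function(whole, fissures) {
  stop_if_mismatch(whole, fissures, "whole and fissure masks")
  w <- vol_data(whole); f <- vol_data(fissures)
  if (any(f == 1L & w == 0L)) stop("fissure mask is not a subset of the whole mask")
  with_data(whole, w == 1L & f == 0L, mask = TRUE)
}

#' Build the three training label maps
#'
#' The label-construction procedure: smooth the external cerebellar mask
#' with the morphological snake (optional), compute the Otsu threshold of
#' the contrast-enhanced image, binarize it, and derive the fissure and
#' tissue maps by mask algebra. The returned triplet satisfies
#' `fissures | tissue == whole` and `fissures & tissue == empty` by
#' construction.
#'
#' @param enhanced contrast-enhanced `intensity_volume` (see
#'   [enhance_contrast()]).
#' @param cereb_mask externally produced cerebellar `binary_mask`.
#' @param use_snakes smooth the mask before deriving labels?
#' @param snake_iterations,snake_smoothing parameters for [smooth_mask()].
#' @return A `mask_triplet`.
#' @examples
#' s <- generate_phantom(phantom_params(seed = 3))
#' tri <- build_label_triplet(enhance_contrast(s$volume), s$truth$whole,
#'                            use_snakes = FALSE)
#' @export
build_label_triplet <- function(enhanced, cereb_mask, use_snakes = TRUE,
                                snake_iterations = 10, snake_smoothing = 1) {
  stop_if_mismatch(enhanced, cereb_mask, "image and mask")
  if (sum(vol_data(cereb_mask)) == 0) stop("cerebellar mask is empty")
  whole <- if (use_snakes) {
    smooth_mask(cereb_mask, snake_iterations, snake_smoothing)
  } else {
    cereb_mask
  }
  thr <- otsu_threshold(enhanced)
  bright <- binarize(enhanced, thr)
  fissures <- derive_fissure_mask(bright, whole)
  tissue <- derive_tissue_mask(whole, fissures)
  mask_triplet(whole, fissures, tissue)
}

#' Quality-control summary for a label triplet
#'
#' Voxel counts and the fissure fraction, a stand-in for the visual
#' inspection step of manual dataset curation.
#'
#' @param triplet a `mask_triplet`.
#' @return A one-row data frame with counts and `fissure_fraction`.
#' @export
triplet_qc <- function(triplet) {
  w <- sum(vol_data(triplet$whole))
  f <- sum(vol_data(triplet$fissures))
  data.frame(whole_voxels = w, fissure_voxels = f,
             tissue_voxels = sum(vol_data(triplet$tissue)),
             fissure_fraction = if (w > 0) f / w else NA_real_)
}
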