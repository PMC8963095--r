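#' Z-score intensity normalization
#'
#' Subtracts the global mean and divides by the global (population, i.e.
#' divide-by-N) standard deviation, the first stage of contrast
#' enhancement. Errors on constant volumes.
#'
#' @param volume an `intensity_volume`.
#' @return The normalized `intensity_volume` (mean 0, SD 1).
#' @seealso [enhance_contrast()]
#' @export
normalize_intensity <- function(volume) {
  x <- vol_data(volume)
  mu <- mean(x)
  sdp <- sqrt(mean((x - mu)^2))
  if (sdp == 0) stop("cannot normalize a constant volume (zero variance)")
  with_data(volume, (x - mu) / sdp)
}

#' Linear rescale to a target range
#'
#' Maps the volume minimum to `lo` and the maximum to `hi`; the default
#' [1, 255] range prepares the image for 8-bit-style histogram
#' equalization.
#'
#' @param volume an `intensity_volume`.
#' @param lo,hi target range endpoints.
#' @return The rescaled `intensity_volume`.
#' @export
rescale_range <- function(volume, lo = 1, hi = 255) {
  x <- vol_data(volume)
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot rescale a constant volume")
  out <- lo + (x - rng[1]) * (hi - lo) / diff(rng)
  with_data(volume, pmin(pmax(out, lo), hi))
}

#' Global histogram equalization
#'
#' Remaps intensities by the empirical cumulative histogram computed on
#' `n_bins` equal-width bins over the observed range, then maps the CDF
#' linearly back onto the observed range. The mapping is monotone
#' non-decreasing in the input, and is close to the identity when the
#' input histogram is already uniform. Equalization is global (no brain
#' mask is applied).
#'
#' @param volume an `intensity_volume`, typically already rescaled.
#' @param n_bins number of histogram bins (default 256).
#' @return The equalized `intensity_volume`.
#' @export
equalize_histogram <- function(volume, n_bins = 256) {
  x <- vol_data(volume)
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot equalize a constant volume")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  cdf <- cumsum(counts) / length(x)
  out <- pmin(pmax(rng[1] + diff(rng) * cdf[bin], rng[1]), rng[2])
  with_data(volume, array(out, dim = dim(x)))
}

#' Contrast enhancement pipeline
#'
#' Composition of [normalize_intensity()], [rescale_range()] (to
#' `[1, 255]`) and [equalize_histogram()]. The result is the input the
#' segmentation models are trained on, and the image the label-construction
#' binarization operates on.
#'
#' @param volume an `intensity_volume`.
#' @param equalize set `FALSE` to skip histogram equalization.
#' @param n_bins bins passed to [equalize_histogram()].
#' @return The contrast-enhanced `intensity_volume`, range within
#'   `[1, 255]`.
#' @examples
#' s <- generate_phantom(phantom_params(seed = 2))
#' e <- enhance_contrast(s$volume)
#' range(e$data)
#' @export
enhance_contrast <- function(volume, equalize = TRUE, n_bins = 256) {
  out <- rescale_range(normalize_intensity(volume), 1, 255)
  if (equalize) out <- equalize_histogram(out, n_bins) else out
}

#' Crop a volume to the bounding box of a mask
#'
#' Computes the tight bounding box of the mask, dilates it by `margin`
#' voxels on every side, clips it to the grid and optionally grows it (still
#' within the grid) so each side length is a multiple of `pad_multiple` --
#' with four pooling halvings the network needs sides divisible by 16.
#' Returns the cropped volume together with the box so predictions can be
#' embedded back into the original grid.
#'
#' @param volume an `intensity_volume` (or `binary_mask`).
#' @param mask a nonempty `binary_mask` on the same grid.
#' @param margin non-negative margin in voxels (default 4).
#' @param pad_multiple if > 0, grow the box so sides are multiples of this.
#' @return A list with `volume` (cropped, same class as input) and `box`
#'   (a `crop_box`: 0-based inclusive `lower`, exclusive `upper`,
#'   `margin`, and the original `grid`).
#' @export
crop_to_mask <- function(volume, mask, margin = 4, pad_multiple = 0) {
  stop_if_mismatch(volume, mask, "volume and mask")
  m <- vol_data(mask)
  if (sum(m) == 0) stop("cannot crop to an empty mask")
  idx <- which(m == 1L, arr.ind = TRUE)
  lower <- apply(idx, 2, min) - 1L  # 0-based inclusive
  upper <- apply(idx, 2, max)      # 0-based exclusive = max 1-based index
  grid <- dim(m)
  lower <- pmax(lower - margin, 0L)
  upper <- pmin(upper + margin, grid)
  if (pad_multiple > 0) {
    for (d in 1:3) {
      need <- (pad_multiple - (upper[d] - lower[d]) %% pad_multiple) %%
        pad_multiple
      if (need > 0) {
        if (upper[d] - lower[d] + need > grid[d]) {
          stop(sprintf(
            "grid dimension %d (%d) too small to pad the crop to a multiple of %d; pad the input volume first",
            d, grid[d], pad_multiple))
        }
        grow_hi <- min(need, grid[d] - upper[d])
        upper[d] <- upper[d] + grow_hi
        lower[d] <- lower[d] - (need - grow_hi)
      }
    }
  }
  box <- structure(list(lower = as.integer(lower), upper = as.integer(upper),
                        margin = as.integer(margin), grid = as.integer(grid)),
                   class = "crop_box")
  x <- vol_data(volume)
  cropped <- x[(lower[1] + 1):upper[1],
               (lower[2] + 1):upper[2],
               (lower[3] + 1):upper[3], drop = FALSE]
  out <- if (inherits(volume, "binary_mask")) {
    binary_mask(cropped, volume$spacing, volume$affine)
  } else if (inherits(volume, "intensity_volume")) {
    intensity_volume(cropped, volume$spacing, volume$affine)
  } else {
    cropped
  }
  list(volume = out, box = box)
}

#' Embed a cropped volume back into its original grid
#'
#' Inverse of [crop_to_mask()]: places the cropped data at the recorded
#' `crop_box`, filling voxels outside the box with `fill`.
#'
#' @param cropped cropped `intensity_volume`/`binary_mask` or array.
#' @param box the `crop_box` returned by [crop_to_mask()].
#' @param fill value outside the box (default 0).
#' @return An array with the original grid dimensions.
#' @export
uncrop <- function(cropped, box, fill = 0) {
  x <- vol_data(cropped)
  expect <- box$upper - box$lower
  if (!all(dim(x) == expect)) {
    stop("cropped data does not match the crop box dimensions")
  }
  out <- array(fill, dim = box$grid)
  out[(box$lower[1] + 1):box$upper[1],
      (box$lower[2] + 1):box$upper[2],
      (box$lower[3] + 1):box$upper[3]] <- x
  out
}

#' @export
print.crop_box <- function(x, ...) {
  cat("<crop_box> [", paste(x$lower, collapse = ","), ") -> [",
      paste(x$upper, collapse = ","), ") of grid ",
      paste(x$grid, collapse = "x"), "\n", sep = "")
  invisible(x)
}
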