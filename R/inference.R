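#' Segment a preprocessed volume
#'
#' Runs a trained model on a contrast-enhanced (and, if needed, cropped or
#' padded) volume. The volume is expected in the `[1, 255]` enhanced range;
#' it is scaled to `[0, 1]` before the forward pass, mirroring training.
#' Probabilities are binarized at `threshold` (default 0.5).
#'
#' @param model an `inception_unet` (e.g. `train_model(...)$best_model`).
#' @param volume `intensity_volume` or 3D array with sides divisible
#'   by 16.
#' @param threshold probability cut for the binary mask.
#' @param crop_box optional `crop_box`; when given it is stored in the
#'   result so the prediction can be embedded back into the original grid
#'   with [uncrop()].
#' @return A `prediction` list with `probabilities` (3D array in
#'   `[0, 1]`), `mask` (`binary_mask`), `threshold`, `crop_box`.
#' @export
segment <- function(model, volume, threshold = 0.5, crop_box = NULL) {
  x <- vol_data(volume) / 255
  prob <- unet_forward(model, x, training = FALSE)
  prob <- array(prob, dim = dim(prob)[1:3])
  mask <- binary_mask(array(as.integer(prob > threshold), dim = dim(prob)))
  structure(list(probabilities = prob, mask = mask, threshold = threshold,
                 crop_box = crop_box),
            class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat("<prediction> ", paste(dim(x$probabilities), collapse = " x "),
      " voxels, ", sum(x$mask$data), " foreground at cut ", x$threshold,
      "\n", sep = "")
  invisible(x)
}

#' Keep only the largest connected component
#'
#' Postprocessing for the tissue and whole-cerebellum models: zeroes every
#' voxel outside the largest connected component of the mask. Components
#' are found at the given connectivity (default 26); ties are broken
#' deterministically toward the component first reached in voxel scan
#' order. The fissure model is evaluated without this step, since fissures
#' are legitimately made of many components. An empty mask is returned
#' unchanged with a warning.
#'
#' @param mask a `binary_mask`.
#' @param connectivity 6, 18 or 26 (neighbors sharing a face, edge or
#'   corner).
#' @return The filtered `binary_mask`.
#' @export
largest_component <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26)) {
    stop("connectivity must be 6, 18 or 26")
  }
  m <- vol_data(mask)
  if (sum(m) == 0) {
    warning("mask is empty; nothing to filter")
    return(mask)
  }
  lab <- cc_label_cpp(as.integer(m), dim(m), as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- which.max(sizes)  # ties -> lowest label = first in scan order
  with_data(mask, array(as.integer(lab == keep), dim = dim(m)), mask = TRUE)
}

#' Derive a fissure mask from the tissue and whole-cerebellum predictions
#'
#' Utility combining two model outputs: voxels predicted as cerebellum
#' (with fissures) but not as fissure-free tissue. Exploratory only -- the
#' validated fissure path is the directly trained fissure model.
#'
#' @param whole_pred,tissue_pred `binary_mask` predictions on one grid.
#' @return A `binary_mask`.
#' @export
fissures_from_difference <- function(whole_pred, tissue_pred) {
  stop_if_mismatch(whole_pred, tissue_pred, "predictions")
  with_data(whole_pred,
            vol_data(whole_pred) == 1L & vol_data(tissue_pred) == 0L,
            mask = TRUE)
}
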