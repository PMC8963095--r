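#' Read a NIfTI volume
#'
#' Loads a NIfTI-1/NIfTI-2 file (plain or gzipped) into an
#' `intensity_volume` or, with `as_mask = TRUE`, a validated
#' `binary_mask` (any value other than 0/1 is rejected).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as_mask validate and return as a `binary_mask`?
#' @return An `intensity_volume` or `binary_mask`.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 3) {
    stop(sprintf("expected a 3D volume, got %d dimensions",
                 length(dim(data))))
  }
  spacing <- RNifti::pixdim(img)[1:3]
  affine <- unclass(RNifti::xform(img))
  if (as_mask) {
    if (!all(data %in% c(0, 1))) {
      stop(sprintf("mask file %s contains values other than 0/1", path))
    }
    binary_mask(array(as.integer(data), dim = dim(data)), spacing, affine)
  } else {
    intensity_volume(data, spacing, affine)
  }
}

#' Write a volume or mask as NIfTI
#'
#' Masks are written as unsigned 8-bit integers, intensity volumes as
#' 32-bit floats; the object's affine and spacing go into the header.
#' Refuses to overwrite an existing file unless `force = TRUE`.
#'
#' @param x an `intensity_volume` or `binary_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param force overwrite an existing file?
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, force = FALSE) {
  if (file.exists(path) && !force) {
    stop(sprintf("%s exists; use force = TRUE to overwrite", path))
  }
  is_mask <- inherits(x, "binary_mask")
  aff <- x$affine
  img <- RNifti::asNifti(vol_data(x) * 1.0, list(
    qform_code = 2L, sform_code = 2L,
    srow_x = aff[1, ], srow_y = aff[2, ], srow_z = aff[3, ],
    pixdim = c(1, x$spacing, 1, 0, 0, 0)))
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

#' Serialize a crop box to JSON
#'
#' @param box a `crop_box`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_crop_box <- function(box, path) {
  jsonlite::write_json(list(lower = box$lower, upper = box$upper,
                            margin = box$margin, grid = box$grid),
                       path)
  invisible(path)
}

#' @rdname write_crop_box
#' @export
read_crop_box <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(lower = as.integer(b$lower), upper = as.integer(b$upper),
                 margin = as.integer(b$margin), grid = as.integer(b$grid)),
            class = "crop_box")
}

#' Save / load trained model weights
#'
#' Weights are stored as a plain JSON dictionary of flattened arrays plus
#' their dimensions, so checkpoints are portable text files.
#'
#' @param model an `inception_unet`.
#' @param path output `.json` path.
#' @return `save_weights`: the path, invisibly. `load_weights`: the model
#'   with weights replaced.
#' @export
save_weights <- function(model, path) {
  payload <- list(
    spec = unclass(model$spec),
    params = lapply(model$params, function(p) {
      list(dim = if (is.null(dim(p))) length(p) else dim(p),
           data = as.numeric(p))
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(arch_spec, payload$spec[c(
    "encoder_filters", "decoder_filters", "dropout_rate", "spatial_rank",
    "input_channels", "output_channels")])
  model <- build_unet(spec)
  for (nm in names(model$params)) {
    p <- payload$params[[nm]]
    if (is.null(p)) stop(sprintf("checkpoint is missing parameter %s", nm))
    a <- as.numeric(p$data)
    if (length(p$dim) > 1) dim(a) <- p$dim
    model$params[[nm]] <- a
  }
  model
}
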