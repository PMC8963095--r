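#' 3D intensity volumes and binary masks
#'
#' Lightweight containers used throughout the pipeline. An
#' `intensity_volume` holds a 3D numeric array together with its voxel
#' spacing (mm) and a 4x4 affine that maps voxel indices to world
#' coordinates; a `binary_mask` holds a congruent 0/1 array. The affine is
#' the sole authority for world coordinates; voxel indices are 0-based in
#' all box arithmetic (see [crop_to_mask()]).
#'
#' @param data 3D numeric array (for masks: values in \{0, 1\}; logical
#'   arrays are accepted and coerced).
#' @param spacing positive numeric triple, voxel size in mm.
#' @param affine 4x4 numeric matrix mapping voxel to world coordinates.
#' @return An object of class `intensity_volume` or `binary_mask`: a list
#'   with elements `data`, `spacing`, `affine`.
#' @examples
#' v <- intensity_volume(array(rnorm(8^3), dim = c(8, 8, 8)))
#' m <- binary_mask(v$data > 0)
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1), affine = diag(4)) {
  data <- as_array3d(data)
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  check_geometry(spacing, affine)
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "intensity_volume")
}

#' @rdname intensity_volume
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = diag(4)) {
  data <- as_array3d(data)
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  }
  if (!all(data %in% c(0L, 1L))) {
    stop("mask values must be 0 or 1")
  }
  storage.mode(data) <- "integer"
  check_geometry(spacing, affine)
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "binary_mask")
}

as_array3d <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3) {
    stop("data must be a 3D array")
  }
  data
}

check_geometry <- function(spacing, affine) {
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be a positive numeric triple")
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4))) {
    stop("affine must be a 4x4 matrix")
  }
  invisible(TRUE)
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat("<intensity_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = "/"),
      " mm, range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

# data accessor tolerant of raw arrays, used by functions that accept either
vol_data <- function(x) {
  if (is.list(x) && !is.null(x$data)) x$data else as_array3d(x)
}

same_grid <- function(a, b) {
  identical(dim(vol_data(a)), dim(vol_data(b)))
}

stop_if_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) {
    stop(sprintf("%s are defined on different grids (%s vs %s)", what,
                 paste(dim(vol_data(a)), collapse = "x"),
                 paste(dim(vol_data(b)), collapse = "x")))
  }
  invisible(TRUE)
}

# carry geometry from a template onto a new data array
with_data <- function(template, data, mask = FALSE) {
  if (mask) {
    binary_mask(data, template$spacing, template$affine)
  } else {
    intensity_volume(data, template$spacing, template$affine)
  }
}

#' Bundle the three training label maps
#'
#' The label-construction procedure produces three congruent binary masks:
#' the whole cerebellum, the fissures inside it, and the tissue with the
#' fissures carved out. By construction `fissures` and `tissue` partition
#' `whole`: their union equals `whole` and their intersection is empty.
#'
#' @param whole,fissures,tissue `binary_mask` objects on one grid.
#' @return A `mask_triplet`: list with elements `whole`, `fissures`,
#'   `tissue`.
#' @export
mask_triplet <- function(whole, fissures, tissue) {
  stop_if_mismatch(whole, fissures, "whole/fissures")
  stop_if_mismatch(whole, tissue, "whole/tissue")
  w <- vol_data(whole); f <- vol_data(fissures); t <- vol_data(tissue)
  if (any(f & t)) stop("fissures and tissue overlap")
  if (!all((f | t) == (w > 0))) stop("fissures and tissue do not partition whole")
  structure(list(whole = whole, fissures = fissures, tissue = tissue),
            class = "mask_triplet")
}

#' @export
print.mask_triplet <- function(x, ...) {
  cat("<mask_triplet> whole:", sum(x$whole$data),
      "fissures:", sum(x$fissures$data),
      "tissue:", sum(x$tissue$data), "voxels\n")
  invisible(x)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
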