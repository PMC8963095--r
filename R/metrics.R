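#' Voxelwise confusion counts
#'
#' 2x2 contingency counts between a predicted and a ground-truth binary
#' mask on one grid: TP and TN are the correctly recognized foreground and
#' background voxels, FP and FN the incorrectly identified ones.
#'
#' @param prediction,truth `binary_mask` objects (or 0/1 arrays) on the
#'   same grid.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(prediction, truth) {
  stop_if_mismatch(prediction, truth, "prediction and truth")
  p <- vol_data(prediction) > 0
  g <- vol_data(truth) > 0
  structure(list(TP = sum(p & g), TN = sum(!p & !g),
                 FP = sum(p & !g), FN = sum(!p & g)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("TP", x$TP, " TN", x$TN, " FP", x$FP, " FN", x$FN, "\n")
  invisible(x)
}

#' Dice score
#'
#' `2 * sum(p * g) / (sum(p^2) + sum(g^2))`; on binary masks this equals
#' the cardinality form `2TP / (2TP + FP + FN)`. Two empty masks are in
#' perfect agreement, so that case is defined as 1 (with a warning).
#'
#' @inheritParams confusion_counts
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(prediction, truth) {
  stop_if_mismatch(prediction, truth, "prediction and truth")
  p <- as.numeric(vol_data(prediction))
  g <- as.numeric(vol_data(truth))
  den <- sum(p^2) + sum(g^2)
  if (den == 0) {
    warning("both masks are empty; Dice defined as 1")
    return(1)
  }
  2 * sum(p * g) / den
}

#' Overlap coefficient
#'
#' `sum(p * g) / min(sum(p), sum(g))`: 1 when one mask contains the other,
#' 0 for disjoint masks. Undefined (error) if either mask is empty.
#'
#' @inheritParams confusion_counts
#' @return Overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(prediction, truth) {
  stop_if_mismatch(prediction, truth, "prediction and truth")
  p <- as.numeric(vol_data(prediction))
  g <- as.numeric(vol_data(truth))
  sp <- sum(p); sg <- sum(g)
  if (sp == 0 || sg == 0) {
    stop("overlap coefficient is undefined for an empty mask")
  }
  sum(p * g) / min(sp, sg)
}

#' Specificity (true negative rate)
#'
#' `TN / (FP + TN)`: the proportion of background voxels recognized as
#' background.
#'
#' @param counts a [confusion_counts()] object.
#' @return Specificity in `[0, 1]`.
#' @export
specificity <- function(counts) {
  if (counts$FP + counts$TN == 0) {
    stop("specificity is undefined without negative voxels")
  }
  counts$TN / (counts$FP + counts$TN)
}

#' Sensitivity (true positive rate)
#'
#' `TP / (TP + FN)`: the proportion of ground-truth voxels recovered.
#'
#' @param counts a [confusion_counts()] object.
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity <- function(counts) {
  if (counts$TP + counts$FN == 0) {
    stop("sensitivity is undefined for an empty ground truth")
  }
  counts$TP / (counts$TP + counts$FN)
}

#' Balanced-accuracy AUC
#'
#' `1 - (FPR + FNR) / 2`, the closed-form area under the ROC curve of a
#' hard classifier; algebraically equal to `(sensitivity + specificity)/2`.
#' This is the closed form, not a threshold-sweep ROC integration.
#'
#' @param counts a [confusion_counts()] object.
#' @return Value in `[0, 1]`.
#' @export
auc_balanced <- function(counts) {
  if (counts$FP + counts$TN == 0 || counts$TP + counts$FN == 0) {
    stop("balanced AUC needs both classes present in the ground truth")
  }
  1 - 0.5 * (counts$FP / (counts$FP + counts$TN) +
               counts$FN / (counts$FN + counts$TP))
}

#' Full evaluation report
#'
#' Computes Dice, overlap coefficient, specificity, sensitivity and
#' balanced AUC between a prediction and its ground truth, plus the raw
#' confusion counts. Matches calling each measure individually.
#'
#' @inheritParams confusion_counts
#' @return A `metrics_report` list with `DSC`, `OC`, `SP`, `SN`, `AUC`,
#'   `counts`.
#' @examples
#' a <- array(0L, c(4, 4, 4)); a[1:2, , ] <- 1L
#' b <- array(0L, c(4, 4, 4)); b[2:3, , ] <- 1L
#' evaluate_masks(binary_mask(a), binary_mask(b))
#' @export
evaluate_masks <- function(prediction, truth) {
  counts <- confusion_counts(prediction, truth)
  structure(list(DSC = dice(prediction, truth),
                 OC = overlap_coefficient(prediction, truth),
                 SP = specificity(counts),
                 SN = sensitivity(counts),
                 AUC = auc_balanced(counts),
                 counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("DSC %.4f  OC %.4f  SP %.4f  SN %.4f  AUC %.4f\n",
              x$DSC, x$OC, x$SP, x$SN, x$AUC))
  invisible(x)
}

#' Flatten a metrics report to a data-frame row
#'
#' Column layout mirrors the usual results tables: DSC, OC, SP, SN, AUC.
#'
#' @param report a `metrics_report`.
#' @param id optional row identifier.
#' @return One-row data frame.
#' @export
report_row <- function(report, id = NA_character_) {
  data.frame(id = id, DSC = report$DSC, OC = report$OC, SP = report$SP,
             SN = report$SN, AUC = report$AUC, stringsAsFactors = FALSE)
}
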