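## Confusion-count agreement metrics between two masks on a shared grid.
## Specificity needs a finite negative region; the paper-style pairwise design
## never defines one, so the default evaluation region is the bounding box of
## the union, dilated by a configurable physical margin.

#' Default evaluation region for specificity
#'
#' Axis-aligned bounding box of \code{test | reference}, dilated by
#' \code{margin_mm} (converted to whole voxels per axis, rounding up) and
#' clipped to the grid. True negatives are counted inside this region only,
#' making specificity well-defined and grid-size independent.
#'
#' @param test,reference [BinaryMask-class] objects on a shared grid.
#' @param margin_mm dilation margin in mm (default 20).
#' @return a [BinaryMask-class] covering the evaluation region.
#' @export
defaultEvalRegion <- function(test, reference, margin_mm = 20) {
  validateSameGrid(test, reference)
  g <- imageGrid(test)
  u <- test@voxels | reference@voxels
  if (!any(u)) .gtv_error("emptyMaskError",
                          "cannot build an evaluation region around two empty masks")
  idx <- which(u, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  pad <- ceiling(margin_mm / g@spacing)
  lo <- pmax(1L, lo - pad)
  hi <- pmin(g@shape, hi + pad)
  region <- array(FALSE, dim = g@shape)
  region[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  BinaryMask(g, region)
}

#' Voxel confusion counts between two masks
#'
#' Counts are taken over an evaluation region: \code{tp = |test & ref|},
#' \code{fp = |test & !ref|}, \code{fn = |ref & !test|},
#' \code{tn = |region & !test & !ref|}. Both masks must be contained in the
#' region.
#'
#' @param test [BinaryMask-class]: the observer being evaluated.
#' @param reference [BinaryMask-class]: the comparator.
#' @param eval_region [BinaryMask-class] or NULL for
#'   [defaultEvalRegion()] with \code{margin_mm}.
#' @param margin_mm margin for the default region (mm).
#' @return list of class \code{ConfusionCounts}: \code{tp, fp, fn, tn,
#'   eval_region_size}, with \code{tp+fp+fn+tn == eval_region_size}.
#' @export
confusionCounts <- function(test, reference, eval_region = NULL, margin_mm = 20) {
  validateSameGrid(test, reference)
  if (is.null(eval_region)) eval_region <- defaultEvalRegion(test, reference, margin_mm)
  validateSameGrid(test, eval_region)
  t <- test@voxels; r <- reference@voxels; e <- eval_region@voxels
  if (any(t & !e) || any(r & !e))
    .gtv_error("containmentError",
               "test and reference masks must be contained in the evaluation region")
  counts <- list(tp = sum(t & r), fp = sum(t & !r), fn = sum(r & !t),
                 tn = sum(e & !t & !r), eval_region_size = sum(e))
  class(counts) <- "ConfusionCounts"
  counts
}

#' Agreement metrics from confusion counts
#'
#' DSC \code{= 2tp/(2tp+fp+fn)}, precision \code{= tp/(tp+fp)}, sensitivity
#' \code{= tp/(tp+fn)}, specificity \code{= tn/(tn+fp)}. A 0/0 case yields
#' \code{NA} (an explicit undefined flag, excluded from downstream means),
#' never a silent 0 or 1.
#'
#' @param counts a \code{ConfusionCounts} list (from [confusionCounts()]).
#' @return list of class \code{AgreementMetrics}: \code{dsc, precision,
#'   sensitivity, specificity}, each in \code{[0,1]} or \code{NA}.
#' @export
agreementMetrics <- function(counts) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, structure(list(
    dsc = ratio(2 * tp, 2 * tp + fp + fn),
    precision = ratio(tp, tp + fp),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp)
  ), class = "AgreementMetrics"))
}

#' Agreement metrics between two masks (convenience)
#'
#' @inheritParams confusionCounts
#' @return an \code{AgreementMetrics} list.
#' @export
maskAgreement <- function(test, reference, eval_region = NULL, margin_mm = 20) {
  agreementMetrics(confusionCounts(test, reference, eval_region, margin_mm))
}
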