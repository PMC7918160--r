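## Background-relative SUV-threshold automatic GTV generation.
## A background SUV is quantified in a healthy-tissue ROI; voxels with
## SUV >= multiplier * background (inclusive) form candidate GTVs, cleaned by
## 26-connected component filtering and optional replayable edits standing in
## for manual plausibility correction.

#' Define a background region of interest
#'
#' @param shape \code{"sphere"} or \code{"box"}.
#' @param center world position of the ROI center (mm).
#' @param size radius in mm (sphere) or half-extent triple in mm (box).
#' @return a \code{BackgroundROI} list.
#' @export
backgroundROI <- function(shape = c("sphere", "box"), center, size) {
  shape <- match.arg(shape)
  center <- as.numeric(center)
  size <- as.numeric(size)
  stopifnot(length(center) == 3, all(is.finite(center)), all(size > 0))
  if (shape == "sphere") stopifnot(length(size) == 1)
  if (shape == "box" && length(size) == 1) size <- rep(size, 3)
  structure(list(shape = shape, center = center, size = size),
            class = "BackgroundROI")
}

## logical array of voxels whose centers fall inside the ROI geometry
.roi_voxels <- function(grid, roi) {
  n <- grid@shape
  ax <- lapply(1:3, function(a) grid@origin[a] + (seq_len(n[a]) - 1) * grid@spacing[a])
  if (roi$shape == "sphere") {
    d2 <- outer(outer((ax[[1]] - roi$center[1])^2, (ax[[2]] - roi$center[2])^2, "+"),
                (ax[[3]] - roi$center[3])^2, "+")
    d2 <= roi$size^2
  } else {
    inx <- abs(ax[[1]] - roi$center[1]) <= roi$size[1]
    iny <- abs(ax[[2]] - roi$center[2]) <= roi$size[2]
    inz <- abs(ax[[3]] - roi$center[3]) <= roi$size[3]
    outer(outer(inx, iny, "&"), inz, "&")
  }
}

#' Background SUV in a healthy-tissue ROI
#'
#' Arithmetic mean of the SUVs at voxels whose centers fall inside the ROI
#' geometry (the median is available as an alternative statistic).
#'
#' @param image an [SUVImage-class].
#' @param roi a [backgroundROI()].
#' @param statistic \code{"mean"} (default) or \code{"median"}.
#' @return positive scalar background SUV.
#' @export
backgroundSUV <- function(image, roi, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  g <- imageGrid(image)
  lo <- roi$center - max(roi$size); hi <- roi$center + max(roi$size)
  gmin <- g@origin - g@spacing / 2
  gmax <- g@origin + (g@shape - 1) * g@spacing + g@spacing / 2
  if (any(lo < gmin) || any(hi > gmax))
    .gtv_error("roiOutsideGridError", "background ROI extends outside the image grid")
  inside <- .roi_voxels(g, roi)
  nvox <- sum(inside)
  if (nvox < 10)
    .gtv_error("degenerateBackgroundError",
               sprintf("background ROI covers only %d voxels (>= 10 required)", nvox))
  b <- if (statistic == "mean") mean(image@values[inside]) else median(image@values[inside])
  if (b <= 0)
    .gtv_error("degenerateBackgroundError", "background SUV is not positive")
  b
}

#' Threshold specification for automatic GTV generation
#'
#' @param background_suv positive scalar background SUV.
#' @param multipliers strictly increasing threshold multipliers, each > 1
#'   (default \code{c(1.5, 2, 2.5)}).
#' @param search_region optional [BinaryMask-class]; thresholding is
#'   restricted to it and components not intersecting it are dropped.
#' @param min_component_ccm minimum connected-component volume kept (ccm,
#'   default 0.1, suppressing single-voxel noise components).
#' @return a \code{ThresholdSpec} list.
#' @export
thresholdSpec <- function(background_suv, multipliers = c(1.5, 2, 2.5),
                          search_region = NULL, min_component_ccm = 0.1) {
  stopifnot(is.numeric(background_suv), length(background_suv) == 1)
  if (background_suv <= 0)
    .gtv_error("degenerateBackgroundError", "background SUV must be positive")
  stopifnot(all(multipliers > 1), all(diff(multipliers) > 0),
            min_component_ccm >= 0)
  structure(list(background_suv = background_suv, multipliers = multipliers,
                 search_region = search_region,
                 min_component_ccm = min_component_ccm),
            class = "ThresholdSpec")
}

#' Label 26-connected components of a mask
#'
#' @param mask a [BinaryMask-class].
#' @return integer array of component labels (0 = background).
#' @export
connectedComponents <- function(mask) {
  lab <- .cc_label_26(as.logical(mask@voxels), imageGrid(mask)@shape)
  array(lab, dim = imageGrid(mask)@shape)
}

## drop components smaller than min_ccm; keep only those meeting `keep_fun`
.filter_components <- function(voxels, grid, min_ccm, intersect_region = NULL) {
  if (!any(voxels)) return(voxels)
  lab <- array(.cc_label_26(as.logical(voxels), grid@shape), dim = grid@shape)
  sizes <- tabulate(lab[lab > 0L])
  vox_ccm <- prod(grid@spacing) / 1000
  keep <- sizes * vox_ccm >= min_ccm
  if (!is.null(intersect_region)) {
    touches <- unique(lab[lab > 0L & intersect_region])
    keep <- keep & (seq_along(sizes) %in% touches)
  }
  if (all(keep)) return(voxels & TRUE)
  lab > 0L & keep[pmax(lab, 1L)]
}

#' Automatic GTV at one background-relative threshold
#'
#' Selects voxels with \code{SUV >= multiplier * background_suv} (inclusive),
#' intersects with the search region when given, labels 26-connected
#' components, removes components smaller than \code{min_component_ccm}, and
#' (with a search region) removes components not intersecting it. The result
#' may be empty.
#'
#' @param image an [SUVImage-class].
#' @param spec a [thresholdSpec()].
#' @param multiplier one of \code{spec$multipliers}.
#' @return a [BinaryMask-class].
#' @export
thresholdGTV <- function(image, spec, multiplier) {
  stopifnot(multiplier %in% spec$multipliers)
  g <- imageGrid(image)
  v <- image@values >= multiplier * spec$background_suv
  region <- NULL
  if (!is.null(spec$search_region)) {
    validateSameGrid(image, spec$search_region)
    region <- spec$search_region@voxels
    v <- v & region
  }
  v <- .filter_components(v, g, spec$min_component_ccm, intersect_region = region)
  BinaryMask(g, array(v, dim = g@shape))
}

#' Replayable edit list for plausibility correction
#'
#' Manual correction of false positive/negative tracer avidity is modeled as
#' an explicit ordered list of edits so that runs are reproducible. Each edit
#' is one of:
#' \itemize{
#'   \item \code{list(op = "remove_component", seed = <world mm triple>)} —
#'     delete the 26-connected component containing the seed;
#'   \item \code{list(op = "add_component", seed = <world mm>, donor =
#'     <BinaryMask>)} — union in the donor-mask component containing the seed;
#'   \item \code{list(op = "subtract_mask", mask = <BinaryMask>)}.
#' }
#'
#' @param ... edits in application order.
#' @return an \code{EditList}.
#' @export
editList <- function(...) {
  edits <- list(...)
  for (e in edits) stopifnot(is.list(e),
    e$op %in% c("remove_component", "add_component", "subtract_mask"))
  structure(edits, class = "EditList")
}

## component (logical array) of `voxels` containing world-point seed, or NULL
.component_at <- function(voxels, grid, seed) {
  idx <- worldToVoxel(grid, matrix(seed, ncol = 3))
  if (any(idx < 1) || any(idx > matrix(grid@shape, ncol = 3)))
    .gtv_error("seedOutsideGridError", "edit seed lies outside the grid")
  lab <- array(.cc_label_26(as.logical(voxels), grid@shape), dim = grid@shape)
  l <- lab[idx[1], idx[2], idx[3]]
  if (l == 0L) return(NULL)
  lab == l
}

#' Apply an edit list to a mask
#'
#' Edits are applied in order; re-application is idempotent. A remove edit
#' whose seed hits no component is a no-op with a warning, not an error.
#'
#' @param mask a [BinaryMask-class].
#' @param edits an [editList()] (empty list allowed).
#' @return the edited [BinaryMask-class].
#' @export
applyEdits <- function(mask, edits) {
  if (length(edits) == 0) return(mask)
  g <- imageGrid(mask)
  v <- mask@voxels
  for (e in edits) {
    if (e$op == "remove_component") {
      comp <- .component_at(v, g, as.numeric(e$seed))
      if (is.null(comp)) {
        warning("remove_component seed hits no component; edit skipped")
      } else v <- v & !comp
    } else if (e$op == "add_component") {
      validateSameGrid(mask, e$donor)
      comp <- .component_at(e$donor@voxels, g, as.numeric(e$seed))
      if (is.null(comp)) {
        warning("add_component seed hits no donor component; edit skipped")
      } else v <- v | comp
    } else if (e$op == "subtract_mask") {
      validateSameGrid(mask, e$mask)
      v <- v & !e$mask@voxels
    }
  }
  BinaryMask(g, v)
}

#' Generate the full set of threshold GTVs
#'
#' One mask per multiplier, produced by [thresholdGTV()] followed by
#' [applyEdits()]. Before edits the masks are nested (a higher multiplier's
#' mask is a subset of a lower one's).
#'
#' @param image an [SUVImage-class].
#' @param roi a [backgroundROI()] used to quantify the background, or NULL if
#'   \code{spec} already carries a measured background.
#' @param spec a [thresholdSpec()]; when \code{roi} is given its
#'   \code{background_suv} is replaced by the measured value.
#' @param edits optional [editList()] applied to every mask.
#' @return named list of [BinaryMask-class], names = multipliers.
#' @export
generateFapiGTVs <- function(image, roi = NULL, spec, edits = NULL) {
  if (!is.null(roi)) {
    b <- backgroundSUV(image, roi)
    spec <- thresholdSpec(b, spec$multipliers, spec$search_region,
                          spec$min_component_ccm)
  }
  out <- lapply(spec$multipliers, function(m) {
    mask <- thresholdGTV(image, spec, m)
    if (!is.null(edits)) mask <- applyEdits(mask, edits) else mask
  })
  names(out) <- as.character(spec$multipliers)
  out
}
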