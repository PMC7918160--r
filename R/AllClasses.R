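#' @useDynLib gtvAgree, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new is validObject setClass setGeneric setMethod setValidity show slot representation slotNames
#' @importFrom stats rnorm runif sd median pf wilcox.test uniroot setNames p.adjust
#' @importFrom utils write.csv read.csv
NULL

#' ImageGrid: axis-aligned voxel lattice geometry
#'
#' Describes the geometry shared by all volumes of one case: the number of
#' voxels along each axis, the physical voxel spacing in mm, and the world
#' position in mm of the \emph{center} of voxel (1,1,1) (1-based R indices).
#' The world position of voxel (i,j,k) is
#' \code{origin + (c(i,j,k) - 1) * spacing}, componentwise; no rotation is
#' represented (only axis-aligned grids are supported).
#'
#' @slot shape integer(3), voxel counts per axis, each >= 1.
#' @slot spacing numeric(3), voxel spacing in mm, each > 0.
#' @slot origin numeric(3), world coordinates (mm) of the first voxel center.
#' @seealso [ImageGrid()] for the constructor, [validateSameGrid()]
#' @export
setClass("ImageGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"))

setValidity("ImageGrid", function(object) {
  msg <- NULL
  if (length(object@shape) != 3L) msg <- c(msg, "shape must have length 3")
  if (length(object@spacing) != 3L) msg <- c(msg, "spacing must have length 3")
  if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
  if (is.null(msg)) {
    if (any(object@shape < 1L)) msg <- c(msg, "all shape components must be >= 1")
    if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
      msg <- c(msg, "all spacing components must be finite and > 0")
    if (any(!is.finite(object@origin))) msg <- c(msg, "origin must be finite")
  }
  if (is.null(msg)) TRUE else msg
})

#' SUVImage: scalar standardized-uptake-value volume on a grid
#'
#' @slot grid an [ImageGrid-class].
#' @slot values 3-D numeric array of SUVs (dimensionless), finite and >= 0,
#'   with \code{dim(values)} equal to the grid shape.
#' @export
setClass("SUVImage", representation(grid = "ImageGrid", values = "array"))

setValidity("SUVImage", function(object) {
  msg <- NULL
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, "values array shape must equal grid shape")
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  else {
    if (any(!is.finite(object@values))) msg <- c(msg, "all values must be finite")
    else if (any(object@values < 0)) msg <- c(msg, "all values must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' BinaryMask: boolean contour volume on a grid
#'
#' A voxelized structure (e.g. a gross tumor volume) as one logical flag per
#' voxel of its [ImageGrid-class]. An all-false (empty) mask is legal.
#'
#' @slot grid an [ImageGrid-class].
#' @slot voxels 3-D logical array with \code{dim} equal to the grid shape.
#' @export
setClass("BinaryMask", representation(grid = "ImageGrid", voxels = "array"))

setValidity("BinaryMask", function(object) {
  msg <- NULL
  if (!identical(dim(object@voxels), as.integer(object@grid@shape)))
    msg <- c(msg, "voxels array shape must equal grid shape")
  if (!is.logical(object@voxels)) msg <- c(msg, "voxels must be logical")
  else if (anyNA(object@voxels)) msg <- c(msg, "voxels must not contain NA")
  if (is.null(msg)) TRUE else msg
})

#' StructureSet: all contours of one patient on a common grid
#'
#' Holds the manual observer masks and the automatically generated
#' threshold masks of one patient. All member masks must share an identical
#' grid; at least one manual mask is required.
#'
#' @slot patientId character(1) label.
#' @slot manual named list of [BinaryMask-class], one per observer.
#' @slot auto named list of [BinaryMask-class], one per threshold multiplier
#'   (names are the multiplier values, e.g. \code{"2"}); may be empty.
#' @export
setClass("StructureSet",
  representation(patientId = "character", manual = "list", auto = "list"))

setValidity("StructureSet", function(object) {
  msg <- NULL
  if (length(object@patientId) != 1L) msg <- c(msg, "patientId must be a single label")
  if (length(object@manual) < 1L) msg <- c(msg, "at least one manual mask is required")
  all_masks <- c(object@manual, object@auto)
  if (!all(vapply(all_masks, is, logical(1), "BinaryMask")))
    msg <- c(msg, "all members must be BinaryMask objects")
  else if (length(all_masks) > 1L) {
    g0 <- all_masks[[1L]]@grid
    for (m in all_masks[-1L]) {
      chk <- .same_grid_check(g0, m@grid)
      if (!isTRUE(chk)) { msg <- c(msg, paste0("masks on differing grids: ", chk)); break }
    }
  }
  if (length(object@manual) && is.null(names(object@manual)))
    msg <- c(msg, "manual masks must be named by observer")
  if (is.null(msg)) TRUE else msg
})

#' RigidTransform: rotation + translation between world spaces
#'
#' Maps PET-space world points (mm) to planning-CT-space world points:
#' \code{y = rotation \%*\% x + translation}.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3) in mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  msg <- NULL
  R <- object@rotation
  if (!identical(dim(R), c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      msg <- c(msg, "rotation must be orthonormal (R'R = I within 1e-9)")
    if (abs(det(R) - 1) > 1e-9) msg <- c(msg, "rotation must have det +1 within 1e-9")
  }
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    msg <- c(msg, "translation must be a finite mm triple")
  if (is.null(msg)) TRUE else msg
})
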