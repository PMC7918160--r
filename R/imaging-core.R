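## Voxel-grid data model, NIfTI I/O and volume measurement.
## Coordinate convention: 1-based voxel indices in R; the world position (mm)
## of voxel (i,j,k) is origin + (c(i,j,k)-1)*spacing (axis-aligned, voxel
## CENTER semantics, matching NIfTI center-of-voxel xforms).

## structured condition helper: all package errors carry a subclass so that
## callers (and tests) can discriminate failure modes.
.gtv_error <- function(subclass, msg, call. = FALSE) {
  stop(structure(class = c(subclass, "gtvAgreeError", "error", "condition"),
                 list(message = msg, call = NULL)))
}

## TRUE, or a string naming the first differing field.
.same_grid_check <- function(a, b) {
  if (!identical(a@shape, b@shape))
    return(sprintf("shape (%s vs %s)", paste(a@shape, collapse = "x"),
                   paste(b@shape, collapse = "x")))
  if (max(abs(a@spacing - b@spacing)) > 1e-6)
    return(sprintf("spacing (%s vs %s mm)", paste(signif(a@spacing, 8), collapse = ","),
                   paste(signif(b@spacing, 8), collapse = ",")))
  if (max(abs(a@origin - b@origin)) > 1e-3)
    return(sprintf("origin (%s vs %s mm)", paste(signif(a@origin, 8), collapse = ","),
                   paste(signif(b@origin, 8), collapse = ",")))
  TRUE
}

#' Construct an ImageGrid
#'
#' @param shape integer(3): voxel counts (nx, ny, nz).
#' @param spacing numeric(3): voxel spacing in mm (default 1 mm isotropic).
#' @param origin numeric(3): world position (mm) of the first voxel center.
#' @return An [ImageGrid-class] object.
#' @examples
#' g <- ImageGrid(c(64, 64, 32), spacing = c(2, 2, 3))
#' @export
ImageGrid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageGrid", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct an SUVImage
#' @param grid an [ImageGrid-class].
#' @param values numeric 3-D array of SUVs matching the grid shape.
#' @export
SUVImage <- function(grid, values) {
  storage.mode(values) <- "double"
  new("SUVImage", grid = grid, values = values)
}

#' Construct a BinaryMask
#' @param grid an [ImageGrid-class].
#' @param voxels logical (or coercible 0/1) 3-D array matching the grid shape.
#' @export
BinaryMask <- function(grid, voxels) {
  if (!is.logical(voxels)) {
    v <- array(voxels != 0, dim = dim(voxels))
    voxels <- v
  }
  new("BinaryMask", grid = grid, voxels = voxels)
}

#' Construct a StructureSet
#' @param patientId character(1) patient label.
#' @param manual named list of observer [BinaryMask-class] objects.
#' @param auto named list of threshold-multiplier masks (may be empty).
#' @export
StructureSet <- function(patientId, manual, auto = list()) {
  new("StructureSet", patientId = as.character(patientId),
      manual = manual, auto = auto)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn ImageGrid the grid of a grid-bearing object
#' @param x a grid-bearing object
#' @export
setMethod("imageGrid", "ImageGrid", function(x) x)
#' @export
setMethod("imageGrid", "SUVImage", function(x) x@grid)
#' @export
setMethod("imageGrid", "BinaryMask", function(x) x@grid)
#' @export
setMethod("imageGrid", "StructureSet", function(x) x@manual[[1L]]@grid)

#' @export
setMethod("gridShape", "ImageGrid", function(x) x@shape)
#' @export
setMethod("gridSpacing", "ImageGrid", function(x) x@spacing)
#' @export
setMethod("gridOrigin", "ImageGrid", function(x) x@origin)
#' @export
setMethod("gridShape", "ANY", function(x) imageGrid(x)@shape)
#' @export
setMethod("gridSpacing", "ANY", function(x) imageGrid(x)@spacing)
#' @export
setMethod("gridOrigin", "ANY", function(x) imageGrid(x)@origin)

#' @export
setMethod("suvValues", "SUVImage", function(x) x@values)
#' @export
setMethod("maskVoxels", "BinaryMask", function(x) x@voxels)
#' @export
setMethod("patientId", "StructureSet", function(x) x@patientId)
#' @export
setMethod("manualMasks", "StructureSet", function(x) x@manual)
#' @export
setMethod("autoMasks", "StructureSet", function(x) x@auto)

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(object@shape, collapse = "x"),
              paste(signif(object@spacing, 4), collapse = "x"),
              paste(signif(object@origin, 4), collapse = ", ")))
})

setMethod("show", "SUVImage", function(object) {
  cat(sprintf("SUVImage: %s voxels, SUV range [%.3g, %.3g]\n",
              paste(object@grid@shape, collapse = "x"),
              min(object@values), max(object@values)))
  show(object@grid)
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d of %d voxels set, volume %.3g ccm\n",
              sum(object@voxels), length(object@voxels), volumeCcm(object)))
  show(object@grid)
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet for patient '%s': %d manual, %d auto mask(s)\n",
              object@patientId, length(object@manual), length(object@auto)))
  show(imageGrid(object))
})

## ---- geometry --------------------------------------------------------------

#' World coordinates of voxel centers
#'
#' @param grid an [ImageGrid-class].
#' @param index integer matrix (n x 3) of 1-based voxel indices.
#' @return numeric matrix (n x 3) of world positions in mm.
#' @export
voxelToWorld <- function(grid, index) {
  index <- matrix(as.numeric(index), ncol = 3)
  sweep(sweep(index - 1, 2, grid@spacing, "*"), 2, grid@origin, "+")
}

#' Nearest voxel index for world coordinates
#'
#' @param grid an [ImageGrid-class].
#' @param world numeric matrix (n x 3) of world positions in mm.
#' @return numeric matrix (n x 3) of 1-based indices (rounded to nearest voxel;
#'   may fall outside \code{1..shape}, callers must range-check).
#' @export
worldToVoxel <- function(grid, world) {
  world <- matrix(as.numeric(world), ncol = 3)
  round(sweep(sweep(world, 2, grid@origin, "-"), 2, grid@spacing, "/")) + 1
}

#' Validate that two objects share a voxel grid
#'
#' Passes iff shape matches exactly, spacing within 1e-6 mm and origin within
#' 1e-3 mm componentwise. Symmetric and reflexive.
#'
#' @param a,b grid-bearing objects ([ImageGrid-class], [SUVImage-class],
#'   [BinaryMask-class] or [StructureSet-class]).
#' @return \code{TRUE} invisibly, or signals a \code{gridMismatchError} naming
#'   the first differing field.
#' @export
validateSameGrid <- function(a, b) {
  chk <- .same_grid_check(imageGrid(a), imageGrid(b))
  if (!isTRUE(chk))
    .gtv_error("gridMismatchError", paste0("grids differ in ", chk))
  invisible(TRUE)
}

## ---- volume ----------------------------------------------------------------

#' Structure volume in ccm
#'
#' Voxel count times the voxel volume (product of the spacings in mm^3),
#' converted to ccm (cm^3). An empty mask has volume 0.
#'
#' @param x a [BinaryMask-class].
#' @return volume in ccm (numeric scalar, >= 0).
#' @examples
#' g <- ImageGrid(c(10, 10, 10))
#' m <- BinaryMask(g, array(TRUE, dim = c(10, 10, 10)))
#' volumeCcm(m)  # 1000 voxels at 1 mm^3 -> 1 ccm
#' @export
setMethod("volumeCcm", "BinaryMask", function(x) {
  sum(x@voxels) * prod(x@grid@spacing) / 1000
})

## ---- NIfTI I/O -------------------------------------------------------------

## sform for our axis-aligned grid: world = origin + index0 * spacing
.grid_sform <- function(grid) {
  m <- diag(4)
  m[1:3, 1:3] <- diag(grid@spacing, 3, 3)
  m[1:3, 4] <- grid@origin
  m
}

## Decompose a NIfTI xform into (grid, aperm permutation, flips); errors on
## oblique orientations. Returns the canonical grid plus instructions to
## rearrange the raw array into positive-diagonal axis order.
.canonicalize_xform <- function(m, dims) {
  D <- m[1:3, 1:3]
  orig <- m[1:3, 4]
  spc <- sqrt(colSums(D^2))
  if (any(spc <= 0)) .gtv_error("unsupportedOrientationError",
                                "degenerate direction matrix in NIfTI header")
  U <- sweep(D, 2, spc, "/")
  ## signed permutation of identity: one +-1 per row/column, rest ~0
  if (max(abs(abs(U) - (abs(U) > 0.5))) > 1e-6 ||
      any(colSums(abs(U) > 0.5) != 1) || any(rowSums(abs(U) > 0.5) != 1))
    .gtv_error("unsupportedOrientationError",
               "oblique (non-axis-aligned) NIfTI orientation is not supported")
  perm <- integer(3)   # perm[a] = index axis feeding world axis a
  sgn <- numeric(3)
  for (a in 1:3) {
    j <- which(abs(U[a, ]) > 0.5)
    perm[a] <- j
    sgn[a] <- sign(U[a, j])
  }
  n <- dims[perm]
  spacing <- spc[perm]
  origin <- numeric(3)
  for (a in 1:3) {
    ## world coord along axis a of the voxel that becomes index 1 after flip
    origin[a] <- orig[a] + if (sgn[a] < 0) D[a, perm[a]] * (dims[perm[a]] - 1) else 0
  }
  list(grid = ImageGrid(n, spacing, origin), perm = perm, flip = sgn < 0)
}

.apply_canonical <- function(arr, canon) {
  arr <- aperm(arr, canon$perm)
  for (a in 1:3) if (canon$flip[a]) {
    idx <- rev(seq_len(dim(arr)[a]))
    arr <- switch(a, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
                  arr[, , idx, drop = FALSE])
  }
  arr
}

#' Read a volume from a NIfTI-1 file
#'
#' Supports only axis-aligned orientations (the direction matrix must be a
#' signed permutation of the identity); axes are reorganized so that world
#' coordinates increase with voxel index along every axis. When read as a
#' mask, any nonzero voxel value becomes \code{TRUE}.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param what \code{"suv"} for an [SUVImage-class], \code{"mask"} for a
#'   [BinaryMask-class].
#' @return an [SUVImage-class] or [BinaryMask-class].
#' @export
readVolume <- function(path, what = c("suv", "mask")) {
  what <- match.arg(what)
  if (!file.exists(path))
    .gtv_error("missingFileError", paste0("no such file: ", path))
  img <- RNifti::readNifti(path)
  m <- structure(RNifti::xform(img), imagedim = NULL, code = NULL, dim = c(4L, 4L))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 3L)
    .gtv_error("unsupportedOrientationError", "only 3-D volumes are supported")
  canon <- .canonicalize_xform(unclass(m)[1:4, 1:4], dim(arr))
  arr <- .apply_canonical(arr, canon)
  if (what == "mask") BinaryMask(canon$grid, array(arr != 0, dim = dim(arr)))
  else SUVImage(canon$grid, arr)
}

#' Write a volume to a NIfTI-1 file
#'
#' Masks are serialized as unsigned 8-bit 0/1 volumes for bit-exact round
#' trips; SUV images as 64-bit floats. The sform encodes the grid spacing and
#' the center-of-voxel origin.
#'
#' @param x an [SUVImage-class] or [BinaryMask-class].
#' @param path destination path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(x, path) {
  grid <- imageGrid(x)
  if (is(x, "BinaryMask")) {
    arr <- array(as.integer(x@voxels), dim = dim(x@voxels))
    dtype <- "uint8"
  } else if (is(x, "SUVImage")) {
    arr <- x@values
    dtype <- "double"
  } else stop("x must be an SUVImage or BinaryMask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid@spacing
  RNifti::sform(img) <- structure(.grid_sform(grid), code = 2L)
  ## version 2 headers carry double-precision spacing/origin, so geometry
  ## round-trips exactly; readers accept both versions transparently
  RNifti::writeNifti(img, path, datatype = dtype, version = 2)
  invisible(path)
}

## ---- manifest --------------------------------------------------------------

#' Write a per-patient manifest
#'
#' The manifest is a JSON file listing the patient id and relative paths of
#' the SUV image, the observer masks, any auto-threshold masks and the rigid
#' PET-to-CT transform.
#'
#' @param manifest a list with elements \code{patient_id}, \code{suv_image},
#'   \code{observer_masks} (named), optional \code{auto_masks} (named),
#'   optional \code{transform}.
#' @param path destination JSON path.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(!is.null(manifest$patient_id))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a per-patient manifest
#' @param path JSON manifest path.
#' @return the manifest list.
#' @export
readManifest <- function(path) {
  if (!file.exists(path))
    .gtv_error("missingFileError", paste0("no such file: ", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Load a patient case from a manifest
#'
#' @param path manifest JSON path; relative paths resolve against its directory.
#' @return list with \code{suv} ([SUVImage-class]), \code{structures}
#'   ([StructureSet-class]) and \code{transform} ([RigidTransform-class] or
#'   NULL).
#' @export
readPatient <- function(path) {
  man <- readManifest(path)
  dir <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(dir, p)
  suv <- if (!is.null(man$suv_image)) readVolume(rel(man$suv_image), "suv") else NULL
  manual <- lapply(man$observer_masks, function(p) readVolume(rel(p), "mask"))
  auto <- if (!is.null(man$auto_masks))
    lapply(man$auto_masks, function(p) readVolume(rel(p), "mask")) else list()
  tr <- if (!is.null(man$transform)) readTransform(rel(man$transform)) else NULL
  list(suv = suv,
       structures = StructureSet(man$patient_id, manual = manual, auto = auto),
       transform = tr)
}
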