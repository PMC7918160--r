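## Surface extraction and distance-to-agreement on anisotropic grids.
## Surface = mask-true voxels with a 6-neighbourhood face exposed (the grid
## boundary counts as exposed); distances are Euclidean between surface-voxel
## CENTERS in physical mm, reported in cm. Point-to-point center distances
## carry a known upward bias of at most half a voxel diagonal relative to
## point-to-facet distances.

## logical array of face-exposed surface voxels
.surface_array <- function(v) {
  d <- dim(v)
  shift_covered <- function(axis, dir) {
    ## TRUE where the face-neighbour along +-axis exists and is mask-true
    out <- array(FALSE, dim = d)
    n <- d[axis]
    if (n < 2) return(out)
    src <- switch(axis,
      v[if (dir > 0) 2:n else 1:(n - 1), , , drop = FALSE],
      v[, if (dir > 0) 2:n else 1:(n - 1), , drop = FALSE],
      v[, , if (dir > 0) 2:n else 1:(n - 1), drop = FALSE])
    if (axis == 1) { if (dir > 0) out[1:(n - 1), , ] <- src else out[2:n, , ] <- src }
    if (axis == 2) { if (dir > 0) out[, 1:(n - 1), ] <- src else out[, 2:n, ] <- src }
    if (axis == 3) { if (dir > 0) out[, , 1:(n - 1)] <- src else out[, , 2:n] <- src }
    out
  }
  interior <- array(TRUE, dim = d)
  for (axis in 1:3) for (dir in c(-1, 1))
    interior <- interior & shift_covered(axis, dir)
  v & !interior
}

#' Surface voxels of a mask
#'
#' Exactly the mask-true voxels with at least one face-adjacent mask-false or
#' out-of-grid neighbour (6-connectivity). Returned as world coordinates of
#' voxel centers in mm.
#'
#' @param mask a non-empty [BinaryMask-class].
#' @return numeric matrix (n x 3) of surface-voxel center positions (mm).
#' @export
surfaceVoxels <- function(mask) {
  if (!any(mask@voxels))
    .gtv_error("emptyMaskError", "cannot extract the surface of an empty mask")
  idx <- which(.surface_array(mask@voxels), arr.ind = TRUE)
  voxelToWorld(mask@grid, idx)
}

#' Distance to agreement between two mask surfaces
#'
#' For each surface voxel of \code{test}, the minimum Euclidean distance (mm)
#' to any surface voxel of \code{reference}; the mean and maximum of these are
#' reported in cm. The directed maximum equals the directed Hausdorff distance
#' between the surface point sets. Both directions plus their symmetrized
#' versions are returned; the pairwise study design consumes the directed
#' result with the evaluated observer as "from".
#'
#' @param test,reference non-empty [BinaryMask-class] objects on a shared grid.
#' @return list of class \code{DtaResult} with \code{mean_dta_cm},
#'   \code{max_dta_cm} (directed, test to reference), the reverse direction
#'   (\code{mean_dta_cm_rev}, \code{max_dta_cm_rev}) and symmetrized values
#'   (\code{mean_dta_cm_sym} = mean of both directed means,
#'   \code{max_dta_cm_sym} = max of both directed maxima).
#' @export
dta <- function(test, reference) {
  validateSameGrid(test, reference)
  p_test <- surfaceVoxels(test)
  p_ref <- surfaceVoxels(reference)
  fwd <- .nn_min_dist(p_test, p_ref) / 10   # mm -> cm
  rev <- .nn_min_dist(p_ref, p_test) / 10
  structure(list(
    mean_dta_cm = mean(fwd), max_dta_cm = max(fwd),
    mean_dta_cm_rev = mean(rev), max_dta_cm_rev = max(rev),
    mean_dta_cm_sym = (mean(fwd) + mean(rev)) / 2,
    max_dta_cm_sym = max(max(fwd), max(rev)),
    direction = "test->reference"
  ), class = "DtaResult")
}
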