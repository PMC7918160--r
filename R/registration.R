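## Rigid mask transfer from the PET grid to the planning-CT grid.
## Transforms are inputs (per-patient files), never estimated: the study's
## registrations were manually adjusted, so estimation is out of scope.
## Resampling is nearest-neighbour, which keeps masks binary and reproduces
## the angular degradation seen when carrying PET contours to a coarser
## planning grid.

#' Construct a RigidTransform
#'
#' @param rotation 3x3 orthonormal rotation matrix (det +1); default identity.
#' @param translation mm triple; default zero.
#' @return a [RigidTransform-class] mapping PET-space world points to
#'   planning-CT-space world points.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = matrix(as.numeric(rotation), 3, 3),
      translation = as.numeric(translation))
}

#' Rotation about a coordinate axis
#'
#' @param axis 1, 2 or 3 (x, y, z).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @param translation optional mm triple.
#' @return a [RigidTransform-class].
#' @export
axisRotation <- function(axis, angle_deg, translation = c(0, 0, 0)) {
  a <- angle_deg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  R <- diag(3)
  ij <- setdiff(1:3, axis)
  R[ij[1], ij[1]] <- c2; R[ij[2], ij[2]] <- c2
  if (axis == 2) { R[ij[1], ij[2]] <- s2; R[ij[2], ij[1]] <- -s2 }
  else { R[ij[1], ij[2]] <- -s2; R[ij[2], ij[1]] <- s2 }
  RigidTransform(R, translation)
}

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (PET -> CT):\n")
  m <- cbind(object@rotation, object@translation)
  rownames(m) <- c("x", "y", "z"); colnames(m) <- c("r1", "r2", "r3", "t_mm")
  print(signif(m, 6))
})

#' Invert a rigid transform
#'
#' @param t a [RigidTransform-class].
#' @return the inverse transform: \code{x = R'(y - t)}.
#' @export
invertRigid <- function(t) {
  stopifnot(is(t, "RigidTransform"))
  Rt <- t(t@rotation)
  RigidTransform(Rt, -as.numeric(Rt %*% t@translation))
}

#' Compose two rigid transforms
#' @param a,b [RigidTransform-class]; returns the map \code{x -> a(b(x))}.
#' @export
composeRigid <- function(a, b) {
  RigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Apply a rigid transform to world points
#' @param t a [RigidTransform-class].
#' @param points numeric matrix (n x 3), mm.
#' @return transformed points (n x 3), mm.
#' @export
applyRigid <- function(t, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sweep(points %*% t(t@rotation), 2, t@translation, "+")
}

#' Transfer a mask to another grid through a rigid transform
#'
#' Each target-grid voxel center is mapped through the inverse transform into
#' source space and takes the value of the nearest source voxel
#' (nearest-neighbour resampling); positions outside the source extent are
#' false.
#'
#' @param mask the source [BinaryMask-class] (e.g. on the PET grid).
#' @param t a [RigidTransform-class] mapping source world to target world.
#' @param target_grid the destination [ImageGrid-class] (e.g. planning CT).
#' @return a [BinaryMask-class] on \code{target_grid}.
#' @export
transferMask <- function(mask, t, target_grid) {
  stopifnot(is(mask, "BinaryMask"), is(t, "RigidTransform"),
            is(target_grid, "ImageGrid"))
  if (any(target_grid@shape < 1L))
    .gtv_error("degenerateGridError", "degenerate target grid")
  n <- target_grid@shape
  idx <- as.matrix(expand.grid(i = seq_len(n[1]), j = seq_len(n[2]),
                               k = seq_len(n[3])))
  world_t <- voxelToWorld(target_grid, idx)
  world_s <- applyRigid(invertRigid(t), world_t)
  src_idx <- worldToVoxel(mask@grid, world_s)
  inb <- src_idx[, 1] >= 1 & src_idx[, 1] <= mask@grid@shape[1] &
         src_idx[, 2] >= 1 & src_idx[, 2] <= mask@grid@shape[2] &
         src_idx[, 3] >= 1 & src_idx[, 3] <= mask@grid@shape[3]
  out <- logical(nrow(idx))
  if (any(inb)) {
    lin <- (src_idx[inb, 3] - 1) * (mask@grid@shape[1] * mask@grid@shape[2]) +
           (src_idx[inb, 2] - 1) * mask@grid@shape[1] + src_idx[inb, 1]
    out[inb] <- mask@voxels[lin]
  }
  BinaryMask(target_grid, array(out, dim = n))
}

#' Write a rigid transform to a JSON file
#'
#' Stored as a row-major 4x4 homogeneous matrix in mm with an explicit
#' direction field (\code{"PET->CT"}).
#'
#' @param t a [RigidTransform-class].
#' @param path destination path.
#' @export
writeTransform <- function(t, path) {
  m <- rbind(cbind(t@rotation, t@translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(direction = "PET->CT", units = "mm",
                            matrix_row_major = as.numeric(t(m))),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a rigid transform from a JSON file
#' @param path transform JSON path.
#' @return a [RigidTransform-class].
#' @export
readTransform <- function(path) {
  if (!file.exists(path))
    .gtv_error("missingFileError", paste0("no such file: ", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(j$matrix_row_major, 4, 4, byrow = TRUE)
  RigidTransform(m[1:3, 1:3], m[1:3, 4])
}
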