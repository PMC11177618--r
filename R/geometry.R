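#' Voxel-grid geometry
#'
#' A `vol_geometry` describes the voxel grid shared by all volumes of a
#' study: grid dimensions, voxel size in mm, the affine mapping voxel
#' indices to world coordinates, and the hemisphere reporting convention.
#' Voxel indices are 1-based (R convention); the affine maps
#' `(i-1, j-1, k-1, 1)` to world mm, so index `(1,1,1)` sits at the affine
#' origin.
#'
#' @param shape integer vector of length 3, voxel counts per axis.
#' @param voxel_size_mm numeric vector of length 3, voxel edge lengths in
#'   mm (all positive).
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling
#'   by `voxel_size_mm` with zero origin. Its upper-left 3x3 block must
#'   have `|det| = dx*dy*dz`.
#' @param world_convention `"right_negative_x"` (default; reported x is
#'   sign-flipped so right-hemisphere voxels carry negative x, the
#'   radiological table convention) or `"right_positive_x"`.
#' @return An object of class `vol_geometry`.
#' @export
vol_geometry <- function(shape, voxel_size_mm = c(1, 1, 1), affine = NULL,
                         world_convention = c("right_negative_x",
                                              "right_positive_x")) {
  world_convention <- match.arg(world_convention)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (is.null(affine))
    affine <- diag(c(voxel_size_mm, 1))
  affine <- unname(as.matrix(affine))
  stopifnot(all(dim(affine) == c(4L, 4L)))
  vdet <- abs(det(affine[1:3, 1:3]))
  if (abs(vdet - prod(voxel_size_mm)) > 1e-6 * prod(voxel_size_mm))
    stop("affine determinant inconsistent with voxel_size_mm")
  structure(list(shape = shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine,
                 world_convention = world_convention),
            class = "vol_geometry")
}

#' @export
print.vol_geometry <- function(x, ...) {
  cat("vol_geometry: ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(x$voxel_size_mm, collapse = " x "),
      " mm, convention ", x$world_convention, "\n", sep = "")
  invisible(x)
}

#' Test whether two geometries describe the same grid
#'
#' Compatible means identical shape and an affine agreeing entrywise
#' within `tol`.
#'
#' @param a,b `vol_geometry` objects.
#' @param tol numeric tolerance on affine entries.
#' @return Logical scalar.
#' @export
geometry_compatible <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

#' Convert voxel indices to world coordinates
#'
#' Applies the geometry's affine to 1-based voxel indices (voxel-center
#' convention). Under `world_convention = "right_negative_x"` the x
#' coordinate is negated relative to the right-positive affine, so that
#' right-hemisphere voxels report negative x.
#'
#' @param index integer vector `(i, j, k)` or an n x 3 matrix of indices.
#' @param geometry a `vol_geometry`.
#' @return Numeric vector `(x, y, z)` in mm, or an n x 3 matrix.
#' @export
world_coords <- function(index, geometry) {
  idx <- if (is.matrix(index)) index else matrix(index, nrow = 1L)
  stopifnot(ncol(idx) == 3L)
  if (any(idx < 1L) || any(t(idx) > geometry$shape + 1e-9))
    stop("voxel index out of bounds")
  h <- cbind(idx - 1, 1)                       # 0-based homogeneous coords
  w <- h %*% t(geometry$affine)
  w <- w[, 1:3, drop = FALSE]
  if (geometry$world_convention == "right_negative_x")
    w[, 1] <- -w[, 1]
  colnames(w) <- c("x", "y", "z")
  if (is.matrix(index)) w else drop(w)
}

## linear index <-> (i,j,k) helpers for a given grid shape
ijk_to_linear <- function(ijk, shape) {
  if (!is.matrix(ijk)) ijk <- matrix(ijk, nrow = 1L)
  as.integer(ijk[, 1] + (ijk[, 2] - 1L) * shape[1] +
             (ijk[, 3] - 1L) * shape[1] * shape[2])
}

linear_to_ijk <- function(lin, shape) {
  arrayInd(as.integer(lin), .dim = shape)
}
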