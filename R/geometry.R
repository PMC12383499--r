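#' Image geometry of a 3D volume
#'
#' Bundles the voxel grid shape, voxel spacing and the 4x4 voxel-to-world
#' affine of a volume, together with the index of the through-plane (axial)
#' axis after canonical anatomical reorientation. Every millimetre or cm^3
#' quantity in the package is derived from one of these objects.
#'
#' The affine maps *0-based* voxel indices to world coordinates in mm, the
#' NIfTI convention. R arrays are 1-based; conversion helpers take care of
#' the offset.
#'
#' @param shape Integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing_mm Numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0).
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world
#'   mm; must be invertible. Defaults to a diagonal affine built from
#'   `spacing_mm`.
#' @param axial_axis Index (1, 2 or 3) of the slice axis; axial slices are
#'   taken perpendicular to this axis. After reorientation to RAS this is 3.
#'
#' @return An object of class `image_geometry`.
#' @export
image_geometry <- function(shape, spacing_mm, affine = NULL, axial_axis = 3L) {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("geometry error: `shape` must be 3 positive integers", call. = FALSE)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("geometry error: `spacing_mm` must be 3 strictly positive values", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(spacing_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
    stop("geometry error: `affine` must be a finite 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < 1e-12)
    stop("geometry error: `affine` is singular", call. = FALSE)
  axial_axis <- as.integer(axial_axis)
  if (!axial_axis %in% 1:3)
    stop("geometry error: `axial_axis` must be 1, 2 or 3", call. = FALSE)
  structure(
    list(shape = shape, spacing_mm = spacing_mm, affine = affine,
         axial_axis = axial_axis),
    class = "image_geometry"
  )
}

#' @export
print.image_geometry <- function(x, ...) {
  cat("<image_geometry> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm, axial axis ", x$axial_axis, "\n", sep = "")
  invisible(x)
}

#' Volume of one voxel in mm^3
#' @param geometry An [image_geometry()].
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(geometry) {
  prod(geometry$spacing_mm)
}

# idx0: n x 3 matrix of 0-based voxel indices -> n x 3 world mm
voxel_to_world <- function(idx0, geometry) {
  idx0 <- matrix(as.numeric(idx0), ncol = 3L)
  out <- cbind(idx0, 1) %*% t(geometry$affine)
  out[, 1:3, drop = FALSE]
}

# pts: n x 3 world mm -> n x 3 continuous 0-based voxel indices
world_to_voxel <- function(pts, geometry) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  out <- cbind(pts, 1) %*% t(solve(geometry$affine))
  out[, 1:3, drop = FALSE]
}

# linear (1-based, column-major) indices -> 0-based voxel index matrix
linear_to_idx0 <- function(lin, shape) {
  arrayInd(lin, shape) - 1L
}

idx0_to_linear <- function(idx0, shape) {
  1L + idx0[, 1L] + shape[1L] * (idx0[, 2L] + shape[2L] * idx0[, 3L])
}

geometry_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing_mm - b$spacing_mm)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol &&
    a$axial_axis == b$axial_axis
}
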