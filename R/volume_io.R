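#' Binary mask volume
#'
#' A 3D grid over {0, 1} plus its [image_geometry()]. Constructed directly
#' from an array or via [read_mask()].
#'
#' @param grid 3D array; coerced to integer 0/1 (values must already be 0/1).
#' @param geometry An [image_geometry()] matching `dim(grid)`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, geometry) {
  grid <- check_grid(grid, geometry)
  if (!all(grid %in% c(0L, 1L)))
    stop("binary mask may only contain values 0 and 1", call. = FALSE)
  structure(list(grid = grid, geometry = geometry), class = "binary_mask")
}

#' Label map volume
#'
#' A 3D grid of non-negative integers plus its [image_geometry()];
#' 0 is background, each positive value identifies one lesion.
#'
#' @param grid 3D array of non-negative integers.
#' @param geometry An [image_geometry()] matching `dim(grid)`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(grid, geometry) {
  grid <- check_grid(grid, geometry)
  if (any(grid < 0L))
    stop("label map may not contain negative values", call. = FALSE)
  structure(list(grid = grid, geometry = geometry), class = "label_map")
}

check_grid <- function(grid, geometry) {
  if (!inherits(geometry, "image_geometry"))
    stop("`geometry` must be an image_geometry", call. = FALSE)
  if (length(dim(grid)) != 3L)
    stop("geometry error: grid must be a 3D array", call. = FALSE)
  if (!identical(as.integer(dim(grid)), geometry$shape))
    stop("geometry error: grid shape does not match geometry", call. = FALSE)
  storage.mode(grid) <- "integer"
  grid
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(x$geometry$shape, collapse = " x "),
      " voxels, ", sum(x$grid > 0L), " foreground\n", sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  labs <- label_ids(x)
  cat("<label_map> ", paste(x$geometry$shape, collapse = " x "),
      " voxels, ", length(labs), " labels\n", sep = "")
  invisible(x)
}

#' Positive labels present in a label map
#' @param map A [label_map()].
#' @return Sorted integer vector of labels.
#' @export
label_ids <- function(map) {
  sort(unique(map$grid[map$grid > 0L]))
}

#' Read a 3D binary mask from NIfTI
#'
#' Reads a NIfTI volume, reorients it to the canonical RAS anatomical
#' orientation (when the header carries a usable qform/sform), and
#' binarises it with a fixed threshold so soft probability masks are
#' accepted without changing genuine 0/1 masks. After reorientation the
#' axial (through-plane) axis is always the third one.
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D volume.
#' @param threshold Foreground threshold; voxels with value strictly above
#'   it become 1. Default 0.5.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, threshold = 0.5) {
  vol <- read_volume(path)
  grid <- array(as.integer(vol$arr > threshold), dim = dim(vol$arr))
  binary_mask(grid, vol$geometry)
}

#' Read a 3D integer label map from NIfTI
#'
#' Like [read_mask()] but values are rounded to integers instead of being
#' binarised, so consistently labelled outputs round-trip.
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D volume.
#' @return A [label_map()].
#' @export
read_labelmap <- function(path) {
  vol <- read_volume(path)
  grid <- array(as.integer(round(vol$arr)), dim = dim(vol$arr))
  label_map(grid, vol$geometry)
}

read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read volume: file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img <- RNifti::asNifti(array(as.array(img), dim = d[1:3]), reference = img)
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("geometry error: volume in ", path, " is not 3D", call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  oriented <- hdr$qform_code > 0L || hdr$sform_code > 0L
  if (oriented) RNifti::orientation(img) <- "RAS"
  arr <- as.array(img)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("geometry error: non-positive voxel spacing in ", path, call. = FALSE)
  affine <- if (oriented) {
    unclass(RNifti::xform(img))[1:4, 1:4]
  } else {
    diag(c(spacing, 1))
  }
  geom <- image_geometry(dim(arr), spacing, affine, axial_axis = 3L)
  list(arr = arr, geometry = geom)
}

#' Write a label map (or binary mask) to NIfTI
#'
#' Grid values, spacing and affine are preserved; integer data are stored
#' as integers (16-bit when they fit, 32-bit otherwise).
#'
#' @param map A [label_map()] or [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(map, path) {
  if (!inherits(map, c("label_map", "binary_mask")))
    stop("`map` must be a label_map or binary_mask", call. = FALSE)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write volume: directory does not exist: ", dir, call. = FALSE)
  geom <- map$geometry
  img <- RNifti::asNifti(map$grid)
  RNifti::pixdim(img) <- geom$spacing_mm
  RNifti::qform(img) <- structure(geom$affine, code = 2L)
  RNifti::sform(img) <- structure(geom$affine, code = 2L)
  dtype <- if (max(map$grid) <= 32767L) "int16" else "int32"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}
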