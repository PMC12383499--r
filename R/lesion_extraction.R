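#' Label connected lesion components
#'
#' Splits a binary lesion mask into individually labelled metastases by
#' grouping connected foreground voxels. Labels 1..N are assigned in
#' deterministic array scan order (first voxel of each component, column-major),
#' so repeated runs on the same mask give identical label maps.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 26 (faces, edges and corners; default), 18, or 6
#'   (faces only). 26 is the most inclusive standard choice and reproduces
#'   the fusing of nearly-touching lesions seen in clinical follow-ups.
#' @return A [label_map()] with one label per connected component.
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (!inherits(mask, "binary_mask"))
    stop("`mask` must be a binary_mask", call. = FALSE)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  d <- mask$geometry$shape
  grid <- mask$grid
  fg <- which(grid > 0L)
  lab <- integer(length(grid))
  if (length(fg)) {
    off <- neighbour_offsets(connectivity)
    n_off <- nrow(off)
    isfg <- logical(length(grid))
    isfg[fg] <- TRUE
    nxt <- 0L
    for (seed in fg) {
      if (lab[seed] > 0L) next
      nxt <- nxt + 1L
      lab[seed] <- nxt
      frontier <- seed
      while (length(frontier)) {
        f1 <- arrayInd(frontier, d)
        m <- nrow(f1)
        nb <- f1[rep.int(seq_len(m), n_off), , drop = FALSE] +
          off[rep(seq_len(n_off), each = m), , drop = FALSE]
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
        nb <- nb[ok, , drop = FALSE]
        lin <- nb[, 1L] + d[1L] * ((nb[, 2L] - 1L) + d[2L] * (nb[, 3L] - 1L))
        lin <- unique(lin[isfg[lin] & lab[lin] == 0L])
        lab[lin] <- nxt
        frontier <- lin
      }
    }
  }
  label_map(array(lab, d), mask$geometry)
}

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6"  = ord == 1L,
    "18" = ord >= 1L & ord <= 2L,
    "26" = ord >= 1L
  )
  storage.mode(g) <- "integer"
  unname(g[keep, , drop = FALSE])
}

#' Tabulate lesions of a label map
#'
#' One row per lesion with voxel count, world-space centroid, volume and
#' largest axial diameter, plus a list-column of the lesion's linear voxel
#' indices. All quantities are computed in the map's own (native) space.
#'
#' @param map A [label_map()].
#' @return A tibble with columns `id`, `n_voxels`, `volume_cm3`,
#'   `diam_axial_mm`, `centroid_x_mm`, `centroid_y_mm`, `centroid_z_mm`
#'   and list-column `voxels`.
#' @export
lesion_table <- function(map) {
  if (!inherits(map, "label_map"))
    stop("`map` must be a label_map", call. = FALSE)
  geom <- map$geometry
  lin <- which(map$grid > 0L)
  empty <- tibble::tibble(
    id = integer(), n_voxels = integer(), volume_cm3 = numeric(),
    diam_axial_mm = numeric(), centroid_x_mm = numeric(),
    centroid_y_mm = numeric(), centroid_z_mm = numeric(), voxels = list()
  )
  if (!length(lin)) return(empty)
  labs <- map$grid[lin]
  ids <- sort(unique(labs))
  world <- voxel_to_world(linear_to_idx0(lin, geom$shape), geom)
  sums <- rowsum(world, group = labs)
  counts <- as.vector(rowsum(rep(1L, length(labs)), group = labs))
  cent <- sums / counts
  vox <- split(lin, labs)
  diam <- vapply(vox, largest_axial_diameter_mm, numeric(1), geometry = geom)
  tibble::tibble(
    id = ids,
    n_voxels = as.integer(counts),
    volume_cm3 = counts * voxel_volume_mm3(geom) / 1000,
    diam_axial_mm = unname(diam),
    centroid_x_mm = cent[, 1L],
    centroid_y_mm = cent[, 2L],
    centroid_z_mm = cent[, 3L],
    voxels = unname(vox)
  )
}

#' World-space centroid of a voxel set
#'
#' Arithmetic mean of the world coordinates of the voxel centres.
#'
#' @param voxels Linear (column-major) voxel indices into the grid.
#' @param geometry The grid's [image_geometry()].
#' @return World 3-vector in mm.
#' @export
lesion_centroid_mm <- function(voxels, geometry) {
  if (!length(voxels)) stop("empty voxel set has no centroid", call. = FALSE)
  colMeans(voxel_to_world(linear_to_idx0(voxels, geometry$shape), geometry))
}

#' Drop lesions lying outside the liver
#'
#' A lesion is kept iff strictly more than `min_inside_fraction` of its
#' voxels fall inside the liver foreground. Kept lesions are not clipped
#' (their voxel sets and therefore volumes are unchanged); surviving
#' labels are renumbered 1..M preserving the original order.
#'
#' @param map A [label_map()] of lesions.
#' @param liver A [binary_mask()] of the liver in the same geometry.
#' @param min_inside_fraction Inside-fraction a lesion must exceed to be
#'   kept; default 0.5.
#' @return A [label_map()] with only the surviving lesions.
#' @export
restrict_to_liver <- function(map, liver, min_inside_fraction = 0.5) {
  if (!inherits(map, "label_map")) stop("`map` must be a label_map", call. = FALSE)
  if (!inherits(liver, "binary_mask")) stop("`liver` must be a binary_mask", call. = FALSE)
  if (!geometry_equal(map$geometry, liver$geometry, tol = 1e-4))
    stop("geometry error: lesion and liver masks of one timepoint must share a geometry",
         call. = FALSE)
  lin <- which(map$grid > 0L)
  if (!length(lin)) return(map)
  labs <- map$grid[lin]
  inside <- liver$grid[lin] > 0L
  frac <- as.vector(rowsum(as.numeric(inside), group = labs)) /
    as.vector(rowsum(rep(1, length(labs)), group = labs))
  ids <- sort(unique(labs))
  keep <- ids[frac > min_inside_fraction]
  lut <- integer(max(ids) + 1L)           # old label -> new label, 0 drops
  lut[keep + 1L] <- seq_along(keep)
  grid <- array(0L, map$geometry$shape)
  sel <- labs %in% keep
  grid[lin[sel]] <- lut[labs[sel] + 1L]
  label_map(grid, map$geometry)
}
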