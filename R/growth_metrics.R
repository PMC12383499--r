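#' Lesion volume in cm^3
#'
#' Voxel count times voxel volume, converted mm^3 to cm^3. Always computed
#' on the lesion's native-space mask; registration never changes volumes.
#'
#' @param n_voxels Number of foreground voxels (vectorised).
#' @param geometry The native [image_geometry()].
#' @return Volume(s) in cm^3.
#' @export
lesion_volume_cm3 <- function(n_voxels, geometry) {
  n_voxels * voxel_volume_mm3(geometry) / 1000
}

#' Largest axial diameter of a lesion in mm
#'
#' For every axial slice (perpendicular to `geometry$axial_axis`) that
#' contains lesion voxels, the maximum pairwise Euclidean distance between
#' in-plane voxel centres is computed; the result is the maximum over
#' slices. This is the in-plane Feret diameter between voxel centres, the
#' RECIST measurement axis. A slice with a single voxel contributes 0.
#'
#' @param voxels Linear voxel indices of the lesion.
#' @param geometry The native [image_geometry()].
#' @return Diameter in mm (0 for a single-voxel lesion).
#' @export
largest_axial_diameter_mm <- function(voxels, geometry) {
  if (!length(voxels)) stop("empty voxel set has no diameter", call. = FALSE)
  idx1 <- arrayInd(voxels, geometry$shape)
  ax <- geometry$axial_axis
  inplane <- setdiff(1:3, ax)
  best <- 0
  for (slice in unique(idx1[, ax])) {
    pts <- idx1[idx1[, ax] == slice, , drop = FALSE]
    if (nrow(pts) < 2L) next
    # convex hull in voxel index space is affine-invariant, so the hull in
    # (i, j) contains the world-space Feret endpoints
    if (nrow(pts) > 8L) {
      h <- tryCatch(grDevices::chull(pts[, inplane[1L]], pts[, inplane[2L]]),
                    error = function(e) seq_len(nrow(pts)))
      pts <- pts[h, , drop = FALSE]
    }
    w <- voxel_to_world(pts - 1L, geometry)
    best <- max(best, max(stats::dist(w)))
  }
  best
}

#' Total hepatic tumor load in cm^3
#'
#' Sum of per-lesion volumes; for a mask or label map this equals the
#' foreground voxel count times the voxel volume, exactly.
#'
#' @param x A [label_map()], [binary_mask()], or a [lesion_table()] tibble.
#' @param geometry Required only when `x` is a lesion tibble without
#'   `volume_cm3` (then volumes are derived from `n_voxels`).
#' @return Tumor load in cm^3 (0 when empty).
#' @export
tumor_load_cm3 <- function(x, geometry = NULL) {
  if (inherits(x, c("label_map", "binary_mask"))) {
    return(lesion_volume_cm3(sum(x$grid > 0L), x$geometry))
  }
  if (is.data.frame(x)) {
    if (!nrow(x)) return(0)
    if ("volume_cm3" %in% names(x)) return(sum(x$volume_cm3))
    if (!is.null(geometry) && "n_voxels" %in% names(x))
      return(sum(lesion_volume_cm3(x$n_voxels, geometry)))
  }
  stop("`x` must be a mask, label map, or lesion table", call. = FALSE)
}

#' One differential-growth record
#'
#' Builds a single growth record from per-timepoint measurements, filling
#' in absolute and relative (percent-of-baseline) differences. Used for
#' ad-hoc calculations; the pipeline builds whole tables with
#' [growth_table()].
#'
#' @param status One of `"matched"`, `"new"`, `"disappeared"`, `"merged"`.
#' @param label Tracked lesion label (default `NA`).
#' @param vol_bl_cm3,diam_bl_mm Baseline volume / largest axial diameter
#'   (must be absent for `status = "new"`).
#' @param vol_fu_cm3,diam_fu_mm Follow-up volume / diameter (must be
#'   absent for `"disappeared"` and `"merged"`).
#' @return A one-row growth tibble (see [growth_table()] for the columns).
#' @export
growth_record <- function(status, label = NA_integer_,
                          vol_bl_cm3 = NA_real_, diam_bl_mm = NA_real_,
                          vol_fu_cm3 = NA_real_, diam_fu_mm = NA_real_) {
  status <- match.arg(status, c("matched", "new", "disappeared", "merged"))
  has_bl <- !is.na(vol_bl_cm3) || !is.na(diam_bl_mm)
  has_fu <- !is.na(vol_fu_cm3) || !is.na(diam_fu_mm)
  if (!has_bl && !has_fu)
    stop("growth record needs at least one timepoint", call. = FALSE)
  if (status == "matched" && (!has_bl || !has_fu))
    stop("matched growth record needs both timepoints", call. = FALSE)
  if (status == "new" && has_bl)
    stop("a new lesion has no baseline measurements", call. = FALSE)
  if (status %in% c("disappeared", "merged") && has_fu)
    stop(status, " lesion has no follow-up measurements of its own", call. = FALSE)
  rec <- tibble::tibble(
    label = as.integer(label), status = status,
    vol_bl_cm3 = vol_bl_cm3, diam_bl_mm = diam_bl_mm,
    vol_fu_cm3 = vol_fu_cm3, diam_fu_mm = diam_fu_mm
  )
  add_growth_deltas(rec)
}

add_growth_deltas <- function(rec) {
  matched <- rec$status == "matched"
  rec$dvol_abs_cm3 <- ifelse(matched, rec$vol_fu_cm3 - rec$vol_bl_cm3, NA_real_)
  rec$dvol_rel_pct <- ifelse(matched & rec$vol_bl_cm3 > 0,
                             100 * (rec$vol_fu_cm3 - rec$vol_bl_cm3) / rec$vol_bl_cm3,
                             NA_real_)
  rec$ddiam_abs_mm <- ifelse(matched, rec$diam_fu_mm - rec$diam_bl_mm, NA_real_)
  rec$ddiam_rel_pct <- ifelse(matched & rec$diam_bl_mm > 0,
                              100 * (rec$diam_fu_mm - rec$diam_bl_mm) / rec$diam_bl_mm,
                              NA_real_)
  rec
}

#' Differential-growth table for a tracked patient
#'
#' Joins native-space baseline and follow-up lesion measurements through a
#' correspondence mapping and computes absolute and relative changes in
#' volume and largest axial diameter. Matched lesions get both timepoints;
#' new lesions have no baseline fields; disappeared and merged lesions
#' have no follow-up fields of their own (a merged lesion's volume is
#' absorbed by its partner's follow-up component).
#'
#' @param lesions_bl,lesions_fu Native-space [lesion_table()]s of the two
#'   timepoints.
#' @param mapping Label mapping tibble from [relabel_maps()] (columns
#'   `track_label`, `status`, `baseline_id`, `followup_id`, `merged_into`).
#' @return A tibble with one row per tracked lesion: `label`, `status`,
#'   `vol_bl_cm3`, `diam_bl_mm`, `vol_fu_cm3`, `diam_fu_mm`,
#'   `dvol_abs_cm3`, `dvol_rel_pct`, `ddiam_abs_mm`, `ddiam_rel_pct`,
#'   `merged_into`.
#' @export
growth_table <- function(lesions_bl, lesions_fu, mapping) {
  bl <- lesions_bl[, c("id", "volume_cm3", "diam_axial_mm")]
  names(bl) <- c("baseline_id", "vol_bl_cm3", "diam_bl_mm")
  fu <- lesions_fu[, c("id", "volume_cm3", "diam_axial_mm")]
  names(fu) <- c("followup_id", "vol_fu_cm3", "diam_fu_mm")
  out <- mapping |>
    dplyr::left_join(bl, by = "baseline_id") |>
    dplyr::left_join(fu, by = "followup_id")
  # merged lesions point at their absorber's follow-up component but carry
  # no follow-up measurement of their own
  merged <- out$status == "merged"
  out$vol_fu_cm3[merged] <- NA_real_
  out$diam_fu_mm[merged] <- NA_real_
  out <- dplyr::rename(out, label = "track_label")
  out <- add_growth_deltas(out)
  out[, c("label", "status", "vol_bl_cm3", "diam_bl_mm", "vol_fu_cm3",
          "diam_fu_mm", "dvol_abs_cm3", "dvol_rel_pct", "ddiam_abs_mm",
          "ddiam_rel_pct", "merged_into")]
}
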