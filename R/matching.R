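#' Pairwise matching scores between baseline and follow-up lesions
#'
#' For every (baseline, follow-up) lesion pair computes the Euclidean
#' distance between 3D centroids, `d(i, j) = ||c_i - c_j||` in mm, and the
#' Dice overlap `Dice(i, j) = 2 |V_i n V_j| / (|V_i| + |V_j|)` of the
#' voxel sets on the shared baseline grid. The follow-up map must already
#' be resampled into baseline space (see [resample_to_baseline()]).
#'
#' @param map_bl Baseline [label_map()].
#' @param map_fu_registered Follow-up [label_map()] resampled onto the
#'   baseline grid.
#' @param centroids_fu_mm Optional matrix/data frame of exact registered
#'   follow-up centroids (rows named/ordered by follow-up label, columns
#'   x, y, z in mm, with a `followup_id` column when a data frame).
#'   Defaults to centroids measured on the resampled map; supplying
#'   transformed native centroids avoids resampling jitter and keeps
#'   lesions that rasterise to nothing on the baseline grid.
#' @return A tibble of match candidates: `baseline_id`, `followup_id`,
#'   `distance_mm`, `dice` -- one row per pair.
#' @export
pairwise_scores <- function(map_bl, map_fu_registered, centroids_fu_mm = NULL) {
  if (!geometry_equal(map_bl$geometry, map_fu_registered$geometry, tol = 1e-4))
    stop("both label maps must live on the baseline grid", call. = FALSE)
  les_bl <- lesion_table(map_bl)
  ids_bl <- les_bl$id
  if (is.null(centroids_fu_mm)) {
    les_fu <- lesion_table(map_fu_registered)
    ids_fu <- les_fu$id
    cent_fu <- as.matrix(les_fu[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  } else if (is.data.frame(centroids_fu_mm)) {
    ids_fu <- as.integer(centroids_fu_mm$followup_id)
    cent_fu <- as.matrix(centroids_fu_mm[, c("x", "y", "z")])
  } else {
    cent_fu <- as.matrix(centroids_fu_mm)
    ids_fu <- seq_len(nrow(cent_fu))
  }
  if (!length(ids_bl) || !length(ids_fu)) {
    return(tibble::tibble(baseline_id = integer(), followup_id = integer(),
                          distance_mm = numeric(), dice = numeric()))
  }
  cent_bl <- as.matrix(les_bl[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  # voxel-set sizes on the common grid
  size_bl <- stats::setNames(les_bl$n_voxels, ids_bl)
  gfu <- map_fu_registered$grid
  nf <- tabulate(gfu[gfu > 0L], nbins = max(ids_fu, max(gfu)))
  size_fu <- stats::setNames(nf[ids_fu], ids_fu)
  # all intersection counts at once from label co-occurrence
  both <- which(map_bl$grid > 0L & gfu > 0L)
  inter <- if (length(both)) {
    as.data.frame(table(bl = map_bl$grid[both], fu = gfu[both]),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(bl = character(), fu = character(), Freq = integer())
  }
  pairs <- expand.grid(baseline_id = ids_bl, followup_id = ids_fu,
                       KEEP.OUT.ATTRS = FALSE)
  key <- paste(pairs$baseline_id, pairs$followup_id)
  ikey <- stats::setNames(inter$Freq, paste(inter$bl, inter$fu))
  n_int <- unname(ikey[key])
  n_int[is.na(n_int)] <- 0L
  denom <- size_bl[as.character(pairs$baseline_id)] +
    size_fu[as.character(pairs$followup_id)]
  dice <- ifelse(denom > 0, 2 * n_int / denom, 0)
  d2 <- outer(rowSums(cent_bl^2), rowSums(cent_fu^2), "+") -
    2 * cent_bl %*% t(cent_fu)
  dmat <- sqrt(pmax(d2, 0))
  dist_mm <- dmat[cbind(match(pairs$baseline_id, ids_bl),
                        match(pairs$followup_id, ids_fu))]
  out <- tibble::tibble(baseline_id = as.integer(pairs$baseline_id),
                        followup_id = as.integer(pairs$followup_id),
                        distance_mm = dist_mm, dice = unname(dice))
  dplyr::arrange(out, .data$baseline_id, .data$followup_id)
}

#' Match lesions across timepoints
#'
#' Establishes one-to-one correspondences from the pairwise scores using a
#' staged, fully deterministic greedy assignment:
#'
#' 1. *Overlap first*: candidates with `dice > 0`, sorted by dice
#'    descending (ties: smaller distance, then smaller baseline id, then
#'    smaller follow-up id), are assigned greedily one-to-one.
#' 2. *Distance fallback*: remaining lesions with
#'    `distance_mm <= max_distance_mm` are assigned greedily by ascending
#'    distance (same tie-breaking), catching small or displaced lesions
#'    that do not overlap after registration.
#' 3. *Merge detection*: each still-unmatched baseline lesion that overlaps
#'    an already-matched follow-up component (`dice > 0`) is marked as
#'    merged into that component (largest dice wins; ties by distance).
#'
#' Whatever remains is new (follow-up) or disappeared (baseline).
#'
#' @param candidates Candidate tibble from [pairwise_scores()], covering
#'   all baseline x follow-up pairs.
#' @param bl_ids,fu_ids Complete label sets of the two timepoints
#'   (defaults to the ids present in `candidates`; pass explicitly when a
#'   timepoint may have lesions absent from `candidates`, e.g. when the
#'   other side is empty).
#' @param max_distance_mm Distance gate for overlap-free matches (default
#'   10 mm): prevents pairing distant unrelated lesions.
#' @return An object of class `lesion_correspondence`: list with `matched`
#'   (tibble `baseline_id`, `followup_id`, `dice`, `distance_mm`, `stage`),
#'   `merged` (tibble `baseline_id`, `followup_id`, `dice`, `distance_mm`),
#'   `new_ids`, `disappeared_ids`.
#' @export
match_lesions <- function(candidates, bl_ids = NULL, fu_ids = NULL,
                          max_distance_mm = 10) {
  if (is.null(bl_ids)) bl_ids <- sort(unique(candidates$baseline_id))
  if (is.null(fu_ids)) fu_ids <- sort(unique(candidates$followup_id))
  bl_ids <- as.integer(bl_ids); fu_ids <- as.integer(fu_ids)
  matched <- tibble::tibble(baseline_id = integer(), followup_id = integer(),
                            dice = numeric(), distance_mm = numeric(),
                            stage = integer())
  greedy <- function(cand, stage) {
    for (r in seq_len(nrow(cand))) {
      b <- cand$baseline_id[r]; f <- cand$followup_id[r]
      if (b %in% matched$baseline_id || f %in% matched$followup_id) next
      matched <<- dplyr::bind_rows(matched, tibble::tibble(
        baseline_id = b, followup_id = f,
        dice = cand$dice[r], distance_mm = cand$distance_mm[r],
        stage = stage))
    }
  }
  # stage 1: overlap evidence
  s1 <- candidates |>
    dplyr::filter(.data$dice > 0) |>
    dplyr::arrange(dplyr::desc(.data$dice), .data$distance_mm,
                   .data$baseline_id, .data$followup_id)
  greedy(s1, 1L)
  # stage 2: gated centroid distance
  s2 <- candidates |>
    dplyr::filter(!.data$baseline_id %in% matched$baseline_id,
                  !.data$followup_id %in% matched$followup_id,
                  .data$distance_mm <= max_distance_mm) |>
    dplyr::arrange(.data$distance_mm, .data$baseline_id, .data$followup_id)
  greedy(s2, 2L)
  # stage 3: leftover baseline lesions absorbed into matched components
  left_bl <- setdiff(bl_ids, matched$baseline_id)
  merged <- candidates |>
    dplyr::filter(.data$baseline_id %in% left_bl,
                  .data$followup_id %in% matched$followup_id,
                  .data$dice > 0) |>
    dplyr::arrange(dplyr::desc(.data$dice), .data$distance_mm,
                   .data$followup_id) |>
    dplyr::distinct(.data$baseline_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$baseline_id)
  res <- structure(list(
    matched = dplyr::arrange(matched, .data$baseline_id),
    merged = merged[, c("baseline_id", "followup_id", "dice", "distance_mm")],
    new_ids = setdiff(fu_ids, matched$followup_id),
    disappeared_ids = setdiff(bl_ids, c(matched$baseline_id, merged$baseline_id)),
    bl_ids = bl_ids, fu_ids = fu_ids
  ), class = "lesion_correspondence")
  validate_correspondence(res)
  res
}

validate_correspondence <- function(x) {
  m <- x$matched
  if (anyDuplicated(m$baseline_id) || anyDuplicated(m$followup_id))
    stop("correspondence invariant violated: matching is not one-to-one", call. = FALSE)
  bl_all <- sort(c(m$baseline_id, x$merged$baseline_id, x$disappeared_ids))
  if (!identical(bl_all, sort(x$bl_ids)) || anyDuplicated(bl_all))
    stop("correspondence invariant violated: baseline labels not partitioned", call. = FALSE)
  fu_all <- sort(c(m$followup_id, x$new_ids))
  if (!identical(fu_all, sort(x$fu_ids)) || anyDuplicated(fu_all))
    stop("correspondence invariant violated: follow-up labels not partitioned", call. = FALSE)
  if (length(x$merged$followup_id) && !all(x$merged$followup_id %in% m$followup_id))
    stop("correspondence invariant violated: merge target is not a matched component",
         call. = FALSE)
  invisible(x)
}

#' @export
print.lesion_correspondence <- function(x, ...) {
  cat("<lesion_correspondence> ", nrow(x$matched), " matched, ",
      length(x$new_ids), " new, ", length(x$disappeared_ids), " disappeared, ",
      nrow(x$merged), " merged\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a lesion correspondence into one row per lesion track
#'
#' @param x A `lesion_correspondence`.
#' @param ... Unused.
#' @return Tibble with `baseline_id`, `followup_id`, `status`, `dice`,
#'   `distance_mm`.
#' @exportS3Method generics::tidy
tidy.lesion_correspondence <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$matched[, c("baseline_id", "followup_id", "dice", "distance_mm")],
                  status = "matched"),
    dplyr::mutate(x$merged, status = "merged"),
    tibble::tibble(baseline_id = NA_integer_, followup_id = x$new_ids,
                   dice = NA_real_, distance_mm = NA_real_, status = "new"),
    tibble::tibble(baseline_id = x$disappeared_ids, followup_id = NA_integer_,
                   dice = NA_real_, distance_mm = NA_real_, status = "disappeared")
  )[, c("baseline_id", "followup_id", "status", "dice", "distance_mm")]
}

#' Relabel both timepoints consistently
#'
#' Matched lesions receive the same integer label in both maps (the
#' baseline label, so the baseline map is unchanged); merged baseline
#' lesions keep their own labels in the baseline map; new follow-up
#' lesions get fresh labels greater than every baseline label, in
#' ascending follow-up order. Relabelling is a bijection on each map's
#' label set.
#'
#' @param map_bl,map_fu Native-space [label_map()]s of the two timepoints.
#' @param corr A `lesion_correspondence` from [match_lesions()].
#' @return List with `baseline` and `followup` (relabelled [label_map()]s)
#'   and `mapping`, a tibble with one row per lesion track: `track_label`,
#'   `status`, `baseline_id`, `followup_id`, `merged_into`.
#' @export
relabel_maps <- function(map_bl, map_fu, corr) {
  validate_correspondence(corr)
  ids_bl <- label_ids(map_bl)
  ids_fu <- label_ids(map_fu)
  if (!setequal(ids_bl, corr$bl_ids) || !setequal(ids_fu, corr$fu_ids))
    stop("correspondence does not cover the label sets of the two maps", call. = FALSE)
  base_max <- if (length(ids_bl)) max(ids_bl) else 0L
  new_ids <- sort(corr$new_ids)
  lut_fu <- integer(max(c(ids_fu, 0L)) + 1L)
  if (nrow(corr$matched))
    lut_fu[corr$matched$followup_id + 1L] <- corr$matched$baseline_id
  if (length(new_ids))
    lut_fu[new_ids + 1L] <- base_max + seq_along(new_ids)
  grid_fu <- map_fu$grid
  pos <- which(grid_fu > 0L)
  grid_fu[pos] <- lut_fu[grid_fu[pos] + 1L]
  m <- corr$matched
  absorber <- stats::setNames(m$baseline_id, m$followup_id)
  mapping <- dplyr::bind_rows(
    tibble::tibble(track_label = m$baseline_id, status = "matched",
                   baseline_id = m$baseline_id, followup_id = m$followup_id,
                   merged_into = NA_integer_),
    tibble::tibble(track_label = base_max + seq_along(new_ids), status = "new",
                   baseline_id = NA_integer_, followup_id = new_ids,
                   merged_into = NA_integer_),
    tibble::tibble(track_label = corr$merged$baseline_id, status = "merged",
                   baseline_id = corr$merged$baseline_id,
                   followup_id = corr$merged$followup_id,
                   merged_into = unname(absorber[as.character(corr$merged$followup_id)])),
    tibble::tibble(track_label = corr$disappeared_ids, status = "disappeared",
                   baseline_id = corr$disappeared_ids, followup_id = NA_integer_,
                   merged_into = NA_integer_)
  ) |> dplyr::arrange(.data$track_label)
  list(baseline = map_bl,
       followup = label_map(grid_fu, map_fu$geometry),
       mapping = mapping)
}
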