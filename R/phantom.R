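#' One scripted phantom lesion
#'
#' @param x,y,z Baseline (object-frame) centre in mm.
#' @param radius_bl_mm Baseline radius in mm (> 0). For `event = "new"`
#'   this is the follow-up radius (the lesion has no baseline).
#' @param growth_factor Radius multiplier applied at follow-up (> 0).
#' @param dx,dy,dz Lesion-specific displacement in mm applied at follow-up
#'   (before global motion).
#' @param event `"tracked"` (present at both timepoints), `"new"`
#'   (follow-up only) or `"disappear"` (baseline only).
#' @return One-row lesion tibble for [phantom_spec()].
#' @export
phantom_lesion <- function(x, y, z, radius_bl_mm, growth_factor = 1,
                           dx = 0, dy = 0, dz = 0,
                           event = c("tracked", "new", "disappear")) {
  event <- match.arg(event)
  tibble::tibble(x = x, y = y, z = z, radius_bl_mm = radius_bl_mm,
                 growth_factor = growth_factor, dx = dx, dy = dy, dz = dz,
                 event = event)
}

#' Specification of a paired baseline/follow-up phantom
#'
#' Describes a synthetic patient: an ellipsoidal liver, spherical lesions
#' with scripted per-lesion growth and displacement, scripted appearance
#' and disappearance events, and a global rigid motion applied to the
#' whole follow-up examination. Rasterisation is by voxel-centre
#' inclusion, matching the centre-based metrics of the tracker, and is
#' fully deterministic.
#'
#' @param shape Baseline grid shape in voxels (default `c(96, 96, 64)`).
#' @param spacing_mm Baseline voxel spacing (default `c(1.5, 1.5, 2)` mm,
#'   a typical hepatobiliary-phase MRI resolution).
#' @param liver_center_mm Liver ellipsoid centre (defaults to the grid centre).
#' @param liver_semiaxes_mm Liver ellipsoid semi-axes (default
#'   `c(55, 42, 45)` mm, an adult-liver-sized ellipsoid).
#' @param lesions Tibble of scripted lesions (rows from [phantom_lesion()]).
#' @param motion_angles_deg Global follow-up rotation about x, y, z (deg).
#' @param motion_shift_mm Global follow-up translation (mm).
#' @param fu_shape,fu_spacing_mm Follow-up grid (defaults: same as baseline;
#'   timepoints may come from different scanners).
#' @param seed Integer seed recorded with the spec (the generator itself is
#'   deterministic; the seed documents how random specs were drawn).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 64L), spacing_mm = c(1.5, 1.5, 2),
                         liver_center_mm = NULL, liver_semiaxes_mm = c(55, 42, 45),
                         lesions = NULL, motion_angles_deg = c(0, 0, 0),
                         motion_shift_mm = c(0, 0, 0),
                         fu_shape = NULL, fu_spacing_mm = NULL, seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(liver_center_mm)) liver_center_mm <- (shape - 1) * spacing_mm / 2
  if (is.null(fu_shape)) fu_shape <- shape
  if (is.null(fu_spacing_mm)) fu_spacing_mm <- spacing_mm
  if (is.null(lesions))
    lesions <- tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                              radius_bl_mm = numeric(), growth_factor = numeric(),
                              dx = numeric(), dy = numeric(), dz = numeric(),
                              event = character())
  lesions <- tibble::as_tibble(lesions)
  lesions$id <- seq_len(nrow(lesions))
  if (nrow(lesions)) {
    if (any(lesions$radius_bl_mm <= 0)) stop("lesion radii must be > 0", call. = FALSE)
    if (any(lesions$growth_factor <= 0)) stop("growth factors must be > 0", call. = FALSE)
    rel <- sweep(as.matrix(lesions[, c("x", "y", "z")]), 2L, liver_center_mm)
    inside <- rowSums(sweep(rel, 2L, liver_semiaxes_mm, "/")^2) <= 1
    if (!all(inside))
      stop("all lesion centres must lie inside the liver ellipsoid", call. = FALSE)
  }
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 liver_center_mm = as.numeric(liver_center_mm),
                 liver_semiaxes_mm = as.numeric(liver_semiaxes_mm),
                 lesions = lesions,
                 motion_angles_deg = as.numeric(motion_angles_deg),
                 motion_shift_mm = as.numeric(motion_shift_mm),
                 fu_shape = as.integer(fu_shape),
                 fu_spacing_mm = as.numeric(fu_spacing_mm),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# axis-aligned sphere rasterisation by voxel-centre inclusion (closed ball)
rasterize_balls <- function(geometry, centers, radii) {
  grid <- array(0L, geometry$shape)
  if (!length(radii)) return(grid)
  sp <- geometry$spacing_mm
  n <- geometry$shape
  axes <- lapply(1:3, function(a) (seq_len(n[a]) - 1) * sp[a])
  centers <- matrix(centers, ncol = 3L)
  for (b in seq_along(radii)) {
    c3 <- centers[b, ]; r <- radii[b]
    rng <- lapply(1:3, function(a) {
      which(axes[[a]] >= c3[a] - r & axes[[a]] <= c3[a] + r)
    })
    if (any(lengths(rng) == 0L)) next
    d2 <- lapply(1:3, function(a) (axes[[a]][rng[[a]]] - c3[a])^2)
    inside <- outer(outer(d2[[1L]], d2[[2L]], "+"), d2[[3L]], "+") <= r^2
    sub <- grid[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE]
    sub[inside] <- 1L
    grid[rng[[1L]], rng[[2L]], rng[[3L]]] <- sub
  }
  grid
}

# ellipsoid rasterisation; `to_object` maps world points into the frame
# where the ellipsoid is axis-aligned
rasterize_ellipsoid <- function(geometry, center, semiaxes, to_object = identity) {
  n <- geometry$shape
  sp <- geometry$spacing_mm
  pts <- cbind(
    rep((seq_len(n[1L]) - 1) * sp[1L], times = n[2L] * n[3L]),
    rep(rep((seq_len(n[2L]) - 1) * sp[2L], each = n[1L]), times = n[3L]),
    rep((seq_len(n[3L]) - 1) * sp[3L], each = n[1L] * n[2L])
  )
  q <- to_object(pts)
  v <- sweep(sweep(q, 2L, center), 2L, semiaxes, "/")
  array(as.integer(rowSums(v^2) <= 1), n)
}

#' Generate a paired baseline/follow-up phantom
#'
#' Rasterises the scripted liver and lesions at both timepoints and
#' returns the four masks together with the ground truth: the true global
#' rigid transform (follow-up world to baseline world), and a per-lesion
#' table with the component labels the tracker should find, analytic
#' volumes and diameters, and the true category under the default
#' thresholds (merge-group members are listed with their group id; which
#' member of a group is reported merged is an algorithmic choice).
#'
#' @param spec A [phantom_spec()].
#' @return List of class `phantom_pair` with `liver_bl`, `lesions_bl`,
#'   `liver_fu`, `lesions_fu` ([binary_mask()]s), `truth` (list with
#'   `transform` and `lesions` tibble) and `spec`.
#' @export
generate_phantom_pair <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec", call. = FALSE)
  geom_bl <- image_geometry(spec$shape, spec$spacing_mm)
  geom_fu <- image_geometry(spec$fu_shape, spec$fu_spacing_mm)
  les <- spec$lesions
  c0 <- spec$liver_center_mm
  rm_ <- rotation_from_angles(spec$motion_angles_deg)
  # object frame -> follow-up world
  motion_fwd <- rigid_transform(rm_, as.numeric(c0 - rm_ %*% c0 + spec$motion_shift_mm))
  truth_transform <- invert_transform(motion_fwd)

  bl_rows <- les[les$event %in% c("tracked", "disappear"), , drop = FALSE]
  lesions_bl <- binary_mask(
    rasterize_balls(geom_bl, as.matrix(bl_rows[, c("x", "y", "z")]),
                    bl_rows$radius_bl_mm),
    geom_bl)
  liver_bl <- binary_mask(
    rasterize_ellipsoid(geom_bl, c0, spec$liver_semiaxes_mm), geom_bl)

  fu_rows <- les[les$event %in% c("tracked", "new"), , drop = FALSE]
  ctr_obj <- as.matrix(fu_rows[, c("x", "y", "z")]) +
    as.matrix(fu_rows[, c("dx", "dy", "dz")])
  r_fu <- ifelse(fu_rows$event == "new", fu_rows$radius_bl_mm,
                 fu_rows$radius_bl_mm * fu_rows$growth_factor)
  ctr_fu <- if (nrow(fu_rows)) apply_transform(motion_fwd, ctr_obj) else ctr_obj
  extent <- (spec$fu_shape - 1) * spec$fu_spacing_mm
  if (nrow(fu_rows)) {
    rr <- matrix(r_fu, nrow = nrow(fu_rows), ncol = 3L)
    lo <- ctr_fu - rr
    hi <- ctr_fu + rr
    if (any(lo < 0) || any(sweep(hi, 2L, extent) > 0))
      stop("bounds error: lesion outside the follow-up grid after motion",
           call. = FALSE)
  }
  lesions_fu <- binary_mask(rasterize_balls(geom_fu, ctr_fu, r_fu), geom_fu)
  inv_motion <- function(p) apply_transform(truth_transform, p)
  liver_fu <- binary_mask(
    rasterize_ellipsoid(geom_fu, c0, spec$liver_semiaxes_mm, to_object = inv_motion),
    geom_fu)

  truth <- phantom_truth(spec, lesions_bl, lesions_fu, ctr_fu, truth_transform)
  structure(list(liver_bl = liver_bl, lesions_bl = lesions_bl,
                 liver_fu = liver_fu, lesions_fu = lesions_fu,
                 truth = truth, spec = spec),
            class = "phantom_pair")
}

label_at_point <- function(map, world_mm) {
  v <- round(world_to_voxel(matrix(world_mm, ncol = 3L), map$geometry))
  n <- map$geometry$shape
  if (any(v < 0) || any(v >= matrix(n, nrow = nrow(v), ncol = 3L, byrow = TRUE)))
    return(0L)
  map$grid[v[, 1L] + 1L + n[1L] * (v[, 2L] + n[2L] * v[, 3L])]
}

phantom_truth <- function(spec, lesions_bl, lesions_fu, ctr_fu, transform) {
  les <- spec$lesions
  map_bl <- label_components(lesions_bl, 26L)
  map_fu <- label_components(lesions_fu, 26L)
  n <- nrow(les)
  bl_label <- rep(NA_integer_, n)
  fu_label <- rep(NA_integer_, n)
  in_bl <- les$event %in% c("tracked", "disappear")
  in_fu <- les$event %in% c("tracked", "new")
  if (any(in_bl))
    bl_label[in_bl] <- vapply(which(in_bl), function(i)
      label_at_point(map_bl, as.numeric(les[i, c("x", "y", "z")])), integer(1))
  if (any(in_fu)) {
    fu_centers <- ctr_fu
    fu_label[which(in_fu)] <- vapply(seq_len(nrow(fu_centers)), function(k)
      label_at_point(map_fu, fu_centers[k, ]), integer(1))
  }
  # lesions sharing a follow-up component form a merge group
  merge_group <- rep(NA_integer_, n)
  shared <- fu_label[!is.na(fu_label)]
  shared <- unique(shared[duplicated(shared)])
  for (g in seq_along(shared))
    merge_group[which(fu_label == shared[g])] <- g
  r_bl <- ifelse(les$event == "new", NA_real_, les$radius_bl_mm)
  r_fu <- dplyr::case_when(
    les$event == "new" ~ les$radius_bl_mm,
    les$event == "tracked" ~ les$radius_bl_mm * les$growth_factor,
    .default = NA_real_
  )
  rel <- 100 * (r_fu - r_bl) / r_bl
  thr <- threshold_config()
  true_cat <- dplyr::case_when(
    les$event == "new" ~ "new",
    les$event == "disappear" ~ "disappeared",
    !is.na(merge_group) ~ NA_character_,   # one of the group will be merged
    2 * r_bl < thr$min_measurable_mm & 2 * r_fu < thr$min_measurable_mm ~ "too_small",
    rel >= thr$progressive_pct ~ "progressive",
    rel <= -thr$regressive_pct ~ "regressive",
    .default = "stable"
  )
  list(
    transform = transform,
    lesions = tibble::tibble(
      id = les$id, event = les$event, merge_group = merge_group,
      bl_label = bl_label, fu_label = fu_label,
      radius_bl_mm = r_bl, radius_fu_mm = r_fu,
      true_vol_bl_cm3 = 4 / 3 * pi * r_bl^3 / 1000,
      true_vol_fu_cm3 = 4 / 3 * pi * r_fu^3 / 1000,
      true_diam_bl_mm = 2 * r_bl, true_diam_fu_mm = 2 * r_fu,
      ddiam_rel_pct_true = rel, true_category = true_cat
    )
  )
}

#' Named phantom scenarios
#'
#' A fixed library of study conditions exercising every tracking event:
#' `identity` (follow-up equals baseline), `all_stable` (sub-threshold
#' growth plus motion), `mixed_growth` (progressive, stable and regressive
#' lesions), `merge` (two lesions whose grown versions fuse into one
#' follow-up component), `new_lesion`, `disappearance`,
#' `solitary_progression` (one growing lesion among five shrinking ones,
#' with a net tumor-load decrease), and `large_cohort` (20 randomised
#' lesions with displacements up to 5 mm and growth factors 0.5-1.5).
#'
#' @param name Scenario name (see above).
#' @param seed Integer seed; only `large_cohort` draws random numbers, and
#'   a fixed seed makes its masks byte-identical across runs.
#' @return A `phantom_pair` (see [generate_phantom_pair()]).
#' @export
phantom_scenario <- function(name = phantom_scenario_names(), seed = 1L) {
  name <- match.arg(name)
  L <- function(dx, dy, dz) c(71.25 + dx, 71.25 + dy, 63 + dz)
  base4 <- function(growth, disp = matrix(0, 4, 3)) {
    pos <- rbind(L(-30, -15, -10), L(25, 10, 5), L(-10, 20, 15), L(5, -25, -20))
    dplyr::bind_rows(lapply(1:4, function(i)
      phantom_lesion(pos[i, 1], pos[i, 2], pos[i, 3],
                     radius_bl_mm = c(4, 6, 8, 11)[i], growth_factor = growth[i],
                     dx = disp[i, 1], dy = disp[i, 2], dz = disp[i, 3])))
  }
  spec <- switch(name,
    identity = phantom_spec(lesions = base4(rep(1, 4)), seed = seed),
    all_stable = phantom_spec(
      lesions = base4(c(1.05, 0.97, 1.08, 0.95),
                      disp = rbind(c(1, -1, 0), c(-2, 1, 1), c(0, 2, -1), c(1, 0, 1))),
      motion_angles_deg = c(0, 0, 1), motion_shift_mm = c(2, -1, 1.5), seed = seed),
    mixed_growth = phantom_spec(
      lesions = dplyr::bind_rows(
        phantom_lesion(L(-32, -12, -8)[1], L(-32, -12, -8)[2], L(-32, -12, -8)[3], 6, 1.40, 1, -1, 0),
        phantom_lesion(L(28, 8, 6)[1], L(28, 8, 6)[2], L(28, 8, 6)[3], 5, 1.25, -1, 2, 1),
        phantom_lesion(L(-8, 22, 14)[1], L(-8, 22, 14)[2], L(-8, 22, 14)[3], 8, 1.00, 2, 0, -1),
        phantom_lesion(L(8, -26, -16)[1], L(8, -26, -16)[2], L(8, -26, -16)[3], 7, 0.90, 0, 1, 1),
        phantom_lesion(L(-22, 14, -18)[1], L(-22, 14, -18)[2], L(-22, 14, -18)[3], 9, 0.65, -2, -1, 0),
        phantom_lesion(L(24, -10, 16)[1], L(24, -10, 16)[2], L(24, -10, 16)[3], 6, 0.62, 1, 1, -1)),
      motion_angles_deg = c(0, 0, 2), motion_shift_mm = c(3, -2, 1), seed = seed),
    merge = phantom_spec(
      lesions = dplyr::bind_rows(
        phantom_lesion(L(-20, 0, 0)[1], L(-20, 0, 0)[2], L(-20, 0, 0)[3], 6, 1.45),
        phantom_lesion(L(-4, 0, 0)[1], L(-4, 0, 0)[2], L(-4, 0, 0)[3], 5, 1.50),
        phantom_lesion(L(30, 20, 10)[1], L(30, 20, 10)[2], L(30, 20, 10)[3], 7, 1.00)),
      seed = seed),
    new_lesion = phantom_spec(
      lesions = dplyr::bind_rows(
        phantom_lesion(L(-28, -12, -8)[1], L(-28, -12, -8)[2], L(-28, -12, -8)[3], 6, 1.02),
        phantom_lesion(L(26, 10, 6)[1], L(26, 10, 6)[2], L(26, 10, 6)[3], 8, 0.98),
        phantom_lesion(L(-8, 22, 12)[1], L(-8, 22, 12)[2], L(-8, 22, 12)[3], 7, 1.05),
        phantom_lesion(L(10, -22, 14)[1], L(10, -22, 14)[2], L(10, -22, 14)[3], 5, event = "new")),
      motion_shift_mm = c(2, 1, -1), seed = seed),
    disappearance = phantom_spec(
      lesions = dplyr::bind_rows(
        phantom_lesion(L(-28, -12, -8)[1], L(-28, -12, -8)[2], L(-28, -12, -8)[3], 6, 1.02),
        phantom_lesion(L(26, 10, 6)[1], L(26, 10, 6)[2], L(26, 10, 6)[3], 8, 0.98),
        phantom_lesion(L(-8, 22, 12)[1], L(-8, 22, 12)[2], L(-8, 22, 12)[3], 7, 1.05),
        phantom_lesion(L(10, -22, 14)[1], L(10, -22, 14)[2], L(10, -22, 14)[3], 6, event = "disappear")),
      motion_shift_mm = c(-2, 1, 1), seed = seed),
    solitary_progression = phantom_spec(
      lesions = dplyr::bind_rows(
        phantom_lesion(L(0, 0, 0)[1], L(0, 0, 0)[2], L(0, 0, 0)[3], 5, 1.35),
        phantom_lesion(L(-30, -14, -10)[1], L(-30, -14, -10)[2], L(-30, -14, -10)[3], 8, 0.80),
        phantom_lesion(L(27, 9, 6)[1], L(27, 9, 6)[2], L(27, 9, 6)[3], 9, 0.78),
        phantom_lesion(L(-10, 24, 14)[1], L(-10, 24, 14)[2], L(-10, 24, 14)[3], 10, 0.82),
        phantom_lesion(L(10, -26, -16)[1], L(10, -26, -16)[2], L(10, -26, -16)[3], 7, 0.75),
        phantom_lesion(L(-24, 16, -16)[1], L(-24, 16, -16)[2], L(-24, 16, -16)[3], 8, 0.80)),
      motion_angles_deg = c(0, 0, 1), motion_shift_mm = c(2, -1, 1), seed = seed),
    large_cohort = large_cohort_spec(seed)
  )
  generate_phantom_pair(spec)
}

#' @rdname phantom_scenario
#' @export
phantom_scenario_names <- function() {
  c("identity", "all_stable", "mixed_growth", "merge", "new_lesion",
    "disappearance", "solitary_progression", "large_cohort")
}

#' @rdname phantom_scenario
#' @return For `phantom_scenario_suite()`, a named list of `phantom_pair`s.
#' @export
phantom_scenario_suite <- function(seed = 1L) {
  stats::setNames(lapply(phantom_scenario_names(), phantom_scenario, seed = seed),
                  phantom_scenario_names())
}

large_cohort_spec <- function(seed) {
  shape <- c(120L, 112L, 80L)
  spacing <- c(1.5, 1.5, 2)
  center <- (shape - 1) * spacing / 2
  semiaxes <- c(70, 58, 62)
  with_local_seed(seed, {
    n_target <- 20L
    radii <- stats::runif(n_target, 3, 6)
    growth <- stats::runif(n_target, 0.5, 1.5)
    dir <- matrix(stats::rnorm(3 * n_target), ncol = 3L)
    dir <- dir / sqrt(rowSums(dir^2))
    disp <- dir * stats::runif(n_target, 0, 5)
    centers <- matrix(NA_real_, 0L, 3L)
    tries <- 0L
    while (nrow(centers) < n_target && tries < 50000L) {
      tries <- tries + 1L
      p <- center + 0.82 * semiaxes * stats::runif(3, -1, 1)
      if (sum(((p - center) / (0.82 * semiaxes))^2) > 1) next
      i <- nrow(centers) + 1L
      if (nrow(centers)) {
        dmin <- sqrt(colSums((t(centers) - p)^2))
        need <- 1.5 * (radii[seq_len(nrow(centers))] + radii[i]) + 14
        if (any(dmin < need)) next
      }
      centers <- rbind(centers, p)
    }
    if (nrow(centers) < n_target)
      stop("could not place the requested number of lesions", call. = FALSE)
    lesions <- dplyr::bind_rows(lapply(seq_len(n_target), function(i)
      phantom_lesion(centers[i, 1], centers[i, 2], centers[i, 3],
                     radius_bl_mm = radii[i], growth_factor = growth[i],
                     dx = disp[i, 1], dy = disp[i, 2], dz = disp[i, 3])))
    phantom_spec(shape = shape, spacing_mm = spacing,
                 liver_semiaxes_mm = semiaxes, lesions = lesions,
                 motion_angles_deg = c(0, 0, 3), motion_shift_mm = c(3, -2, 2),
                 seed = seed)
  })
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Write a phantom pair to disk
#'
#' Writes the four masks in the same NIfTI layout the tracker consumes,
#' plus the ground truth as JSON.
#'
#' @param pair A `phantom_pair`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(pair, dir) {
  if (!inherits(pair, "phantom_pair")) stop("`pair` must be a phantom_pair", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    baseline_lesions = file.path(dir, "baseline_lesions.nii.gz"),
    followup_lesions = file.path(dir, "followup_lesions.nii.gz"),
    baseline_liver = file.path(dir, "baseline_liver.nii.gz"),
    followup_liver = file.path(dir, "followup_liver.nii.gz"),
    truth = file.path(dir, "truth.json")
  )
  write_labelmap(pair$lesions_bl, paths[["baseline_lesions"]])
  write_labelmap(pair$lesions_fu, paths[["followup_lesions"]])
  write_labelmap(pair$liver_bl, paths[["baseline_liver"]])
  write_labelmap(pair$liver_fu, paths[["followup_liver"]])
  jsonlite::write_json(list(
    transform = list(rotation = pair$truth$transform$rotation,
                     translation_mm = pair$truth$transform$translation_mm),
    lesions = pair$truth$lesions
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
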