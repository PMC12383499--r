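#' Tracking run configuration
#'
#' All tunable parameters of a tracking run, with the package defaults.
#' Only the classification thresholds are fixed by the response criteria;
#' everything else is visible and overridable here or through a YAML/JSON
#' config file ([read_track_config()], [default_config_yaml()]).
#'
#' @param connectivity Connected-component connectivity: 26 (default), 18 or 6.
#' @param registration List: `enabled` (default `TRUE`),
#'   `max_rotation_deg` (15), `translation_step_mm` (1).
#' @param matching List: `max_distance_mm` (10) -- distance gate for
#'   overlap-free matches.
#' @param thresholds List passed to [threshold_config()]:
#'   `progressive_pct` (20), `regressive_pct` (30), `min_measurable_mm`
#'   (5), `fold_disappeared_into_regressive` (`FALSE`).
#' @param report List: `order_by` (`"diameter"` or `"volume"`), `format`
#'   (`"csv"`, `"json"` or `"both"`).
#' @return An object of class `track_config`.
#' @export
track_config <- function(connectivity = 26L,
                         registration = list(),
                         matching = list(),
                         thresholds = list(),
                         report = list()) {
  defaults <- list(
    connectivity = 26L,
    registration = list(enabled = TRUE, max_rotation_deg = 15,
                        translation_step_mm = 1),
    matching = list(max_distance_mm = 10),
    thresholds = list(progressive_pct = 20, regressive_pct = 30,
                      min_measurable_mm = 5,
                      fold_disappeared_into_regressive = FALSE),
    report = list(order_by = "diameter", format = "csv")
  )
  cfg <- defaults
  cfg$connectivity <- as.integer(connectivity)
  cfg$registration <- utils::modifyList(cfg$registration, registration)
  cfg$matching <- utils::modifyList(cfg$matching, matching)
  cfg$thresholds <- utils::modifyList(cfg$thresholds, thresholds)
  cfg$report <- utils::modifyList(cfg$report, report)
  if (!cfg$connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  if (!cfg$report$order_by %in% c("diameter", "volume"))
    stop("report.order_by must be 'diameter' or 'volume'", call. = FALSE)
  if (!cfg$report$format %in% c("csv", "json", "both"))
    stop("report.format must be 'csv', 'json' or 'both'", call. = FALSE)
  do.call(threshold_config, cfg$thresholds)   # validates threshold invariants
  structure(cfg, class = "track_config")
}

#' Read a tracking configuration from YAML or JSON
#'
#' Keys missing from the file keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A [track_config()].
#' @export
read_track_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(track_config, raw)
}

#' Default configuration as YAML text
#' @return A single YAML string with every default value.
#' @export
default_config_yaml <- function() {
  yaml::as.yaml(unclass(track_config()))
}

as_mask <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "binary_mask")) return(x)
  if (is.character(x)) return(read_mask(x))
  stop("stage input: `", what, "` must be a file path or binary_mask", call. = FALSE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Track one patient end-to-end
#'
#' Runs the full pipeline: read masks, label connected lesions, restrict
#' to the liver, register the timepoints via the liver masks, score and
#' match lesions, relabel consistently, measure differential growth in
#' native space, classify, and assemble the decision-support report.
#' When `out_dir` is given, all artifacts are written there: the growth
#' table (CSV and/or JSON), a summary JSON, the two consistently
#' relabelled NIfTI label maps, the two category-coded NIfTI volumes and
#' a structured run log.
#'
#' Liver masks are optional: without them, liver restriction is skipped
#' and matching proceeds with an identity registration (a warning is
#' emitted).
#'
#' @param baseline_lesions,followup_lesions Lesion masks (paths or
#'   [binary_mask()]s).
#' @param baseline_liver,followup_liver Optional liver masks.
#' @param config A [track_config()].
#' @param out_dir Optional output directory.
#' @return An object of class `tracking_result`: list with `report`
#'   (`patient_report`), `growth` (classified growth tibble), `maps`
#'   (relabelled baseline/follow-up [label_map()]s), `category_maps`,
#'   `correspondence`, `registration`, `log` and, when written, `paths`.
#' @export
track_patient <- function(baseline_lesions, followup_lesions,
                          baseline_liver = NULL, followup_liver = NULL,
                          config = track_config(), out_dir = NULL) {
  if (!inherits(config, "track_config")) config <- do.call(track_config, config)
  log <- list()

  mask_bl <- run_stage("read", as_mask(baseline_lesions, "baseline_lesions"))
  mask_fu <- run_stage("read", as_mask(followup_lesions, "followup_lesions"))
  liver_bl <- run_stage("read", as_mask(baseline_liver, "baseline_liver"))
  liver_fu <- run_stage("read", as_mask(followup_liver, "followup_liver"))
  have_liver <- !is.null(liver_bl) && !is.null(liver_fu)

  map_bl <- run_stage("label", label_components(mask_bl, config$connectivity))
  map_fu <- run_stage("label", label_components(mask_fu, config$connectivity))
  log$n_components <- c(baseline = length(label_ids(map_bl)),
                        followup = length(label_ids(map_fu)))

  if (have_liver) {
    map_bl <- run_stage("liver_restrict", restrict_to_liver(map_bl, liver_bl))
    map_fu <- run_stage("liver_restrict", restrict_to_liver(map_fu, liver_fu))
  }
  log$n_lesions <- c(baseline = length(label_ids(map_bl)),
                     followup = length(label_ids(map_fu)))

  lesions_bl <- run_stage("measure", lesion_table(map_bl))
  lesions_fu <- run_stage("measure", lesion_table(map_fu))

  reg <- if (have_liver && isTRUE(config$registration$enabled)) {
    run_stage("register", estimate_liver_registration(
      liver_bl, liver_fu,
      max_rotation_deg = config$registration$max_rotation_deg,
      translation_step_mm = config$registration$translation_step_mm))
  } else {
    if (!have_liver)
      warning("no liver masks supplied: skipping liver restriction and ",
              "using identity registration", call. = FALSE)
    structure(list(transform = rigid_transform(), liver_dice = NA_real_,
                   liver_dice_com = NA_real_,
                   params = c(tx = 0, ty = 0, tz = 0)),
              class = "liver_registration")
  }
  log$liver_dice <- reg$liver_dice

  corr <- run_stage("match", {
    map_fu_reg <- resample_to_baseline(map_fu, reg$transform, map_bl$geometry)
    cent_fu <- if (nrow(lesions_fu)) {
      tibble::tibble(
        followup_id = lesions_fu$id,
        as.data.frame(apply_transform(reg$transform, as.matrix(
          lesions_fu[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])) |>
            `colnames<-`(c("x", "y", "z")))
      )
    } else NULL
    cand <- pairwise_scores(map_bl, map_fu_reg, centroids_fu_mm = cent_fu)
    match_lesions(cand, bl_ids = label_ids(map_bl), fu_ids = label_ids(map_fu),
                  max_distance_mm = config$matching$max_distance_mm)
  })
  log$correspondence <- c(matched = nrow(corr$matched), new = length(corr$new_ids),
                          disappeared = length(corr$disappeared_ids),
                          merged = nrow(corr$merged))

  relab <- run_stage("relabel", relabel_maps(map_bl, map_fu, corr))
  growth <- run_stage("measure", growth_table(lesions_bl, lesions_fu, relab$mapping))
  thr <- do.call(threshold_config, config$thresholds)
  growth <- run_stage("classify", classify_growth(growth, thr))
  report <- run_stage("report", build_report(growth, order_by = config$report$order_by))
  log$category_counts <- report$counts
  log$tumor_load_cm3 <- c(baseline = report$tumor_load_bl_cm3,
                          followup = report$tumor_load_fu_cm3,
                          delta = report$tumor_load_delta_cm3)

  cats <- stats::setNames(as.character(growth$category), growth$label)
  cat_bl <- run_stage("report", write_category_volume(relab$baseline, cats))
  cat_fu <- run_stage("report", write_category_volume(relab$followup, cats))

  result <- structure(list(
    report = report, growth = growth,
    maps = list(baseline = relab$baseline, followup = relab$followup),
    category_maps = list(baseline = cat_bl, followup = cat_fu),
    correspondence = corr, registration = reg, log = log
  ), class = "tracking_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      report_csv = file.path(out_dir, "growth_table.csv"),
      report_json = file.path(out_dir, "growth_table.json"),
      summary = file.path(out_dir, "summary.json"),
      baseline_labels = file.path(out_dir, "baseline_labels.nii.gz"),
      followup_labels = file.path(out_dir, "followup_labels.nii.gz"),
      baseline_categories = file.path(out_dir, "baseline_categories.nii.gz"),
      followup_categories = file.path(out_dir, "followup_categories.nii.gz"),
      run_log = file.path(out_dir, "run_log.json")
    )
    fmt <- config$report$format
    if (fmt %in% c("csv", "both"))
      write_report_table(report, paths[["report_csv"]], "csv")
    if (fmt %in% c("json", "both"))
      write_report_table(report, paths[["report_json"]], "json")
    jsonlite::write_json(glance(report), paths[["summary"]],
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    write_labelmap(relab$baseline, paths[["baseline_labels"]])
    write_labelmap(relab$followup, paths[["followup_labels"]])
    write_labelmap(cat_bl, paths[["baseline_categories"]])
    write_labelmap(cat_fu, paths[["followup_categories"]])
    jsonlite::write_json(log, paths[["run_log"]], auto_unbox = TRUE, digits = NA)
    result$paths <- paths[file.exists(paths)]
  }
  result
}

#' @export
print.tracking_result <- function(x, ...) {
  cat("<tracking_result>\n")
  print(x$report)
  if (!is.na(x$registration$liver_dice))
    cat("  liver Dice after registration: ",
        round(x$registration$liver_dice, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname track_patient
#' @param x A `tracking_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tracking_result <- function(x, ...) tidy(x$report)

#' @rdname track_patient
#' @exportS3Method generics::glance
glance.tracking_result <- function(x, ...) {
  dplyr::mutate(glance(x$report), liver_dice = x$registration$liver_dice)
}
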