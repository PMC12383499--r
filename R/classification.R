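#' RECIST 1.1-adapted classification thresholds
#'
#' The per-lesion response thresholds: a lesion is progressive when its
#' largest axial diameter increased by at least `progressive_pct` percent,
#' regressive when it decreased by at least `regressive_pct` percent, and
#' too small to measure when its diameter is below `min_measurable_mm` at
#' both timepoints. Both thresholds are closed ("at least"): exactly +20%
#' is progressive and exactly -30% is regressive.
#'
#' @param progressive_pct Minimum relative diameter increase, percent
#'   (default 20, must be > 0).
#' @param regressive_pct Minimum relative diameter decrease, percent
#'   magnitude (default 30, must be > 0; applied as `<= -regressive_pct`).
#' @param min_measurable_mm Measurability cut-off in mm (default 5).
#' @param fold_disappeared_into_regressive Report disappeared lesions as
#'   regressive instead of a distinct category (default `FALSE`).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(progressive_pct = 20, regressive_pct = 30,
                             min_measurable_mm = 5,
                             fold_disappeared_into_regressive = FALSE) {
  if (!is.numeric(progressive_pct) || progressive_pct <= 0)
    stop("`progressive_pct` must be > 0", call. = FALSE)
  if (!is.numeric(regressive_pct) || regressive_pct <= 0)
    stop("`regressive_pct` must be > 0", call. = FALSE)
  if (!is.numeric(min_measurable_mm) || min_measurable_mm <= 0)
    stop("`min_measurable_mm` must be > 0", call. = FALSE)
  structure(list(progressive_pct = progressive_pct,
                 regressive_pct = regressive_pct,
                 min_measurable_mm = min_measurable_mm,
                 fold_disappeared_into_regressive =
                   isTRUE(fold_disappeared_into_regressive)),
            class = "threshold_config")
}

#' Lesion category levels
#' @return Character vector of the categories, in reporting order.
#' @export
category_levels <- function() {
  c("progressive", "stable", "regressive", "new", "merged", "too_small",
    "disappeared")
}

#' Integer codes used in category-coded label volumes
#' @return Named integer vector mapping category to voxel code.
#' @export
category_codes <- function() {
  stats::setNames(seq_along(category_levels()), category_levels())
}

#' Categorise tracked lesions
#'
#' Assigns each growth record exactly one category with this precedence:
#' new, merged and disappeared statuses map to their own categories; then
#' a matched lesion smaller than the measurability cut-off at *both*
#' timepoints is too small to measure; then the relative diameter change
#' decides progressive (`>= +progressive_pct`), regressive
#' (`<= -regressive_pct`) or stable. A new lesion is always "new"
#' regardless of size -- the too-small condition requires both timepoints,
#' which a new lesion cannot satisfy. Classification uses diameters only;
#' volume changes are reported but never classified on.
#'
#' @param records Growth tibble from [growth_table()] (or [growth_record()]).
#' @param thresholds A [threshold_config()].
#' @return `records` with a `category` factor column appended.
#' @export
classify_growth <- function(records, thresholds = threshold_config()) {
  if (!inherits(thresholds, "threshold_config"))
    stop("`thresholds` must be a threshold_config", call. = FALSE)
  if (!nrow(records)) {
    records$category <- factor(character(), levels = category_levels())
    return(records)
  }
  matched <- records$status == "matched"
  if (any(matched & (is.na(records$diam_bl_mm) | is.na(records$diam_fu_mm))))
    stop("matched growth record lacking diameters", call. = FALSE)
  small <- matched &
    records$diam_bl_mm < thresholds$min_measurable_mm &
    records$diam_fu_mm < thresholds$min_measurable_mm
  rel <- records$ddiam_rel_pct
  cat <- dplyr::case_when(
    records$status == "new" ~ "new",
    records$status == "merged" ~ "merged",
    records$status == "disappeared" ~
      if (thresholds$fold_disappeared_into_regressive) "regressive" else "disappeared",
    small ~ "too_small",
    !is.na(rel) & rel >= thresholds$progressive_pct ~ "progressive",
    !is.na(rel) & rel <= -thresholds$regressive_pct ~ "regressive",
    .default = "stable"
  )
  records$category <- factor(cat, levels = category_levels())
  records
}

#' Count lesions per category
#'
#' @param x A `category` factor/character vector, or a classified growth
#'   tibble with a `category` column.
#' @return Named integer vector over all of [category_levels()]; counts
#'   sum to the number of lesions.
#' @export
category_counts <- function(x) {
  if (is.data.frame(x)) x <- x$category
  x <- factor(as.character(x), levels = category_levels())
  if (anyNA(x)) stop("unknown category value", call. = FALSE)
  table(x) |> as.integer() |> stats::setNames(category_levels())
}
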