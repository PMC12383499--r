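#' Assemble the per-patient decision-support report
#'
#' Orders the classified growth records the way the reading radiologist
#' sees them -- new lesions first, then matched lesions by descending
#' relative growth, then merged, then disappeared; ties by label -- and
#' attaches tumor loads, category counts and the orange/blue colour code
#' (orange for progressive or new lesions, blue otherwise).
#'
#' Tumor loads are derived from the rows themselves: the baseline load
#' sums every lesion present at baseline (matched, merged, disappeared),
#' the follow-up load every component present at follow-up (matched, new),
#' so the load delta equals the signed sum of per-lesion volume changes
#' (new lesions count positive, disappeared and merged-away negative).
#'
#' @param records Classified growth tibble from [classify_growth()].
#' @param order_by `"diameter"` (default) sorts matched rows by relative
#'   diameter change, `"volume"` by relative volume change.
#' @return An object of class `patient_report`: list with `rows` (ordered
#'   tibble incl. `category` and `color`), `tumor_load_bl_cm3`,
#'   `tumor_load_fu_cm3`, `tumor_load_delta_cm3`, `counts`.
#' @export
build_report <- function(records, order_by = c("diameter", "volume")) {
  order_by <- match.arg(order_by)
  if (!"category" %in% names(records))
    stop("records must be classified first (see classify_growth())", call. = FALSE)
  growth_col <- if (order_by == "diameter") "ddiam_rel_pct" else "dvol_rel_pct"
  status_rank <- c(new = 1L, matched = 2L, merged = 3L, disappeared = 4L)
  rows <- records |>
    dplyr::mutate(
      color = ifelse(.data$category %in% c("progressive", "new"), "orange", "blue"),
      .rank = status_rank[.data$status],
      .growth = ifelse(.data$status == "matched", .data[[growth_col]], NA_real_)
    ) |>
    dplyr::arrange(.data$.rank, dplyr::desc(!is.na(.data$.growth)),
                   dplyr::desc(.data$.growth), .data$label) |>
    dplyr::select(-".rank", -".growth")
  load_bl <- sum(rows$vol_bl_cm3, na.rm = TRUE)
  load_fu <- sum(rows$vol_fu_cm3, na.rm = TRUE)
  structure(list(
    rows = rows,
    tumor_load_bl_cm3 = load_bl,
    tumor_load_fu_cm3 = load_fu,
    tumor_load_delta_cm3 = load_fu - load_bl,
    counts = category_counts(rows)
  ), class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat("<patient_report> ", nrow(x$rows), " lesion tracks\n", sep = "")
  cat("  tumor load: ", sprintf("%.2f", x$tumor_load_bl_cm3), " -> ",
      sprintf("%.2f", x$tumor_load_fu_cm3), " cm^3 (delta ",
      sprintf("%+.2f", x$tumor_load_delta_cm3), " cm^3)\n", sep = "")
  nz <- x$counts[x$counts > 0]
  if (length(nz))
    cat("  categories: ", paste(names(nz), nz, sep = " ", collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' @rdname build_report
#' @param x A `patient_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.patient_report <- function(x, ...) x$rows

#' One-row summary of a patient report
#' @param x A `patient_report`.
#' @param ... Unused.
#' @return Tibble with lesion count, tumor loads and per-category counts.
#' @exportS3Method generics::glance
glance.patient_report <- function(x, ...) {
  cnt <- as.list(x$counts)
  names(cnt) <- paste0("n_", names(cnt))
  tibble::as_tibble(c(list(
    n_lesions = nrow(x$rows),
    tumor_load_bl_cm3 = x$tumor_load_bl_cm3,
    tumor_load_fu_cm3 = x$tumor_load_fu_cm3,
    tumor_load_delta_cm3 = x$tumor_load_delta_cm3
  ), cnt))
}

#' Plot differential growth of a tracked patient
#'
#' Waterfall chart of the relative diameter change of matched lesions,
#' coloured with the report's orange/blue coding; new, merged and
#' disappeared lesions are listed in the subtitle.
#'
#' @param object A `patient_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.patient_report <- function(object, ...) {
  rows <- object$rows
  m <- rows[rows$status == "matched" & !is.na(rows$ddiam_rel_pct), ]
  other <- category_counts(rows)[c("new", "merged", "disappeared")]
  sub <- paste(paste(other, names(other)), collapse = ", ")
  ggplot2::ggplot(m, ggplot2::aes(
    x = stats::reorder(factor(.data$label), -.data$ddiam_rel_pct),
    y = .data$ddiam_rel_pct, fill = .data$color)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(20, -30), linetype = "dashed") +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(
      x = "lesion", y = "largest axial diameter change (% of baseline)",
      title = sprintf("Tumor load %.2f -> %.2f cm^3",
                      object$tumor_load_bl_cm3, object$tumor_load_fu_cm3),
      subtitle = sub) +
    ggplot2::theme_minimal()
}

report_columns <- c("label", "category", "vol_bl_cm3", "vol_fu_cm3",
                    "dvol_abs_cm3", "dvol_rel_pct", "diam_bl_mm",
                    "diam_fu_mm", "ddiam_abs_mm", "ddiam_rel_pct")

rounded_rows <- function(report) {
  r <- report$rows
  cm3 <- c("vol_bl_cm3", "vol_fu_cm3", "dvol_abs_cm3")
  one <- c("dvol_rel_pct", "diam_bl_mm", "diam_fu_mm", "ddiam_abs_mm",
           "ddiam_rel_pct")
  r[cm3] <- lapply(r[cm3], round, digits = 2)
  r[one] <- lapply(r[one], round, digits = 1)
  r$category <- as.character(r$category)
  r[report_columns]
}

#' Write the differential-growth table
#'
#' One row per lesion with columns `label`, `category`, `vol_bl_cm3`,
#' `vol_fu_cm3`, `dvol_abs_cm3`, `dvol_rel_pct`, `diam_bl_mm`,
#' `diam_fu_mm`, `ddiam_abs_mm`, `ddiam_rel_pct`, in report order.
#' Volumes are written in cm^3 with two decimals, millimetre and percent
#' values with one decimal; missing fields are empty (CSV) or null (JSON).
#'
#' @param report A `patient_report`.
#' @param path Output file path.
#' @param format `"csv"` (default) or `"json"`. The JSON rendering also
#'   carries the tumor-load summary and category counts.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  r <- rounded_rows(report)
  if (format == "csv") {
    readr::write_csv(r, path, na = "")
  } else {
    jsonlite::write_json(list(
      tumor_load_bl_cm3 = round(report$tumor_load_bl_cm3, 2),
      tumor_load_fu_cm3 = round(report$tumor_load_fu_cm3, 2),
      tumor_load_delta_cm3 = round(report$tumor_load_delta_cm3, 2),
      counts = as.list(report$counts),
      rows = r
    ), path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Write a category-coded label volume
#'
#' Replaces each lesion label by the small-integer code of its category
#' (see [category_codes()]); background stays 0. This keeps the volume
#' analysis-ready; mapping codes to display colours (orange for
#' progressive/new, blue otherwise) is a viewer concern.
#'
#' @param map A consistently relabelled [label_map()].
#' @param categories Named vector mapping label to category, or a
#'   classified tibble with `label` and `category` columns.
#' @param path Output NIfTI path, or `NULL` to just return the coded map.
#' @return The category-coded [label_map()], invisibly when written.
#' @export
write_category_volume <- function(map, categories, path = NULL) {
  if (is.data.frame(categories))
    categories <- stats::setNames(as.character(categories$category),
                                  categories$label)
  ids <- label_ids(map)
  missing <- setdiff(as.character(ids), names(categories))
  if (length(missing))
    stop("label(s) without category: ", paste(missing, collapse = ", "),
         call. = FALSE)
  codes <- category_codes()
  bad <- setdiff(unique(as.character(categories)), names(codes))
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "), call. = FALSE)
  lut <- integer(max(c(ids, 0L)) + 1L)
  lut[ids + 1L] <- codes[as.character(categories[as.character(ids)])]
  grid <- map$grid
  pos <- which(grid > 0L)
  grid[pos] <- lut[grid[pos] + 1L]
  coded <- label_map(grid, map$geometry)
  if (!is.null(path)) {
    write_labelmap(coded, path)
    return(invisible(coded))
  }
  coded
}
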