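demo_records <- function() {
  classify_growth(dplyr::bind_rows(
    growth_record("matched", 1L, vol_bl_cm3 = 1.0, diam_bl_mm = 10,
                  vol_fu_cm3 = 1.6, diam_fu_mm = 12.5),   # +25% progressive
    growth_record("matched", 2L, vol_bl_cm3 = 2.0, diam_bl_mm = 12,
                  vol_fu_cm3 = 1.8, diam_fu_mm = 10.8),   # -10% stable
    growth_record("matched", 3L, vol_bl_cm3 = 0.8, diam_bl_mm = 8,
                  vol_fu_cm3 = 0.9, diam_fu_mm = 8.4),    # +5% stable
    growth_record("new", 5L, vol_fu_cm3 = 0.3, diam_fu_mm = 6),
    growth_record("disappeared", 4L, vol_bl_cm3 = 0.5, diam_bl_mm = 7),
    growth_record("merged", 6L, vol_bl_cm3 = 0.4, diam_bl_mm = 6.5)
  ))
}

test_that("report rows are ordered new-first, then by descending growth", {
  rep <- build_report(demo_records())
  expect_equal(rep$rows$label, c(5L, 1L, 3L, 2L, 6L, 4L))
  expect_equal(rep$rows$status[1], "new")
  # deterministic: rebuilding gives identical ordering
  expect_identical(rep$rows, build_report(demo_records())$rows)
})

test_that("tumor loads satisfy exact conservation over the rows", {
  rep <- build_report(demo_records())
  rows <- rep$rows
  expect_equal(rep$tumor_load_bl_cm3, 1.0 + 2.0 + 0.8 + 0.5 + 0.4)
  expect_equal(rep$tumor_load_fu_cm3, 1.6 + 1.8 + 0.9 + 0.3)
  expect_equal(rep$tumor_load_delta_cm3,
               rep$tumor_load_fu_cm3 - rep$tumor_load_bl_cm3)
  # signed per-lesion sum: matched deltas, new +vol_fu, disappeared/merged -vol_bl
  signed <- sum(rows$dvol_abs_cm3[rows$status == "matched"]) +
    sum(rows$vol_fu_cm3[rows$status == "new"]) -
    sum(rows$vol_bl_cm3[rows$status %in% c("disappeared", "merged")])
  expect_equal(rep$tumor_load_delta_cm3, signed)
  expect_identical(rep$counts, category_counts(rows))
})

test_that("rows are colour-coded orange for progressive/new, blue otherwise", {
  rep <- build_report(demo_records())
  expect_identical(rep$rows$color,
                   ifelse(rep$rows$category %in% c("progressive", "new"),
                          "orange", "blue"))
})

test_that("CSV and JSON renderings agree and round-trip at stated precision", {
  rep <- build_report(demo_records())
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report_table(rep, csv, "csv")
  write_report_table(rep, js, "json")
  got_csv <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(names(got_csv),
               c("label", "category", "vol_bl_cm3", "vol_fu_cm3", "dvol_abs_cm3",
                 "dvol_rel_pct", "diam_bl_mm", "diam_fu_mm", "ddiam_abs_mm",
                 "ddiam_rel_pct"))
  expect_equal(got_csv$vol_bl_cm3, round(rep$rows$vol_bl_cm3, 2))
  expect_equal(got_csv$ddiam_rel_pct, round(rep$rows$ddiam_rel_pct, 1))
  got_js <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(got_js$rows$vol_bl_cm3, got_csv$vol_bl_cm3)
  expect_equal(got_js$rows$ddiam_rel_pct, got_csv$ddiam_rel_pct)
  expect_equal(got_js$tumor_load_delta_cm3, round(rep$tumor_load_delta_cm3, 2))

  # empty report -> header-only CSV
  empty <- build_report(classify_growth(demo_records()[0, 1:11]))
  csv2 <- withr::local_tempfile(fileext = ".csv")
  write_report_table(empty, csv2)
  expect_equal(nrow(readr::read_csv(csv2, show_col_types = FALSE)), 0)
})

test_that("category volumes encode categories per voxel, background intact", {
  grid <- array(0L, c(16, 8, 4))
  grid[2:4, 2:4, 2:3] <- 1L
  grid[8:10, 2:4, 2:3] <- 2L
  grid[13:14, 5:7, 2:3] <- 3L
  map <- label_map(grid, image_geometry(c(16, 8, 4), c(1, 1, 1)))
  cats <- c(`1` = "progressive", `2` = "stable", `3` = "new")
  coded <- write_category_volume(map, cats)
  codes <- category_codes()
  for (lab in 1:3) {
    expect_true(all(coded$grid[grid == lab] == codes[[cats[[lab]]]]))
  }
  expect_true(all(coded$grid[grid == 0L] == 0L))
  # voxel-weighted code histogram matches the per-lesion voxel counts
  hist <- table(coded$grid[coded$grid > 0L])
  expect_identical(as.integer(hist[as.character(codes[["progressive"]])]),
                   sum(grid == 1L))
  expect_error(write_category_volume(map, cats[1:2]), "without category")
})

test_that("tidy, glance and autoplot expose the report in standard forms", {
  rep <- build_report(demo_records())
  expect_identical(tidy(rep), rep$rows)
  g <- glance(rep)
  expect_equal(g$n_lesions, 6L)
  expect_equal(g$n_progressive, 1L)
  expect_equal(g$tumor_load_delta_cm3, rep$tumor_load_delta_cm3)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})
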