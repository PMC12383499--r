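test_that("volumes follow voxel count times voxel volume", {
  g1 <- image_geometry(c(10, 10, 10), c(1, 1, 1))
  expect_equal(lesion_volume_cm3(1000, g1), 1.0)
  g2 <- image_geometry(c(4, 4, 4), c(2, 2, 2))
  expect_equal(lesion_volume_cm3(1, g2), 0.008)
})

test_that("rasterised spheres match the analytic volume and diameter", {
  # r chosen so (4/3) pi r^3 = 1 cm^3
  s <- sphere_mask(6.2035, spacing = c(1, 1, 1), center_off = c(0.3, -0.2, 0.4))
  les <- lesion_table(label_components(s))
  expect_equal(nrow(les), 1L)
  expect_lt(abs(les$volume_cm3 - 1.0), 0.05)

  s5 <- sphere_mask(5, spacing = c(1, 1, 1))
  les5 <- lesion_table(label_components(s5))
  expect_lt(abs(les5$diam_axial_mm - 10), 1 + 1e-9)
  # convergence: finer spacing means smaller relative volume error
  err <- sapply(c(2, 1, 0.5), function(sp) {
    v <- lesion_table(label_components(sphere_mask(5, spacing = rep(sp, 3),
                                                   center_off = rep(0.21, 3))))$volume_cm3
    abs(v - 4 / 3 * pi * 125 / 1000)
  })
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
})

test_that("largest axial diameter is the in-plane Feret distance over slices", {
  rod <- array(0L, c(3, 7, 3))
  rod[2, 2:6, 2] <- 1L                 # 1x5x1 rod in one axial plane
  les <- lesion_table(label_components(tiny_mask(rod)))
  expect_equal(les$diam_axial_mm, 4.0)

  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_equal(lesion_table(label_components(tiny_mask(single)))$diam_axial_mm, 0.0)

  # brute-force pairwise oracle on a random blob
  set.seed(5)
  arr <- array(0L, c(10, 10, 6))
  arr[sample(600, 60)] <- 1L
  geom <- image_geometry(c(10, 10, 6), c(1.1, 0.8, 2))
  vox <- which(arr > 0L)
  got <- largest_axial_diameter_mm(vox, geom)
  idx <- arrayInd(vox, c(10, 10, 6))
  best <- 0
  for (a in seq_along(vox)) for (b in seq_len(a - 1)) {
    if (idx[a, 3] != idx[b, 3]) next
    d <- sqrt(sum(((idx[a, ] - idx[b, ]) * c(1.1, 0.8, 2))^2))
    best <- max(best, d)
  }
  expect_equal(got, best)
})

test_that("diameter never decreases when voxels are added", {
  set.seed(9)
  geom <- image_geometry(c(12, 12, 6), c(1, 1, 2))
  vox <- sample(12 * 12 * 6, 40)
  d_prev <- largest_axial_diameter_mm(vox[1:10], geom)
  for (k in c(20, 30, 40)) {
    d_now <- largest_axial_diameter_mm(vox[1:k], geom)
    expect_gte(d_now, d_prev)
    d_prev <- d_now
  }
})

test_that("tumor load is conserved: sum of lesions equals whole-mask volume", {
  set.seed(13)
  arr <- array(as.integer(runif(16^3) < 0.15), c(16, 16, 16))
  geom <- image_geometry(c(16, 16, 16), c(1.3, 1.3, 1.7))
  mask <- binary_mask(arr, geom)
  map <- label_components(mask)
  les <- lesion_table(map)
  expect_identical(tumor_load_cm3(les), sum(les$volume_cm3))
  expect_equal(tumor_load_cm3(les), sum(arr) * prod(c(1.3, 1.3, 1.7)) / 1000)
  expect_identical(tumor_load_cm3(map), tumor_load_cm3(mask))
  expect_equal(tumor_load_cm3(les[0, ]), 0)
})

test_that("growth records carry absolute and relative differences", {
  rec <- growth_record("matched", label = 2L, vol_bl_cm3 = 0.06, diam_bl_mm = 4.8,
                       vol_fu_cm3 = 0.14, diam_fu_mm = 6.5)
  expect_equal(rec$ddiam_abs_mm, 1.7)
  expect_equal(rec$ddiam_rel_pct, 100 * 1.7 / 4.8, tolerance = 1e-12)
  identical_rec <- growth_record("matched", vol_bl_cm3 = 1, diam_bl_mm = 10,
                                 vol_fu_cm3 = 1, diam_fu_mm = 10)
  expect_equal(identical_rec$dvol_abs_cm3, 0)
  expect_equal(identical_rec$ddiam_rel_pct, 0)
  expect_error(growth_record("matched", vol_bl_cm3 = 1, diam_bl_mm = 10), "both")
  expect_error(growth_record("new", vol_bl_cm3 = 1, diam_bl_mm = 10,
                             vol_fu_cm3 = 1, diam_fu_mm = 10), "baseline")
  expect_error(growth_record("merged", vol_bl_cm3 = 1, diam_bl_mm = 10,
                             vol_fu_cm3 = 1, diam_fu_mm = 10), "follow-up")
})

test_that("a phantom sphere grown 10% in radius reports ~+10% diameter change", {
  bl <- sphere_mask(6, spacing = c(1, 1, 1), center_off = c(0.2, 0.1, -0.3), pad = 4)
  fu <- sphere_mask(6.6, spacing = c(1, 1, 1), center_off = c(0.2, 0.1, -0.3), pad = 4)
  dbl <- lesion_table(label_components(bl))$diam_axial_mm
  dfu <- lesion_table(label_components(fu))$diam_axial_mm
  rel <- 100 * (dfu - dbl) / dbl
  expect_lt(abs(rel - 10), 3)
})

test_that("reported sizes come from native space, untouched by resampling", {
  pair <- phantom_scenario("all_stable", seed = 1)
  map_fu <- label_components(pair$lesions_fu)
  native <- lesion_table(map_fu)
  reg <- estimate_liver_registration(pair$liver_bl, pair$liver_fu)
  res <- resample_to_baseline(map_fu, reg$transform,
                              label_components(pair$lesions_bl)$geometry)
  resampled <- lesion_table(res)
  # the tracker must keep using `native` for metrics; resampling visibly
  # perturbs per-lesion voxel counts, which is why it is for overlap only
  run <- track_patient(pair$lesions_bl, pair$lesions_fu,
                       pair$liver_bl, pair$liver_fu)
  fu_vols <- sort(run$growth$vol_fu_cm3[run$growth$status == "matched"])
  expect_equal(fu_vols, sort(native$volume_cm3))
  expect_equal(nrow(resampled), nrow(native))
})
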