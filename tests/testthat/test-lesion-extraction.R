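test_that("connected clusters are isolated into individual lesions", {
  arr <- array(0L, c(10, 10, 10))
  arr[2:3, 2:3, 2:3] <- 1L            # one 2x2x2 cube
  map <- label_components(tiny_mask(arr))
  les <- lesion_table(map)
  expect_equal(nrow(les), 1L)
  expect_equal(les$n_voxels, 8L)

  arr[7:8, 7:8, 7:8] <- 1L            # second cube, >= 2 voxels away
  les2 <- lesion_table(label_components(tiny_mask(arr)))
  expect_equal(nrow(les2), 2L)
  expect_equal(sort(les2$n_voxels), c(8L, 8L))
})

test_that("corner-touching voxels fuse at 26-connectivity but not at 6", {
  arr <- array(0L, c(5, 5, 5))
  arr[2, 2, 2] <- 1L
  arr[3, 3, 3] <- 1L
  expect_equal(nrow(lesion_table(label_components(tiny_mask(arr), 26))), 1L)
  expect_equal(nrow(lesion_table(label_components(tiny_mask(arr), 6))), 2L)
})

test_that("labelling agrees with an exhaustive flood-fill oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    arr <- array(as.integer(runif(12^3) < 0.25), c(12, 12, 12))
    for (conn in c(6L, 18L, 26L)) {
      got <- label_components(tiny_mask(arr), conn)$grid
      want <- flood_fill_labels(arr, conn)
      expect_true(partition_equal(label_partition(got), label_partition(want)),
                  label = sprintf("seed %d connectivity %d", seed, conn))
    }
  }
})

test_that("lesions partition the foreground and counts shrink with connectivity", {
  set.seed(42)
  arr <- array(as.integer(runif(14^3) < 0.2), c(14, 14, 14))
  mask <- tiny_mask(arr)
  les <- lesion_table(label_components(mask, 26))
  expect_identical(sum(les$n_voxels), sum(arr))
  expect_identical(sort(unlist(les$voxels)), which(arr > 0L))
  n6 <- nrow(lesion_table(label_components(mask, 6)))
  n18 <- nrow(lesion_table(label_components(mask, 18)))
  n26 <- nrow(lesion_table(label_components(mask, 26)))
  expect_true(n6 >= n18 && n18 >= n26)
  # deterministic given mask and connectivity
  expect_identical(label_components(mask, 26)$grid, label_components(mask, 26)$grid)
})

test_that("liver restriction keeps lesions by majority membership, unclipped", {
  arr <- array(0L, c(12, 6, 6))
  arr[2:6, 2, 2] <- 1L                 # 5-voxel rod
  arr[2:6, 5, 5] <- 1L                 # second rod fully inside
  map <- label_components(tiny_mask(arr))
  liver40 <- array(0L, c(12, 6, 6)); liver40[2:3, , ] <- 1L   # covers 2/5
  liver60 <- array(0L, c(12, 6, 6)); liver60[2:4, , ] <- 1L   # covers 3/5
  geom <- map$geometry
  kept40 <- lesion_table(restrict_to_liver(map, binary_mask(liver40, geom)))
  expect_equal(nrow(kept40), 0L)       # 40% inside both rods -> removed
  kept60 <- lesion_table(restrict_to_liver(map, binary_mask(liver60, geom)))
  expect_equal(nrow(kept60), 2L)       # 60% inside -> kept
  expect_equal(kept60$n_voxels, c(5L, 5L))   # kept lesions are not clipped
  liver_one <- array(0L, c(12, 6, 6)); liver_one[, 5, 5] <- 1L  # only rod 2
  kept <- lesion_table(restrict_to_liver(map, binary_mask(liver_one, geom)))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$id, 1L)            # renumbered 1..M
  expect_equal(kept$n_voxels, 5L)
  other_geom <- binary_mask(liver60, image_geometry(c(12, 6, 6), c(2, 1, 1)))
  expect_error(restrict_to_liver(map, other_geom), "geometry")
})

test_that("centroids equal the mean of voxel-centre world coordinates", {
  arr <- array(0L, c(5, 5, 5)); arr[1, 1, 1] <- 1L
  les <- lesion_table(label_components(tiny_mask(arr)))
  expect_equal(unlist(les[1, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")],
                      use.names = FALSE), c(0, 0, 0))

  geom5 <- image_geometry(c(5, 5, 5), c(1, 1, 1))
  two_vox <- which(array(seq_len(125), c(5, 5, 5)) %in% c(1L, 3L))
  expect_equal(as.numeric(lesion_centroid_mm(two_vox, geom5)), c(1, 0, 0))

  set.seed(3)
  arr3 <- array(0L, c(9, 9, 9))
  arr3[sample(9^3, 50)] <- 1L
  geom <- image_geometry(c(9, 9, 9), c(1.2, 0.9, 2.1))
  mask3 <- binary_mask(arr3, geom)
  les3 <- lesion_table(label_components(mask3))
  # independent loop over every voxel of every lesion
  for (r in seq_len(nrow(les3))) {
    acc <- c(0, 0, 0)
    for (lin in les3$voxels[[r]]) {
      idx <- arrayInd(lin, c(9, 9, 9)) - 1L
      acc <- acc + as.numeric(idx) * c(1.2, 0.9, 2.1)
    }
    expect_equal(as.numeric(les3[r, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")]),
                 acc / les3$n_voxels[r])
  }
  expect_equal(as.numeric(lesion_centroid_mm(les3$voxels[[1]], geom)),
               as.numeric(les3[1, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")]))
})
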