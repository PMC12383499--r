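two_maps <- function(bl_arr, fu_arr, spacing = c(1, 1, 1)) {
  geom <- image_geometry(dim(bl_arr), spacing)
  list(bl = label_components(binary_mask(array(as.integer(bl_arr != 0), dim(bl_arr)), geom)),
       fu = label_components(binary_mask(array(as.integer(fu_arr != 0), dim(fu_arr)), geom)))
}

test_that("Dice and centroid distance follow their defining formulas", {
  # |Vi| = 4, |Vj| = 6, |Vi n Vj| = 3 -> Dice = 0.6
  bl <- array(0L, c(10, 6, 4)); bl[2:5, 2, 2] <- 1L
  fu <- array(0L, c(10, 6, 4)); fu[3:8, 2, 2] <- 1L
  m <- two_maps(bl, fu)
  sc <- pairwise_scores(m$bl, m$fu)
  expect_equal(sc$dice, 2 * 3 / (4 + 6))

  # 3-4-5 right triangle between single-voxel centroids
  bl2 <- array(0L, c(8, 8, 3)); bl2[1, 1, 2] <- 1L
  fu2 <- array(0L, c(8, 8, 3)); fu2[4, 5, 2] <- 1L
  sc2 <- pairwise_scores(two_maps(bl2, fu2)$bl, two_maps(bl2, fu2)$fu)
  expect_equal(sc2$distance_mm, 5)
  expect_equal(sc2$dice, 0)
})

test_that("formula Dice equals brute-force voxel-set intersection, exactly", {
  for (seed in 1:25) {
    set.seed(seed)
    d <- sample(8:18, 3, replace = TRUE)
    a <- array(as.integer(runif(prod(d)) < 0.4), d)
    b <- array(as.integer(runif(prod(d)) < 0.4), d)
    geom <- image_geometry(d, c(1, 1, 1))
    map_a <- label_map(array(a, d), geom)   # single-label maps
    map_b <- label_map(array(b, d), geom)
    if (!sum(a) || !sum(b)) next
    sc <- pairwise_scores(map_a, map_b)
    want <- 2 * length(intersect(which(a > 0L), which(b > 0L))) / (sum(a) + sum(b))
    expect_identical(max(sc$dice), want)
    # symmetry under argument swap
    expect_identical(max(pairwise_scores(map_b, map_a)$dice), want)
  }
})

test_that("a volume matched against itself is a perfect correspondence", {
  pair <- phantom_scenario("identity", seed = 1)
  map <- label_components(pair$lesions_bl)
  sc <- pairwise_scores(map, map)
  corr <- match_lesions(sc, label_ids(map), label_ids(map))
  expect_equal(nrow(corr$matched), length(label_ids(map)))
  expect_true(all(corr$matched$baseline_id == corr$matched$followup_id))
  expect_true(all(corr$matched$dice == 1))
  expect_length(corr$new_ids, 0)
  expect_length(corr$disappeared_ids, 0)
  expect_equal(nrow(corr$merged), 0)
})

test_that("fused components are flagged merged; leftovers become new/disappeared", {
  # two baseline blobs -> one follow-up union blob, plus one brand-new blob
  bl <- array(0L, c(32, 10, 6))
  bl[3:7, 3:6, 2:4] <- 1L
  bl[10:14, 3:6, 2:4] <- 1L
  fu <- array(0L, c(32, 10, 6))
  fu[3:14, 3:6, 2:4] <- 1L                   # union of both
  fu[27:29, 7:9, 2:4] <- 1L                  # new lesion, beyond the 10 mm gate
  m <- two_maps(bl, fu)
  sc <- pairwise_scores(m$bl, m$fu)
  corr <- match_lesions(sc, label_ids(m$bl), label_ids(m$fu))
  expect_equal(nrow(corr$matched), 1)
  expect_equal(nrow(corr$merged), 1)
  expect_equal(corr$merged$followup_id, corr$matched$followup_id)
  expect_length(corr$new_ids, 1)
  expect_length(corr$disappeared_ids, 0)

  # empty follow-up: everything disappears
  corr2 <- match_lesions(sc[0, ], bl_ids = label_ids(m$bl), fu_ids = integer())
  expect_equal(corr2$disappeared_ids, label_ids(m$bl))
})

test_that("every lesion lands in exactly one correspondence bucket", {
  for (seed in c(2, 4, 6)) {
    cons <- random_constellation(k = 4, seed = seed)
    m <- list(bl = label_components(cons$bl), fu = label_components(cons$fu))
    sc <- pairwise_scores(m$bl, m$fu)
    corr <- match_lesions(sc, label_ids(m$bl), label_ids(m$fu))
    td <- tidy(corr)
    bl_seen <- td$baseline_id[!is.na(td$baseline_id)]
    fu_seen <- td$followup_id[td$status %in% c("matched", "new")]
    expect_setequal(bl_seen, label_ids(m$bl))
    expect_false(anyDuplicated(bl_seen) > 0)
    expect_setequal(fu_seen, label_ids(m$fu))
  }
})

test_that("greedy assignment equals the exhaustive optimum on small instances", {
  for (seed in 1:8) {
    cons <- random_constellation(k = sample(3:6, 1), seed = 100 + seed)
    m <- list(bl = label_components(cons$bl), fu = label_components(cons$fu))
    sc <- pairwise_scores(m$bl, m$fu)
    corr <- match_lesions(sc, label_ids(m$bl), label_ids(m$fu))
    got <- corr$matched[corr$matched$dice > 0, c("baseline_id", "followup_id")]
    want <- exhaustive_matching(sc)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE, label = sprintf("instance %d", seed))
  }
})

test_that("relabelling makes labels consistent and numbers new lesions last", {
  bl <- array(0L, c(30, 12, 6))
  bl[3:6, 3:5, 2:4] <- 1L
  bl[12:15, 3:5, 2:4] <- 1L
  bl[22:25, 3:5, 2:4] <- 1L
  fu <- bl
  fu[3:6, 8:10, 2:4] <- 1L                   # one new lesion among 3 matched
  m <- two_maps(bl, fu)
  corr <- match_lesions(pairwise_scores(m$bl, m$fu), label_ids(m$bl), label_ids(m$fu))
  relab <- relabel_maps(m$bl, m$fu, corr)
  expect_identical(relab$baseline$grid, m$bl$grid)
  new_row <- relab$mapping[relab$mapping$status == "new", ]
  expect_equal(new_row$track_label, 4L)
  # matched lesions carry the same label in both maps
  for (r in seq_len(nrow(corr$matched))) {
    b <- corr$matched$baseline_id[r]
    vox <- which(m$bl$grid == b)
    expect_true(all(relab$followup$grid[which(m$fu$grid == corr$matched$followup_id[r])] == b))
    expect_true(all(relab$baseline$grid[vox] == b))
  }
  # bijection on each map's label set
  expect_setequal(label_ids(relab$followup), c(corr$matched$baseline_id, 4L))
})

test_that("the merge scenario keeps the absorbing partner's label in follow-up", {
  pair <- phantom_scenario("merge", seed = 1)
  res <- track_patient(pair$lesions_bl, pair$lesions_fu, pair$liver_bl, pair$liver_fu)
  tr <- pair$truth$lesions
  grp <- tr[!is.na(tr$merge_group), ]
  merged_row <- res$growth[res$growth$status == "merged", ]
  expect_equal(nrow(merged_row), 1)
  expect_true(merged_row$label %in% grp$bl_label)
  expect_true(merged_row$merged_into %in% grp$bl_label)
  # the follow-up union blob carries the surviving partner's label
  expect_true(merged_row$merged_into %in% label_ids(res$maps$followup))
  expect_false(merged_row$label %in% label_ids(res$maps$followup))
})
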