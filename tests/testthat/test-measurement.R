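test_that("extents use the inclusive pixel-count convention", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(unname(maskExtents(PlantMask(single))), c(1, 1))
  block <- matrix(FALSE, 30, 30); block[6:25, 4:13] <- TRUE  # 10 cols, 20 rows
  expect_equal(unname(maskExtents(PlantMask(block))), c(10, 20))
  expect_equal(unname(maskWidthHeight(PlantMask(block))), c(10, 20))
  expect_equal(unname(maskExtents(PlantMask(matrix(FALSE, 4, 4)))), c(0, 0))
  set.seed(41)
  for (rep in 1:20) {
    m <- randomMask(25, 25, runif(1, 0.02, 0.5))
    expect_equal(unname(maskExtents(PlantMask(m))), scanExtents(m))
  }
})

test_that("maximum Feret diameter equals the pairwise oracle", {
  two <- matrix(FALSE, 6, 6); two[1, 1] <- TRUE; two[5, 4] <- TRUE  # 3-4-5
  expect_equal(maxDiameter(PlantMask(two)), 5)
  rect <- matrix(FALSE, 30, 30); rect[3:22, 5:14] <- TRUE  # 10 x 20 block
  expect_equal(maxDiameter(PlantMask(rect)), sqrt(9^2 + 19^2))
  expect_equal(maxDiameter(PlantMask(matrix(FALSE, 4, 4))), 0)
  one <- matrix(FALSE, 4, 4); one[2, 2] <- TRUE
  expect_equal(maxDiameter(PlantMask(one)), 0)
  set.seed(42)
  for (rep in 1:30) {
    m <- matrix(FALSE, 30, 30)
    n <- sample(2:200, 1)
    m[sample(900, n)] <- TRUE
    expect_equal(maxDiameter(PlantMask(m)), pairwiseDiameter(m),
                 tolerance = 1e-9)
  }
})

test_that("projected area is pixel count times the squared pixel size", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(projectedArea(PlantMask(m), 0.5), 25)
  expect_equal(projectedArea(PlantMask(matrix(FALSE, 3, 3)), 2), 0)
  expect_error(projectedArea(PlantMask(m), 0), "positive")
  set.seed(43)
  m <- randomMask(40, 40, 0.3)
  expect_equal(projectedArea(PlantMask(m), 0.25), sum(m) * 0.0625)
})

test_that("measurement records populate the view-appropriate fields", {
  sideCfg <- ViewConfig("side", classes = list(), mmPerPx = 1)
  block <- matrix(FALSE, 40, 40); block[11:30, 16:25] <- TRUE
  rec <- measurePlant(PlantMask(block), sideCfg, "p1", "d1")
  expect_equal(rec$width_mm, 10)
  expect_equal(rec$height_mm, 20)
  expect_equal(rec$projected_shoot_area_mm2, 200)
  expect_true(is.na(rec$x_extent_mm) && is.na(rec$diameter_mm))
  expect_false(rec$empty_flag)

  empty <- measurePlant(PlantMask(matrix(FALSE, 5, 5)), sideCfg)
  expect_true(empty$empty_flag)
  expect_equal(empty$projected_shoot_area_mm2, 0)
  expect_equal(empty$pixel_count, 0L)

  # top-view disk of radius 40 px at mm_per_px = 1
  topCfg <- ViewConfig("top", classes = list(), mmPerPx = 1)
  n <- 101
  xy <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  disk <- matrix((xy$x - 50)^2 + (xy$y - 50)^2 <= 40^2, n, n, byrow = TRUE)
  rec <- measurePlant(PlantMask(disk), topCfg)
  expect_equal(rec$x_extent_mm, 81)
  expect_equal(rec$y_extent_mm, 81)
  expect_gte(rec$diameter_mm, 79)
  expect_lte(rec$diameter_mm, 81)
  expect_equal(rec$projected_shoot_area_mm2, pi * 40^2,
               tolerance = 0.01)
})

test_that("measurements are translation invariant", {
  set.seed(44)
  base <- matrix(FALSE, 40, 40)
  base[10:20, 8:18][randomMask(11, 11, 0.5)] <- TRUE
  cfg <- ViewConfig("top", classes = list(), mmPerPx = 0.7)
  ref <- measurePlant(PlantMask(base), cfg)
  for (shift in list(c(5, 3), c(-4, 10), c(12, -2))) {
    shifted <- matrix(FALSE, 40, 40)
    idx <- which(base, arr.ind = TRUE)
    shifted[cbind(idx[, 1] + shift[1], idx[, 2] + shift[2])] <- TRUE
    rec <- measurePlant(PlantMask(shifted), cfg)
    for (f in c("x_extent_mm", "y_extent_mm", "diameter_mm",
                "projected_shoot_area_mm2", "pixel_count"))
      expect_equal(rec[[f]], ref[[f]])
  }
})

test_that("90-degree rotation swaps extents, preserves diameter and area", {
  set.seed(45)
  for (rep in 1:10) {
    m <- randomMask(30, 30, runif(1, 0.05, 0.5))
    rot <- t(m[nrow(m):1, ])  # 90-degree rotation
    e <- maskExtents(PlantMask(m)); er <- maskExtents(PlantMask(rot))
    expect_equal(unname(e), unname(rev(er)))
    expect_equal(maxDiameter(PlantMask(m)), maxDiameter(PlantMask(rot)),
                 tolerance = 1e-9)
    expect_equal(sum(m), sum(rot))
    # diameter dominates the largest extent minus one
    if (any(m))
      expect_gte(maxDiameter(PlantMask(m)) + 1e-9, max(e) - 1)
  }
})

test_that("group summaries give mean and n-1 standard error", {
  recs <- data.frame(plant_id = c("a", "b", "c"), timepoint = "d1",
                     projected_shoot_area_mm2 = c(10, 10, 10))
  grp <- data.frame(plant_id = c("a", "b", "c"), group = "g")
  s <- summarizeGroups(recs, grp)
  expect_equal(s$mean_area_mm2, 10)
  expect_equal(s$se_area_mm2, 0)
  expect_identical(s$n, 3L)

  recs <- data.frame(plant_id = c("a", "b"), timepoint = "d1",
                     projected_shoot_area_mm2 = c(1, 3))
  s <- summarizeGroups(recs, grp[1:2, ])
  expect_equal(s$mean_area_mm2, 2)
  expect_equal(s$se_area_mm2, 1)  # sd = sqrt(2), / sqrt(2)

  # single replicate: SE 0 with a warning
  recs1 <- data.frame(plant_id = "a", timepoint = "d1",
                      projected_shoot_area_mm2 = 5)
  expect_warning(s1 <- summarizeGroups(recs1, grp[1, , drop = FALSE]),
                 "single replicate")
  expect_equal(s1$se_area_mm2, 0)

  # all-NA cell: omitted with a warning
  recsNA <- data.frame(plant_id = c("a", "b"), timepoint = "d1",
                       projected_shoot_area_mm2 = NA_real_)
  expect_warning(s2 <- summarizeGroups(recsNA, grp[1:2, ]), "omitted")
  expect_identical(nrow(s2), 0L)

  # unlabelled plant is an error
  expect_error(summarizeGroups(recs, data.frame(plant_id = "a", group = "g")),
               "no group label")
})

test_that("summaries recover generator means within sampling error", {
  set.seed(46)
  hits <- 0L; cells <- 0L
  for (rep in 1:25) {
    mu <- runif(1, 500, 3000); cv <- 0.2; n <- 10
    sdlog <- sqrt(log(1 + cv^2))
    vals <- rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
    recs <- data.frame(plant_id = sprintf("p%02d", 1:n), timepoint = "d1",
                       projected_shoot_area_mm2 = vals)
    grp <- data.frame(plant_id = recs$plant_id, group = "g")
    s <- summarizeGroups(recs, grp)
    cells <- cells + 1L
    if (abs(s$mean_area_mm2 - mu) <= 3 * s$se_area_mm2) hits <- hits + 1L
  }
  expect_gte(hits / cells, 0.9)
})
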