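test_that("closed intervals contain their endpoints and regions gate classes", {
  prof <- deriveProfile(rbind(c(40, 150, 50), c(80, 200, 90)))
  cfg <- ViewConfig("side",
    classes = list(ObjectClass("carrier", prof, region = "carrier"),
                   ObjectClass("plant", prof)),
    regions = list(Region("carrier", "rectangle", c(0, 0, 4, 4))))
  masks <- regionMasks(cfg, 10, 10)
  # pixel exactly at every lower bound of the profile
  atLo <- c(prof@lo[["R"]], prof@lo[["G"]], prof@lo[["B"]])
  expect_identical(classifyPixel(atLo, c(2, 2), cfg, masks), "carrier")
  # same colour outside the carrier region falls through to "plant"
  expect_identical(classifyPixel(atLo, c(8, 8), cfg, masks), "plant")
  # a colour matching no class is background
  expect_identical(classifyPixel(c(255, 255, 255), c(2, 2), cfg, masks),
                   "background")
})

test_that("region-restricted classes never label pixels outside their region", {
  cfg <- ViewConfig("side",
    classes = list(
      ObjectClass("carrier", deriveProfile(rbind(c(40, 150, 50),
                                                 c(80, 200, 90))),
                  region = "carrier")),
    regions = list(Region("carrier", "rectangle", c(0, 0, 4, 4))))
  # a colour that is itself one of the calibration samples, so it lies in
  # the profile volume on all six channels
  img <- array(0L, dim = c(10, 10, 3))
  img[, , 1] <- 40L; img[, , 2] <- 150L; img[, , 3] <- 50L
  li <- segmentImage(img, cfg)
  lab <- labelMatrix(li)
  inRegion <- rasterize(sceneRegions(cfg)$carrier, 10, 10)
  expect_true(all(lab[!inRegion] == 0L))
  expect_true(all(lab[inRegion] == 1L))
})

test_that("uniform images segment to a single class", {
  cfg <- defaultViewConfig("side")
  pal <- syntheticPalette()
  img <- array(0L, dim = c(20, 20, 3))
  for (k in 1:3) img[, , k] <- pal$plant[k]
  li <- segmentImage(img, cfg)
  expect_true(all(labelMatrix(li) == match("plant", classNames(li))))
  for (k in 1:3) img[, , k] <- 255L
  expect_true(all(labelMatrix(segmentImage(img, cfg)) == 0L))
  expect_error(segmentImage(array(0L, dim = c(5, 5, 2)), cfg), "RGB")
})

test_that("segmentation equals the longhand per-pixel oracle", {
  set.seed(31)
  for (rep in 1:3) {
    cfg <- randomViewConfig(32, 32)
    img <- randomRgbImage(32, 32)
    li <- segmentImage(img, cfg)
    expect_identical(labelMatrix(li), oracleClassify(img, cfg))
  }
  # and under the packaged default configuration
  cfg <- defaultViewConfig("top", width = 32L, height = 32L)
  img <- randomRgbImage(32, 32)
  expect_identical(labelMatrix(segmentImage(img, cfg)),
                   oracleClassify(img, cfg))
})

test_that("permuting classes with disjoint colour volumes keeps labels", {
  cfg <- defaultViewConfig("side")
  sc <- generateScene(sceneSpec("side", noise = 4L, seed = 3L))
  li1 <- segmentImage(sc$image, sc$config)
  perm <- sc$config
  # reverse the region-bound classes, keep plant last
  k <- length(perm@classes)
  perm@classes <- c(rev(perm@classes[-k]), perm@classes[k])
  li2 <- segmentImage(sc$image, perm)
  n1 <- classNames(li1); n2 <- classNames(li2)
  expect_identical(n1[ifelse(labelMatrix(li1) == 0, NA, labelMatrix(li1))],
                   n2[ifelse(labelMatrix(li2) == 0, NA, labelMatrix(li2))])
})

test_that("plant extraction selects exactly the plant label", {
  sc <- generateScene(sceneSpec("side", seed = 4L))
  li <- segmentImage(sc$image, sc$config)
  pm <- extractPlant(li)
  expect_identical(sum(maskMatrix(pm)),
                   sum(labelMatrix(li) == match("plant", classNames(li))))
  allBg <- LabelImage(matrix(0L, 5, 5), classNames(li))
  expect_identical(sum(maskMatrix(extractPlant(allBg))), 0L)
})

test_that("erosion and dilation match the neighbourhood-scan oracle", {
  set.seed(32)
  for (rep in 1:10) {
    m <- randomMask(32, 32, p = runif(1, 0.2, 0.8))
    for (rad in 1:2) {
      expect_identical(maskMatrix(maskErode(PlantMask(m), rad)),
                       scanErode(m, rad))
      expect_identical(maskMatrix(maskDilate(PlantMask(m), rad)),
                       scanDilate(m, rad))
    }
  }
})

test_that("morphology edge cases: radius 0, isolated pixels, borders", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  pm <- PlantMask(m)
  expect_identical(maskMatrix(maskErode(pm, 0)), m)
  expect_identical(maskMatrix(maskDilate(pm, 0)), m)
  expect_identical(sum(maskMatrix(maskErode(pm, 1))), 0L)
  expect_identical(sum(maskMatrix(maskDilate(pm, 1))), 9L)
  # foreground touching the border erodes away (outside counts as false)
  full <- PlantMask(matrix(TRUE, 5, 5))
  expect_identical(sum(maskMatrix(maskErode(full, 1))), 9L)
  expect_error(maskErode(pm, -1), "non-negative")
})

test_that("opening preserves large shapes, removes specks, is idempotent and anti-extensive", {
  block <- matrix(FALSE, 14, 14); block[3:12, 3:12] <- TRUE
  opened <- maskOpening(PlantMask(block), 1)
  expect_identical(maskMatrix(opened), block)
  expect_identical(maskMatrix(opened),
                   scanDilate(scanErode(block, 1), 1))
  set.seed(33)
  specks <- matrix(FALSE, 20, 20)
  specks[cbind(sample(1:20, 8), sample(1:20, 8))] <- TRUE
  # isolated pixels vanish under radius-1 opening
  iso <- maskOpening(PlantMask(specks), 1)
  expect_lte(sum(maskMatrix(iso)), sum(scanDilate(scanErode(specks, 1), 1)))
  for (rep in 1:5) {
    m <- randomMask(24, 24, 0.55)
    for (rad in 1:2) {
      o1 <- maskOpening(PlantMask(m), rad)
      expect_true(all(maskMatrix(o1) <= m))         # anti-extensive
      o2 <- maskOpening(o1, rad)
      expect_identical(maskMatrix(o2), maskMatrix(o1))  # idempotent
    }
  }
})

test_that("colour-coded label images use display colours and yellow background", {
  sc <- generateScene(sceneSpec("side", seed = 5L))
  li <- segmentImage(sc$image, sc$config)
  cimg <- labelColourImage(li, sc$config)
  expect_identical(dim(cimg), c(dim(labelMatrix(li)), 3L))
  bg <- labelMatrix(li) == 0L
  expect_true(all(cimg[, , 1][bg] == 255L & cimg[, , 2][bg] == 255L &
                  cimg[, , 3][bg] == 0L))
  plantIdx <- labelMatrix(li) == match("plant", classNames(li))
  expect_true(all(cimg[, , 2][plantIdx] == 255L))
})
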