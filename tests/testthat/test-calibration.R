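test_that("profiles derived with trim = 0 are per-channel sample extrema", {
  samples <- rbind(c(10, 200, 10), c(20, 220, 30))
  p <- deriveProfile(samples)
  expect_equal(unname(p@lo[c("R", "G", "B")]), c(10, 200, 10))
  expect_equal(unname(p@hi[c("R", "G", "B")]), c(20, 220, 30))
  hsv <- rgbToHsv(samples)
  for (ch in c("S", "V")) {
    expect_equal(p@lo[[ch]], min(hsv[, ch]))
    expect_equal(p@hi[[ch]], max(hsv[, ch]))
  }
  expect_equal(p@lo[["H"]], min(hsv[, "H"]))
  expect_equal(p@hi[["H"]], max(hsv[, "H"]))
})

test_that("a single-sample profile is degenerate and contains its sample", {
  p <- deriveProfile(c(37, 112, 59))
  expect_equal(unname(p@lo), unname(p@hi))
  expect_true(profileContains(p, c(37, 112, 59)))
  expect_error(deriveProfile(matrix(numeric(0), ncol = 3)), "at least one")
})

test_that("hue samples straddling zero yield a wrapping interval covering them", {
  set.seed(11)
  hues <- stats::runif(1000, -10, 10) %% 360  # near 0: 350..360 and 0..10
  rgb <- hsvToRgb(cbind(hues, 0.9, 0.9))
  p <- deriveProfile(rgb)
  expect_true(p@hWraps)
  expect_gt(p@lo[["H"]], p@hi[["H"]])
  h <- rgbToHsv(rgb)[, "H"]
  # brute-force membership of every sample hue in the circular interval
  inside <- h >= p@lo[["H"]] | h <= p@hi[["H"]]
  expect_true(all(inside))
  # and the interval is narrow, not the whole circle
  expect_lt((p@hi[["H"]] - p@lo[["H"]]) %% 360, 30)
})

test_that("every labelled sample satisfies its own trim-0 profile", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    samples <- matrix(sample(0:255, 3 * n, replace = TRUE), ncol = 3)
    p <- deriveProfile(samples)
    expect_true(all(profileContains(p, samples)))
  }
})

test_that("increasing trim never widens any channel interval", {
  set.seed(13)
  samples <- matrix(sample(0:255, 300, replace = TRUE), ncol = 3)
  trims <- c(0, 0.05, 0.1, 0.25, 0.4)
  profs <- lapply(trims, function(tr) deriveProfile(samples, trim = tr))
  width <- function(p, ch) {
    if (ch == "H") (p@hi[["H"]] - p@lo[["H"]]) %% 360
    else p@hi[[ch]] - p@lo[[ch]]
  }
  for (ch in c("R", "G", "B", "H", "S", "V")) {
    ws <- vapply(profs, width, numeric(1), ch = ch)
    expect_true(all(diff(ws) <= 1e-9))
  }
})

test_that("profiles re-derived from pixels inside a volume stay inside it", {
  set.seed(14)
  p0 <- deriveProfile(matrix(sample(40:200, 60, replace = TRUE), ncol = 3))
  # uniform RGB samples inside the original RGB box
  inner <- cbind(sample(p0@lo[["R"]]:p0@hi[["R"]], 200, TRUE),
                 sample(p0@lo[["G"]]:p0@hi[["G"]], 200, TRUE),
                 sample(p0@lo[["B"]]:p0@hi[["B"]], 200, TRUE))
  p1 <- deriveProfile(inner)
  for (ch in c("R", "G", "B")) {
    expect_gte(p1@lo[[ch]], p0@lo[[ch]])
    expect_lte(p1@hi[[ch]], p0@hi[[ch]])
  }
})

test_that("the packaged default configurations are sound", {
  for (v in c("top", "side")) {
    path <- system.file("extdata", sprintf("config_%s.yaml", v),
                        package = "phenopipe")
    cfg <- readViewConfig(path)
    expect_length(validateConfig(cfg), 0)
    expect_identical(configView(cfg), v)
  }
  # default region sets: five regions in top view, three in side view
  expect_length(sceneRegions(defaultViewConfig("top")), 5)
  expect_length(sceneRegions(defaultViewConfig("side")), 3)
})

test_that("validateConfig reports missing regions and volume overlaps", {
  prof <- deriveProfile(rbind(c(10, 10, 10), c(40, 40, 40)))
  bad <- ViewConfig("side",
    classes = list(ObjectClass("carrier", prof, region = "karrier"),
                   ObjectClass("plant", prof)),
    regions = list(Region("carrier", "rectangle", c(0, 0, 10, 10))))
  diag <- validateConfig(bad)
  expect_length(diag, 1)
  expect_match(diag, "missing region \"karrier\"")

  twin <- ViewConfig("side",
    classes = list(ObjectClass("a", prof, region = "shared"),
                   ObjectClass("b", prof, region = "shared"),
                   ObjectClass("plant", prof)),
    regions = list(Region("shared", "rectangle", c(0, 0, 10, 10))))
  diag <- validateConfig(twin)
  expect_length(diag, 1)
  expect_match(diag, "overlapping colour volumes")

  zero <- ViewConfig("top",
    classes = list(ObjectClass("plant", prof)),
    regions = list(Region("line", "rectangle", c(5, 0, 5, 10))),
    mmPerPx = -1)
  diag <- validateConfig(zero)
  expect_length(diag, 2)
  expect_match(diag, "zero area", all = FALSE)
  expect_match(diag, "mm_per_px", all = FALSE)
})

test_that("configuration files round-trip through YAML", {
  cfg <- defaultViewConfig("top", mmPerPx = 0.37, regionScale = 1.2,
                           openingRadius = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeViewConfig(cfg, path)
  back <- readViewConfig(path)
  expect_identical(configView(back), "top")
  expect_equal(mmPerPx(back), 0.37)
  expect_equal(regionScale(back), 1.2)
  expect_identical(openingRadius(back), 2L)
  set.seed(15)
  rgb <- matrix(sample(0:255, 3000, replace = TRUE), ncol = 3)
  ch <- pixelChannels(rgb)
  for (i in seq_along(objectClasses(cfg))) {
    expect_identical(
      profileContains(objectClasses(back)[[i]]@profiles[[1]], ch),
      profileContains(objectClasses(cfg)[[i]]@profiles[[1]], ch))
  }
})

test_that("byte-unit hue thresholds are rescaled on input", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "schema: 1", "view: side", "mm_per_px: 1.0", "region_scale: 1.0",
    "opening_radius: 0", "regions: []", "classes:",
    "- name: plant", "  display_colour: [0, 255, 0]", "  profiles:",
    "  - h_unit: byte",
    "    R: [0, 255]", "    G: [0, 255]", "    B: [0, 255]",
    "    H: [64, 128]", "    S: [0, 1]", "    V: [0, 1]"), path)
  cfg <- readViewConfig(path)
  p <- objectClasses(cfg)[[1]]@profiles[[1]]
  expect_equal(p@lo[["H"]], 64 * 360 / 256)
  expect_equal(p@hi[["H"]], 128 * 360 / 256)
})

test_that("labelled pixel samples load from the r,g,b,label format", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("10,200,10,plant", "20,220,30,plant", "120,85,40,soil"), path)
  px <- readPixelSamples(path)
  expect_identical(nrow(px), 3L)
  expect_identical(px$label, c("plant", "plant", "soil"))
  p <- deriveProfile(as.matrix(px[px$label == "plant", c("r", "g", "b")]))
  expect_equal(unname(p@lo[c("R", "G", "B")]), c(10, 200, 10))
})
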