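## Synthetic greenhouse scenes with exact ground truth.
##
## The generator emulates the automated-greenhouse image layout: a plant of
## known geometry over a structured scene of coloured non-plant objects
## (soil, carrier, cages, sticks, conveyor belt) confined to known regions,
## against a uniform backdrop, with optional uniform illumination noise and
## optional plant-coloured distractor blobs inside non-plant regions.
## Ground-truth measurements are computed by independent brute-force scans
## (never by the measurement module under test), so every pipeline stage can
## be validated without any real imagery.

#' Reference scene palette
#'
#' Interior colours used by the synthetic scene generator, one per object
#' class plus the backdrop.  The colours follow the conventional scene:
#' brown soil, blue carrier and sticks, magenta cages, near-black conveyor
#' belt, green plant, light neutral backdrop.  They are separated by at
#' least 40 intensity units in some RGB channel, so class colour volumes
#' derived with moderate margins stay disjoint.
#'
#' @return Named list of RGB triples.
#' @seealso [paletteConfig()], [sceneSpec()]
#' @export
syntheticPalette <- function() {
  list(backdrop      = c(205, 205, 215),
       soil          = c(120,  85,  40),
       carrier       = c( 70,  95, 165),
       cages         = c(190,  60, 175),
       sticks        = c( 40,  60, 120),
       conveyor_belt = c( 35,  35,  35),
       plant         = c( 55, 165,  60))
}

.displayColours <- function() {
  list(soil          = c(139,  90,  43),
       carrier       = c(  0,   0, 255),
       cages         = c(255,   0, 255),
       sticks        = c( 70,  70, 255),
       conveyor_belt = c(  0,   0,   0),
       plant         = c(  0, 255,   0))
}

## Exact box profile: enumerate every RGB value within `halfWidth` of the
## colour (clipped to [0, 255]) and take per-channel extrema.  Any pixel
## whose RGB lies in the box is then inside the derived volume by
## construction, on all six channels.
.boxProfile <- function(colour, halfWidth) {
  rng <- lapply(colour, function(c0)
    max(0, c0 - halfWidth):min(255, c0 + halfWidth))
  grid <- as.matrix(expand.grid(rng[[1L]], rng[[2L]], rng[[3L]]))
  deriveProfile(grid, trim = 0)
}

.regionClassNames <- function(view) {
  if (view == "top") c("soil", "carrier", "cages", "sticks", "conveyor_belt")
  else c("carrier", "cages", "sticks")
}

.defaultRegions <- function(view, w, h) {
  r <- function(name, x0, y0, x1, y1)
    Region(name, "rectangle", round(c(x0, y0, x1, y1)))
  if (view == "top") {
    list(
      Region("soil", "circle",
             c((w - 1) / 2, (h - 1) / 2, round(0.30 * min(w, h)))),
      r("carrier", 0.06 * w, 0.06 * h, 0.94 * w - 1, 0.94 * h - 1),
      r("cages", 0, 0.35 * h, 0.05 * w, 0.65 * h),
      r("sticks", 0.95 * w, 0.35 * h, w - 1, 0.65 * h),
      r("conveyor_belt", 0, 0.93 * h, w - 1, h - 1)
    )
  } else {
    list(
      r("carrier", 0.15 * w, 0.82 * h, 0.85 * w, h - 1),
      r("cages", 0, 0.08 * h, 0.10 * w, 0.80 * h),
      r("sticks", 0.90 * w, 0.08 * h, w - 1, 0.80 * h)
    )
  }
}

#' Build a view configuration matched to a scene palette
#'
#' Derives one threshold profile per object class by exhaustively
#' enumerating the RGB cube of half-width `noise + 2` around the class's
#' palette colour and taking exact per-channel extrema (circular for hue).
#' Every colour within `noise` of the palette colour is a member of that
#' enumeration, so the derived volume contains all "safe" perturbations by
#' construction.  Optionally widens one region-bound class with a second
#' profile around a distractor colour, so that plant-coloured distractors
#' inside that class's region are claimed by the region-bound class rather
#' than by the unrestricted `"plant"` class declared after it.
#'
#' @param view `"top"` or `"side"`.
#' @param width,height reference image size for the region layout.
#' @param palette scene palette from [syntheticPalette()].
#' @param noise maximum per-channel perturbation the profiles must absorb.
#' @param mmPerPx,regionScale,openingRadius calibration scalars.
#' @param configId identifier stored in the configuration.
#' @param widenClass optional name of a region-bound class to widen.
#' @param widenColour RGB triple the widened class must additionally cover.
#' @return A [ViewConfig].
#' @seealso [defaultViewConfig()], [generateScene()]
#' @export
paletteConfig <- function(view = c("top", "side"), width = 200L,
                          height = if (match.arg(view) == "top") 200L else 240L,
                          palette = syntheticPalette(), noise = 8L,
                          mmPerPx = 1, regionScale = 1, openingRadius = 1L,
                          configId = paste0("palette-", match.arg(view)),
                          widenClass = NULL, widenColour = NULL) {
  view <- match.arg(view)
  disp <- .displayColours()
  halfWidth <- noise + 2L
  classes <- lapply(.regionClassNames(view), function(nm) {
    profiles <- list(.boxProfile(palette[[nm]], halfWidth))
    if (!is.null(widenClass) && identical(nm, widenClass)) {
      if (is.null(widenColour)) stop("'widenColour' required with 'widenClass'")
      profiles <- c(profiles, list(.boxProfile(widenColour, halfWidth)))
    }
    ObjectClass(nm, profiles, region = nm, displayColour = disp[[nm]])
  })
  classes <- c(classes, list(
    ObjectClass("plant", list(.boxProfile(palette$plant, halfWidth)),
                displayColour = disp$plant)))
  ViewConfig(view = view, classes = classes,
             regions = .defaultRegions(view, width, height),
             regionScale = regionScale, mmPerPx = mmPerPx,
             openingRadius = openingRadius, configId = configId)
}

#' Specify a synthetic scene
#'
#' @param view `"top"` or `"side"`.
#' @param width,height image size in pixels.
#' @param plant plant model: for side view
#'   `list(type = "rect", w =, h =)` (solid canopy rectangle) or
#'   `list(type = "stem", height =, leaves =, leafLen =)` (stylized stem
#'   with leaves); for top view `list(type = "disk", r =)` or
#'   `list(type = "ellipse", rx =, ry =)`.
#' @param noise maximum per-channel uniform perturbation (integer `>= 0`).
#'   Scenes whose noise the companion configuration absorbs exactly are
#'   "safe"; see [paletteConfig()].
#' @param clutter optional distractor specification
#'   `list(region =, n =, radius =)`: `n` blobs of plant-like colour placed
#'   inside the named non-plant region.  Clutter makes the scene
#'   adversarial; the companion configuration widens the owning class so
#'   the region restriction (not colour alone) decides those pixels.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @param palette scene palette.
#' @param mmPerPx,openingRadius calibration scalars for the companion
#'   configuration.
#' @return A list of class `"SceneSpec"`.
#' @seealso [generateScene()]
#' @export
sceneSpec <- function(view = c("side", "top"), width = 200L,
                      height = if (match.arg(view) == "top") 200L else 240L,
                      plant = list(type = "rect", w = 40L, h = 80L),
                      noise = 0L, clutter = NULL, seed = 1L,
                      palette = syntheticPalette(), mmPerPx = 1,
                      openingRadius = 1L) {
  view <- match.arg(view)
  if (!is.numeric(noise) || noise < 0 || noise != round(noise))
    stop("'noise' must be a non-negative integer")
  if (!is.null(clutter) &&
      !all(c("region", "n", "radius") %in% names(clutter)))
    stop("'clutter' must be list(region =, n =, radius =)")
  structure(list(view = view, width = as.integer(width),
                 height = as.integer(height), plant = plant,
                 noise = as.integer(noise), clutter = clutter,
                 seed = as.integer(seed), palette = palette,
                 mmPerPx = mmPerPx, openingRadius = openingRadius,
                 adversarial = !is.null(clutter)),
            class = "SceneSpec")
}

## ---- independent brute-force ground-truth measurements ----
## Deliberately written as explicit scans so they share no code with the
## measurement module they are used to check.

.bfBoundingBox <- function(mask) {
  xmin <- Inf; xmax <- -Inf; ymin <- Inf; ymax <- -Inf; count <- 0L
  for (row in seq_len(nrow(mask))) for (col in seq_len(ncol(mask))) {
    if (!mask[row, col]) next
    count <- count + 1L
    x <- col - 1L; y <- row - 1L
    if (x < xmin) xmin <- x
    if (x > xmax) xmax <- x
    if (y < ymin) ymin <- y
    if (y > ymax) ymax <- y
  }
  if (count == 0L)
    return(list(width = 0L, height = 0L, count = 0L))
  list(width = xmax - xmin + 1L, height = ymax - ymin + 1L, count = count,
       xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
}

.bfBoundaryPixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- NULL
  for (row in seq_len(h)) for (col in seq_len(w)) {
    if (!mask[row, col]) next
    edge <- row == 1L || row == h || col == 1L || col == w ||
      !mask[row - 1L, col] || !mask[row + 1L, col] ||
      !mask[row, col - 1L] || !mask[row, col + 1L]
    if (edge) out <- rbind(out, c(col - 1L, row - 1L))
  }
  out
}

## The maximising pixel pair always has both ends on the mask boundary, so a
## pairwise scan over boundary pixels equals the full O(n^2) scan.
.bfDiameter <- function(mask) {
  b <- .bfBoundaryPixels(mask)
  if (is.null(b) || nrow(b) < 2L) return(0)
  best <- 0
  for (i in seq_len(nrow(b) - 1L)) for (j in (i + 1L):nrow(b)) {
    d <- sqrt((b[i, 1L] - b[j, 1L])^2 + (b[i, 2L] - b[j, 2L])^2)
    if (d > best) best <- d
  }
  best
}

## ---- scene rendering ----

.fillColour <- function(img, sel, colour) {
  for (k in 1:3) {
    plane <- img[, , k]
    plane[sel] <- colour[k]
    img[, , k] <- plane
  }
  img
}

.plantPixelMask <- function(spec) {
  w <- spec$width; h <- spec$height
  m <- matrix(FALSE, h, w)
  p <- spec$plant
  if (spec$view == "side") {
    if (identical(p$type, "rect")) {
      pw <- as.integer(p$w); ph <- as.integer(p$h)
      y1 <- round(0.80 * h); y0 <- y1 - ph + 1L
      x0 <- round((w - pw) / 2); x1 <- x0 + pw - 1L
      if (y0 < 0L || x0 < 0L || x1 > w - 1L)
        stop("plant larger than the image")
      m[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)] <- TRUE
    } else if (identical(p$type, "stem")) {
      sh <- as.integer(p$height)
      y1 <- round(0.80 * h); y0 <- y1 - sh + 1L
      xc <- round(w / 2)
      if (y0 < 0L) stop("plant larger than the image")
      m[(y0 + 1L):(y1 + 1L), (xc:(xc + 1L)) + 1L] <- TRUE
      nl <- if (is.null(p$leaves)) 4L else as.integer(p$leaves)
      ll <- if (is.null(p$leafLen)) round(0.15 * w) else as.integer(p$leafLen)
      for (i in seq_len(nl)) {
        ya <- y0 + round(i * sh / (nl + 1))
        dir <- if (i %% 2L == 0L) 1L else -1L
        for (t in 0:ll) {
          xx <- xc + dir * t; yy <- ya - round(t / 2)
          if (xx >= 0L && xx <= w - 1L && yy >= 0L && yy <= h - 1L)
            m[yy + 1L, xx + 1L] <- TRUE
        }
      }
    } else stop("unknown side-view plant model: ", p$type)
  } else {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    if (identical(p$type, "disk")) {
      dx2 <- (seq_len(w) - 1 - cx)^2
      dy2 <- (seq_len(h) - 1 - cy)^2
      m <- outer(dy2, dx2, "+") <= p$r^2
    } else if (identical(p$type, "ellipse")) {
      dx2 <- ((seq_len(w) - 1 - cx) / p$rx)^2
      dy2 <- ((seq_len(h) - 1 - cy) / p$ry)^2
      m <- outer(dy2, dx2, "+") <= 1
    } else stop("unknown top-view plant model: ", p$type)
  }
  m
}

#' Generate a synthetic scene with ground truth
#'
#' Renders, deterministically for a given seed, a greenhouse-style scene:
#' backdrop, region-bound objects painted into their regions, optional
#' distractor blobs, and finally the plant.  Emits the exact per-pixel label
#' map and brute-force plant measurements (bounding box, pixel count,
#' maximum pairwise diameter) computed by code independent of the
#' measurement module, plus a companion [ViewConfig] whose colour volumes
#' absorb perturbations up to the declared noise amplitude exactly.
#'
#' @param spec a [sceneSpec()].
#' @param config optional precomputed companion [ViewConfig] for the same
#'   view, palette and noise amplitude (as produced by [paletteConfig()]);
#'   skips the per-scene profile derivation when many scenes share one
#'   calibration.  Ignored for adversarial specs, whose configuration
#'   depends on the clutter colour.
#' @return A list with elements `image` (`height x width x 3` integer
#'   array), `truth` (list: `labels` [LabelImage], `bbox` = `c(width,
#'   height)` px, `pixelCount`, `diameter` px, `clutterMask`), `config`
#'   (companion [ViewConfig]) and `spec`.
#' @examples
#' sc <- generateScene(sceneSpec("side", plant = list(type = "rect",
#'                                                    w = 30, h = 60)))
#' sc$truth$bbox  # 30 60
#' @export
generateScene <- function(spec, config = NULL) {
  stopifnot(inherits(spec, "SceneSpec"))
  set.seed(spec$seed)
  w <- spec$width; h <- spec$height
  pal <- spec$palette
  clutterColour <- {
    o <- min(spec$noise + 2L, 6L)
    pmin(pmax(pal$plant + c(o, o, -o), 0L), 255L)
  }
  cfg <- if (!is.null(config) && !spec$adversarial) config else
    paletteConfig(spec$view, width = w, height = h, palette = pal,
                  noise = spec$noise, mmPerPx = spec$mmPerPx,
                  openingRadius = spec$openingRadius,
                  configId = paste0("synthetic-", spec$view),
                  widenClass = if (spec$adversarial) spec$clutter$region,
                  widenColour = if (spec$adversarial) clutterColour)
  classNames <- vapply(cfg@classes, function(x) x@name, character(1))
  img <- array(0L, dim = c(h, w, 3L))
  img <- .fillColour(img, matrix(TRUE, h, w), pal$backdrop)
  labels <- matrix(0L, h, w)
  masks <- regionMasks(cfg, w, h)
  ## paint region-bound objects; in top view the soil disc sits on top of
  ## the carrier rectangle, so paint the carrier first
  paintOrder <- intersect(c("carrier", "conveyor_belt", "cages", "sticks",
                            "soil"), .regionClassNames(spec$view))
  for (nm in paintOrder) {
    sel <- masks[[nm]]
    img <- .fillColour(img, sel, pal[[nm]])
    labels[sel] <- match(nm, classNames)
  }
  ## distractor blobs: plant-like colour confined to a non-plant region
  clutterMask <- matrix(FALSE, h, w)
  if (spec$adversarial) {
    own <- spec$clutter$region
    rm <- masks[[own]]
    if (is.null(rm) || !any(rm)) stop("clutter region is empty: ", own)
    cand <- which(rm, arr.ind = TRUE)
    picks <- cand[sample.int(nrow(cand), spec$clutter$n, replace = TRUE), ,
                  drop = FALSE]
    rad <- spec$clutter$radius
    for (i in seq_len(nrow(picks))) {
      dx2 <- (seq_len(w) - picks[i, 2L])^2
      dy2 <- (seq_len(h) - picks[i, 1L])^2
      blob <- (outer(dy2, dx2, "+") <= rad^2) & rm
      clutterMask <- clutterMask | blob
    }
    img <- .fillColour(img, clutterMask, clutterColour)
    labels[clutterMask] <- match(own, classNames)
  }
  ## the plant, painted last: plant parts may appear anywhere
  plantMask <- .plantPixelMask(spec)
  img <- .fillColour(img, plantMask, pal$plant)
  labels[plantMask] <- match("plant", classNames)
  ## uniform illumination noise, clipped to the 8-bit range
  if (spec$noise > 0L) {
    pert <- array(sample(seq(-spec$noise, spec$noise), h * w * 3L,
                         replace = TRUE), dim = dim(img))
    img <- pmin(pmax(img + pert, 0L), 255L)
  }
  storage.mode(img) <- "integer"
  bb <- .bfBoundingBox(plantMask)
  list(image = img,
       truth = list(labels = LabelImage(labels, classNames),
                    bbox = c(width = bb$width, height = bb$height),
                    pixelCount = bb$count,
                    diameter = .bfDiameter(plantMask),
                    plantMask = plantMask,
                    clutterMask = clutterMask),
       config = cfg, spec = spec)
}

#' Generate a synthetic growth time series
#'
#' Emulates the structure of a cultivar-by-treatment screening: for each
#' group (e.g. cultivar x watering condition), each plant and each day, one
#' scene per requested view is generated with the plant's true projected
#' area drawn from a log-normal distribution with the group/day mean and a
#' common coefficient of variation.  The manifest records every drawn target
#' and the exact rendered ground truth, so group summaries computed from
#' pipeline output can be checked against the generating distribution.
#'
#' @param meanArea numeric matrix of expected projected areas in px^2, rows
#'   = groups (rownames required), columns = days (colnames used as
#'   timepoint labels, e.g. `"28"`).
#' @param nPlants plants per group.
#' @param cv between-plant coefficient of variation of the true area.
#' @param views character subset of `c("side", "top")`.
#' @param width,height scene size in pixels.
#' @param noise per-channel noise amplitude passed to each scene.
#' @param seed integer seed for the whole series.
#' @param dir optional output directory; when given, scenes are written as
#'   `<plant>_<view>_d<day>.png` together with `manifest.csv`,
#'   `config_side.yaml`/`config_top.yaml`, and images are dropped from the
#'   return value.
#' @return A list with `manifest` (data.frame: `file`, `plant_id`, `group`,
#'   `view`, `timepoint`, `target_area_px`, `true_area_px`,
#'   `true_width_px`, `true_height_px`), `configs` (named list of
#'   [ViewConfig]), and `scenes` (named list of images unless `dir` was
#'   given).
#' @seealso [runBatch()], [summarizeGroups()]
#' @export
generateTimeseries <- function(meanArea, nPlants = 8L, cv = 0.15,
                               views = "side", width = 160L, height = 200L,
                               noise = 0L, seed = 1L, dir = NULL) {
  stopifnot(is.matrix(meanArea), !is.null(rownames(meanArea)),
            nPlants >= 1L, ncol(meanArea) >= 1L, cv >= 0)
  days <- colnames(meanArea)
  if (is.null(days)) days <- as.character(seq_len(ncol(meanArea)))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  configs <- list()
  for (v in views)
    configs[[v]] <- paletteConfig(v, width = width, height = height,
                                  noise = noise,
                                  configId = paste0("synthetic-", v))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (v in views)
      writeViewConfig(configs[[v]], file.path(dir, sprintf("config_%s.yaml", v)))
  }
  rows <- list(); scenes <- list()
  for (g in rownames(meanArea)) for (i in seq_len(nPlants)) {
    pid <- paste0(gsub("[^A-Za-z0-9]", "", g), sprintf("%02d", i))
    for (d in seq_along(days)) {
      mu <- meanArea[g, d]
      target <- if (cv > 0)
        stats::rlnorm(1L, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      else mu
      for (v in views) {
        plant <- if (v == "side") {
          ph <- max(3L, round(sqrt(2 * target)))
          pw <- max(3L, round(target / ph))
          list(type = "rect", w = pw, h = ph)
        } else list(type = "disk", r = sqrt(target / pi))
        sc <- generateScene(sceneSpec(
          v, width = width, height = height, plant = plant, noise = noise,
          seed = sample.int(.Machine$integer.max, 1L)), config = configs[[v]])
        fname <- sprintf("%s_%s_d%s.png", pid, v, days[d])
        if (!is.null(dir)) writePlantImage(sc$image, file.path(dir, fname))
        else scenes[[fname]] <- sc$image
        rows[[length(rows) + 1L]] <- data.frame(
          file = fname, plant_id = pid, group = g, view = v,
          timepoint = days[d], target_area_px = target,
          true_area_px = sc$truth$pixelCount,
          true_width_px = sc$truth$bbox[["width"]],
          true_height_px = sc$truth$bbox[["height"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(manifest = manifest, configs = configs,
       scenes = if (is.null(dir)) scenes else NULL, dir = dir)
}
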