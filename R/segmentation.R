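## Multidimensional histogram thresholding (MHT): purely per-pixel
## classification by closed min/max intervals on all six RGB+HSV channels,
## restricted to calibrated scene regions for non-plant classes.  No
## neighbourhood context enters the classifier; cleanup is left to the
## morphological opening applied to the extracted plant mask.

#' Rasterized region masks for a configuration
#'
#' Rasterizes every region of a [ViewConfig] once, after applying the
#' configuration's automatic region scaling, so that per-pixel classification
#' can test region membership by lookup.
#'
#' @param cfg a [ViewConfig].
#' @param width,height image dimensions in pixels.
#' @return Named list of `height x width` logical matrices, one per region.
#' @seealso [classifyPixel()], [segmentImage()]
#' @export
regionMasks <- function(cfg, width, height) {
  masks <- lapply(cfg@regions, function(r)
    rasterize(scaleRegion(r, cfg@regionScale), width, height))
  names(masks) <- vapply(cfg@regions, function(r) r@name, character(1))
  masks
}

## Vectorized classifier core: channel matrix (n x 6) + per-pixel region
## membership.  Returns integer labels, 0 = background.
.classifyCore <- function(channels, inRegion, cfg) {
  n <- nrow(channels)
  labels <- integer(n)
  unassigned <- rep(TRUE, n)
  for (ci in seq_along(cfg@classes)) {
    cl <- cfg@classes[[ci]]
    hit <- rep(FALSE, n)
    for (p in cl@profiles) hit <- hit | profileContains(p, channels)
    if (!is.na(cl@region)) {
      rm <- inRegion[[cl@region]]
      if (is.null(rm)) stop("class \"", cl@name,
                            "\" references missing region \"", cl@region, "\"")
      hit <- hit & rm
    }
    sel <- hit & unassigned
    labels[sel] <- ci
    unassigned <- unassigned & !sel
    if (!any(unassigned)) break
  }
  labels
}

#' Classify a single pixel
#'
#' Returns the name of the first class in the configuration's declaration
#' order whose region (if any) contains the pixel position and whose colour
#' volume (any one of its profiles, all six channels conjunctively, hue
#' circularly when the interval wraps) contains the pixel colour;
#' `"background"` when no class matches.  Declaration order is the only
#' conflict-resolution rule, which is why the unrestricted `"plant"` class is
#' conventionally declared last.
#'
#' @param p RGB pixel (length-3 integer vector in `[0, 255]`).
#' @param position 0-based pixel coordinate `c(x, y)` (x = column, y = row).
#' @param cfg a [ViewConfig].
#' @param masks precomputed [regionMasks()] for the image size.
#' @return A single class name.
#' @examples
#' cfg <- defaultViewConfig("side")
#' masks <- regionMasks(cfg, 200, 240)
#' classifyPixel(c(55, 165, 60), c(100, 100), cfg, masks)  # "plant"
#' @export
classifyPixel <- function(p, position, cfg, masks) {
  row <- position[2L] + 1L; col <- position[1L] + 1L
  inRegion <- lapply(masks, function(m) {
    if (row < 1L || col < 1L || row > nrow(m) || col > ncol(m))
      stop("'position' lies outside the image")
    m[row, col]
  })
  lab <- .classifyCore(pixelChannels(p), inRegion, cfg)
  if (lab == 0L) "background" else cfg@classes[[lab]]@name
}

#' Segment an image into object classes
#'
#' Applies the per-pixel MHT classifier to every pixel of an 8-bit RGB
#' image, with region masks rasterized once from the configuration's scaled
#' regions.
#'
#' @param img an RGB image: `height x width x 3` array of integer
#'   intensities in `[0, 255]` (see [readPlantImage()]).
#' @param cfg a [ViewConfig].
#' @return A [LabelImage] of the same dimensions.
#' @seealso [extractPlant()], [labelColourImage()]
#' @export
segmentImage <- function(img, cfg) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("'img' must be a height x width x 3 RGB array")
  if (anyNA(img) || any(img < 0 | img > 255))
    stop("'img' must contain 8-bit intensities in [0, 255]")
  h <- dim(img)[1L]; w <- dim(img)[2L]
  rgb <- cbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
               as.vector(img[, , 3L]))
  channels <- pixelChannels(rgb)
  masks <- regionMasks(cfg, w, h)
  inRegion <- lapply(masks, as.vector)
  labels <- matrix(.classifyCore(channels, inRegion, cfg), nrow = h, ncol = w)
  LabelImage(labels, vapply(cfg@classes, function(x) x@name, character(1)))
}

#' Extract the plant mask from a label image
#'
#' The plant is the object of interest and carries no region restriction;
#' extraction simply selects the pixels labelled `"plant"`.
#'
#' @param li a [LabelImage].
#' @return A [PlantMask]; all-`FALSE` when the configuration has no
#'   `"plant"` class or no pixel matched it.
#' @export
extractPlant <- function(li) {
  idx <- match("plant", li@classNames)
  if (is.na(idx)) return(PlantMask(matrix(FALSE, nrow(li@labels),
                                          ncol(li@labels))))
  PlantMask(li@labels == idx)
}

## shift a logical matrix by (dy, dx), padding with `fill`
.shiftLogical <- function(m, dy, dx, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  if (abs(dy) >= h || abs(dx) >= w) return(out)
  rs <- max(1L, 1L + dy):min(h, h + dy)
  cs <- max(1L, 1L + dx):min(w, w + dx)
  out[rs, cs] <- m[rs - dy, cs - dx, drop = FALSE]
  out
}

.checkRadius <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
      radius < 0 || radius != round(radius))
    stop("'radius' must be a non-negative integer")
  as.integer(radius)
}

#' Binary erosion with a square structuring element
#'
#' A pixel survives erosion iff every pixel of the
#' `(2 * radius + 1)` square structuring element centred on it is foreground;
#' pixels outside the image count as background, so foreground touching the
#' border is eroded away.
#'
#' @param m a [PlantMask].
#' @param radius structuring-element half-width (integer `>= 0`;
#'   `0` = identity).
#' @return A [PlantMask].
#' @seealso [maskDilate()], [maskOpening()]
#' @export
maskErode <- function(m, radius) {
  radius <- .checkRadius(radius)
  out <- m@mask
  if (radius == 0L || !any(out)) return(PlantMask(out))
  src <- m@mask
  for (dy in -radius:radius) for (dx in -radius:radius) {
    if (dy == 0L && dx == 0L) next
    out <- out & .shiftLogical(src, dy, dx, fill = FALSE)
  }
  PlantMask(out)
}

#' Binary dilation with a square structuring element
#'
#' A pixel is foreground after dilation iff any pixel of the square
#' structuring element centred on it is foreground in the input.
#'
#' @inheritParams maskErode
#' @return A [PlantMask].
#' @export
maskDilate <- function(m, radius) {
  radius <- .checkRadius(radius)
  out <- m@mask
  if (radius == 0L || !any(m@mask)) return(PlantMask(out))
  src <- m@mask
  for (dy in -radius:radius) for (dx in -radius:radius) {
    if (dy == 0L && dx == 0L) next
    out <- out | .shiftLogical(src, dy, dx, fill = FALSE)
  }
  PlantMask(out)
}

#' Morphological opening of the plant mask
#'
#' Erosion followed by dilation with the same square structuring element.
#' Opening removes foreground features smaller than the element — isolated
#' misclassified pixels and thin colour-similarity artefacts — while shapes
#' larger than the element survive unchanged; it never adds pixels
#' (anti-extensive) and applying it twice changes nothing (idempotent).
#'
#' @inheritParams maskErode
#' @return A [PlantMask].
#' @export
maskOpening <- function(m, radius) {
  maskDilate(maskErode(m, radius), radius)
}

#' Colour-coded label image
#'
#' Renders a [LabelImage] using each class's display colour and yellow for
#' the reserved background label, the conventional colour coding of the
#' segmentation stage.
#'
#' @param li a [LabelImage].
#' @param cfg the [ViewConfig] the labels came from.
#' @param backgroundColour RGB triple for unmatched pixels.
#' @return A `height x width x 3` integer array.
#' @seealso [buildStack()], [writePlantImage()]
#' @export
labelColourImage <- function(li, cfg, backgroundColour = c(255, 255, 0)) {
  pal <- rbind(backgroundColour,
               t(vapply(cfg@classes, function(x) x@displayColour,
                        numeric(3))))
  idx <- li@labels + 1L
  out <- array(0L, dim = c(nrow(li@labels), ncol(li@labels), 3L))
  for (k in 1:3) out[, , k] <- matrix(pal[idx, k], nrow(li@labels))
  storage.mode(out) <- "integer"
  out
}
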