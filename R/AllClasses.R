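#' @import methods
NULL

CHANNELS <- c("R", "G", "B", "H", "S", "V")

.channelRange <- function(channel) {
  switch(channel,
    R = , G = , B = c(0, 255),
    H = c(0, 360),
    S = , V = c(0, 1)
  )
}

#' Scene region
#'
#' A named geometric region of the image plane that restricts where a
#' non-plant object class may be segmented.  Coordinates are 0-based pixel
#' coordinates with x running along columns and y along rows, origin at the
#' top-left corner.  Rectangles are stored as `(x0, y0, x1, y1)` with closed
#' bounds; circles as `(cx, cy, radius)`.
#'
#' @slot name single string identifying the region within a [ViewConfig].
#' @slot shape `"rectangle"` or `"circle"`.
#' @slot geometry numeric vector: length 4 for rectangles, 3 for circles.
#'
#' @seealso [Region()], [scaleRegion()], [rasterize()]
#' @export
setClass("Region",
  representation(name = "character", shape = "character", geometry = "numeric")
)

setValidity("Region", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a single non-empty string")
  if (length(object@shape) != 1L || !object@shape %in% c("rectangle", "circle"))
    msgs <- c(msgs, "'shape' must be \"rectangle\" or \"circle\"")
  g <- object@geometry
  if (identical(object@shape, "rectangle")) {
    if (length(g) != 4L || anyNA(g))
      msgs <- c(msgs, "rectangle geometry must be (x0, y0, x1, y1)")
    else if (g[1] > g[3] || g[2] > g[4])
      msgs <- c(msgs, "rectangle requires x0 <= x1 and y0 <= y1")
  } else if (identical(object@shape, "circle")) {
    if (length(g) != 3L || anyNA(g))
      msgs <- c(msgs, "circle geometry must be (cx, cy, radius)")
    else if (g[3] <= 0)
      msgs <- c(msgs, "circle radius must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname Region-class
#' @param name region identifier.
#' @param shape `"rectangle"` or `"circle"`.
#' @param geometry numeric geometry vector (see the class description).
#' @return A `Region` object.
#' @examples
#' Region("soil", "circle", c(100, 100, 60))
#' @export
Region <- function(name, shape = c("rectangle", "circle"), geometry) {
  shape <- match.arg(shape)
  new("Region", name = as.character(name), shape = shape,
      geometry = as.numeric(geometry))
}

setMethod("show", "Region", function(object) {
  cat(sprintf("Region \"%s\" (%s): %s\n", object@name, object@shape,
              paste(signif(object@geometry, 6), collapse = ", ")))
})

#' Colour threshold profile
#'
#' Closed `[lo, hi]` intervals on all six channels of the combined RGB+HSV
#' colour space.  A pixel satisfies the profile when every channel value lies
#' inside its interval (conjunction over channels).  The hue interval may wrap
#' around 0/360 degrees: with `hWraps = TRUE` and `lo > hi` the interval
#' denotes `[lo, 360) U [0, hi]`.
#'
#' @slot lo,hi named numeric vectors over channels `R, G, B, H, S, V`.
#'   R/G/B are 8-bit intensities in `[0, 255]`, H is in degrees `[0, 360)`,
#'   S and V are in `[0, 1]`.
#' @slot hWraps logical flag; wrap-around is only meaningful for hue.
#'
#' @seealso [ThresholdProfile()], [deriveProfile()], [profileContains()]
#' @export
setClass("ThresholdProfile",
  representation(lo = "numeric", hi = "numeric", hWraps = "logical")
)

setValidity("ThresholdProfile", function(object) {
  msgs <- character()
  if (!identical(names(object@lo), CHANNELS) ||
      !identical(names(object@hi), CHANNELS))
    return("'lo' and 'hi' must each name all six channels R, G, B, H, S, V")
  if (length(object@hWraps) != 1L || is.na(object@hWraps))
    msgs <- c(msgs, "'hWraps' must be TRUE or FALSE")
  for (ch in CHANNELS) {
    rng <- .channelRange(ch)
    lo <- object@lo[[ch]]; hi <- object@hi[[ch]]
    if (is.na(lo) || is.na(hi) || lo < rng[1] || hi < rng[1] ||
        lo > rng[2] || hi > rng[2] || (ch == "H" && (lo >= 360 || hi >= 360)))
      msgs <- c(msgs, sprintf("channel %s bounds outside its range", ch))
    if (ch != "H" && lo > hi)
      msgs <- c(msgs, sprintf("channel %s requires lo <= hi", ch))
    if (ch == "H" && lo > hi && !isTRUE(object@hWraps))
      msgs <- c(msgs, "hue lo > hi requires hWraps = TRUE")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname ThresholdProfile-class
#' @param lo,hi numeric vectors of lower/upper bounds, named or in channel
#'   order `R, G, B, H, S, V`.
#' @param hWraps does the hue interval wrap around 0/360?
#' @return A `ThresholdProfile`.
#' @examples
#' ThresholdProfile(lo = c(0, 100, 0, 80, 0.2, 0.1),
#'                  hi = c(120, 255, 120, 160, 1, 1))
#' @export
ThresholdProfile <- function(lo, hi, hWraps = FALSE) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  names(lo) <- names(hi) <- CHANNELS
  new("ThresholdProfile", lo = lo, hi = hi, hWraps = isTRUE(hWraps))
}

setMethod("show", "ThresholdProfile", function(object) {
  cat("ThresholdProfile\n")
  for (ch in CHANNELS)
    cat(sprintf("  %s: [%g, %g]%s\n", ch, object@lo[[ch]], object@hi[[ch]],
                if (ch == "H" && object@hWraps) " (wraps)" else ""))
})

#' Object class definition
#'
#' Binds one or more colour [ThresholdProfile]s (a disjunction) to a named
#' scene object, optionally restricted to a [Region], with a display colour
#' used in colour-coded label images.  The class named `"plant"` must not be
#' region-bound: plant parts may appear anywhere in the image.
#'
#' @slot name class identifier, unique within a [ViewConfig].
#' @slot profiles list of [ThresholdProfile]; a pixel matches the class when
#'   it satisfies any one profile.
#' @slot region name of the restricting region, or `NA` for none.
#' @slot displayColour RGB triple in `[0, 255]`.
#'
#' @seealso [ObjectClass()], [ViewConfig()]
#' @export
setClass("ObjectClass",
  representation(name = "character", profiles = "list",
                 region = "character", displayColour = "numeric")
)

setValidity("ObjectClass", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a single non-empty string")
  if (identical(object@name, "background"))
    msgs <- c(msgs, "\"background\" is reserved for unmatched pixels")
  if (length(object@profiles) < 1L ||
      !all(vapply(object@profiles, is, logical(1), "ThresholdProfile")))
    msgs <- c(msgs, "'profiles' must be a non-empty list of ThresholdProfile")
  if (length(object@region) != 1L)
    msgs <- c(msgs, "'region' must be a single string or NA")
  dc <- object@displayColour
  if (length(dc) != 3L || anyNA(dc) || any(dc < 0 | dc > 255))
    msgs <- c(msgs, "'displayColour' must be an RGB triple in [0, 255]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ObjectClass-class
#' @param name class identifier.
#' @param profiles a [ThresholdProfile] or list of them.
#' @param region optional region name (`NA` = unrestricted).
#' @param displayColour RGB triple for label-image rendering.
#' @return An `ObjectClass`.
#' @export
ObjectClass <- function(name, profiles, region = NA_character_,
                        displayColour = c(128, 128, 128)) {
  if (is(profiles, "ThresholdProfile")) profiles <- list(profiles)
  new("ObjectClass", name = as.character(name), profiles = profiles,
      region = as.character(region), displayColour = as.numeric(displayColour))
}

setMethod("show", "ObjectClass", function(object) {
  cat(sprintf("ObjectClass \"%s\": %d profile(s), region %s\n", object@name,
              length(object@profiles),
              if (is.na(object@region)) "<none>" else dQuote(object@region)))
})

#' Per-view segmentation configuration
#'
#' The complete calibration for one camera view: the ordered object classes
#' (declaration order is segmentation priority, first match wins), the named
#' regions they may reference, the automatic region scaling factor, the
#' pixel-to-millimetre factor and the structuring-element radius of the
#' morphological opening applied to the plant mask.
#'
#' @slot view `"top"` or `"side"`.
#' @slot classes ordered list of [ObjectClass].
#' @slot regions list of [Region], named by region name.
#' @slot regionScale positive scalar multiplying every region about its
#'   centroid before rasterization (camera-zoom compensation).
#' @slot mmPerPx physical edge length of one pixel in millimetres.
#' @slot openingRadius half-width of the square structuring element; the
#'   element is `(2 * openingRadius + 1)` pixels on a side.
#' @slot configId free-form identifier recorded in result tables.
#'
#' @seealso [ViewConfig()], [readViewConfig()], [validateConfig()],
#'   [segmentImage()]
#' @export
setClass("ViewConfig",
  representation(view = "character", classes = "list", regions = "list",
                 regionScale = "numeric", mmPerPx = "numeric",
                 openingRadius = "numeric", configId = "character")
)

setValidity("ViewConfig", function(object) {
  msgs <- character()
  if (length(object@view) != 1L || !object@view %in% c("top", "side"))
    msgs <- c(msgs, "'view' must be \"top\" or \"side\"")
  if (!all(vapply(object@classes, is, logical(1), "ObjectClass")))
    msgs <- c(msgs, "'classes' must be a list of ObjectClass")
  if (!all(vapply(object@regions, is, logical(1), "Region")))
    msgs <- c(msgs, "'regions' must be a list of Region")
  cn <- vapply(object@classes, function(x) x@name, character(1))
  if (anyDuplicated(cn))
    msgs <- c(msgs, "class names must be unique within a view")
  rn <- vapply(object@regions, function(x) x@name, character(1))
  if (anyDuplicated(rn))
    msgs <- c(msgs, "region names must be unique within a view")
  for (cl in object@classes) {
    if (identical(cl@name, "plant") && !is.na(cl@region))
      msgs <- c(msgs, "the \"plant\" class must not be region-bound")
  }
  if (length(object@regionScale) != 1L || is.na(object@regionScale) ||
      object@regionScale <= 0)
    msgs <- c(msgs, "'regionScale' must be a positive scalar")
  if (length(object@mmPerPx) != 1L || !is.finite(object@mmPerPx))
    msgs <- c(msgs, "'mmPerPx' must be a finite scalar")
  if (length(object@openingRadius) != 1L || is.na(object@openingRadius) ||
      object@openingRadius < 0 ||
      object@openingRadius != round(object@openingRadius))
    msgs <- c(msgs, "'openingRadius' must be a non-negative integer")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ViewConfig-class
#' @param view `"top"` or `"side"`.
#' @param classes ordered list of [ObjectClass] (priority order).
#' @param regions list of [Region].
#' @param regionScale positive region scaling factor.
#' @param mmPerPx millimetres per pixel edge.
#' @param openingRadius structuring-element half-width (integer `>= 0`).
#' @param configId identifier recorded in result tables.
#' @return A `ViewConfig`.
#' @export
ViewConfig <- function(view, classes, regions = list(), regionScale = 1,
                       mmPerPx = 1, openingRadius = 1L,
                       configId = "unnamed") {
  regions <- as.list(regions)
  names(regions) <- vapply(regions, function(r) r@name, character(1))
  new("ViewConfig", view = view, classes = as.list(classes),
      regions = regions, regionScale = as.numeric(regionScale),
      mmPerPx = as.numeric(mmPerPx),
      openingRadius = as.numeric(openingRadius),
      configId = as.character(configId))
}

setMethod("show", "ViewConfig", function(object) {
  cat(sprintf("ViewConfig \"%s\" (%s view)\n", object@configId, object@view))
  cat(sprintf("  %d classes: %s\n", length(object@classes),
              paste(vapply(object@classes, function(x) x@name, character(1)),
                    collapse = ", ")))
  cat(sprintf("  %d regions, regionScale %g, mmPerPx %g, openingRadius %d\n",
              length(object@regions), object@regionScale, object@mmPerPx,
              as.integer(object@openingRadius)))
})

#' Per-pixel class assignment
#'
#' Stores the segmentation result: an integer matrix with 0 for the reserved
#' `"background"` label and `i` for the i-th class of the originating
#' [ViewConfig], together with the class name vector.
#'
#' @slot labels integer matrix (rows = image rows).
#' @slot classNames character vector; `labels` values index into it.
#'
#' @seealso [segmentImage()], [extractPlant()], [labelColourImage()]
#' @export
setClass("LabelImage",
  representation(labels = "matrix", classNames = "character")
)

setValidity("LabelImage", function(object) {
  l <- object@labels
  if (!is.numeric(l) || anyNA(l))
    return("'labels' must be a numeric matrix without NAs")
  if (any(l < 0) || any(l > length(object@classNames)) || any(l != round(l)))
    return("'labels' must index classNames (0 = background)")
  TRUE
})

#' @rdname LabelImage-class
#' @param labels integer label matrix (0 = background).
#' @param classNames class names indexed by positive labels.
#' @return A `LabelImage`.
#' @export
LabelImage <- function(labels, classNames) {
  storage.mode(labels) <- "integer"
  new("LabelImage", labels = labels, classNames = as.character(classNames))
}

setMethod("show", "LabelImage", function(object) {
  tab <- tabulate(object@labels + 1L, nbins = length(object@classNames) + 1L)
  cat(sprintf("LabelImage %d x %d px\n", nrow(object@labels),
              ncol(object@labels)))
  nm <- c("background", object@classNames)
  for (i in seq_along(nm))
    if (tab[i] > 0) cat(sprintf("  %s: %d px\n", nm[i], tab[i]))
})

#' Binary plant mask
#'
#' The plant-foreground mask obtained by extracting the `"plant"` label from a
#' [LabelImage] (and, downstream, refined by [maskOpening()]).
#'
#' @slot mask logical matrix; `TRUE` = plant pixel.
#'
#' @seealso [extractPlant()], [maskOpening()], [measurePlant()]
#' @export
setClass("PlantMask", representation(mask = "matrix"))

setValidity("PlantMask", function(object) {
  if (!is.logical(object@mask) || anyNA(object@mask))
    return("'mask' must be a logical matrix without NAs")
  TRUE
})

#' @rdname PlantMask-class
#' @param mask logical matrix (`TRUE` = plant).
#' @return A `PlantMask`.
#' @export
PlantMask <- function(mask) {
  storage.mode(mask) <- "logical"
  new("PlantMask", mask = mask)
}

setMethod("show", "PlantMask", function(object) {
  cat(sprintf("PlantMask %d x %d px, %d plant pixel(s)\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask)))
})
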