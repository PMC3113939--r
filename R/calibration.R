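## Calibration: turn labelled pixel samples into per-class threshold
## profiles, validate whole-view configurations, and read/write the YAML
## configuration files.

## Smallest circular interval covering a hue sample, optionally trimmed.
## The reference cut is placed in the largest circular gap between sorted
## sample hues, which minimizes the circular span of the covered arc.
.circularHueInterval <- function(h, trim = 0) {
  h <- h %% 360
  n <- length(h)
  if (n == 1L) return(list(lo = h, hi = h, wraps = FALSE))
  hs <- sort(h)
  gaps <- c(diff(hs), hs[1L] + 360 - hs[n])
  k <- which.max(gaps)
  start <- if (k == n) hs[1L] else hs[k + 1L]
  end <- if (k == n) hs[n] else hs[k]
  if (trim == 0) {
    ## endpoints are exact sample hues; no modular arithmetic that could
    ## perturb the bounds by a few ulps and exclude a boundary sample
    lo <- start; hi <- end
  } else {
    shifted <- (h - start) %% 360
    qs <- stats::quantile(shifted, c(trim, 1 - trim), names = FALSE)
    lo <- (start + qs[1L]) %% 360
    hi <- (start + qs[2L]) %% 360
  }
  list(lo = lo, hi = hi, wraps = lo > hi)
}

#' Derive a threshold profile from labelled pixel samples
#'
#' The calibration estimator: for each of the six channels (`R, G, B` as
#' given, `H, S, V` via [rgbToHsv()]) the lower and upper thresholds are the
#' `trim` and `1 - trim` sample quantiles; `trim = 0` gives the exact sample
#' minimum and maximum, so every sample pixel satisfies the derived profile.
#' Hue is handled circularly: the reference cut that minimizes the circular
#' span of the sample hues is chosen before quantiles are taken, and the
#' wrap-around flag is set accordingly (so samples straddling 0/360 degrees
#' yield a narrow wrapping interval rather than the whole hue circle).
#'
#' @param samples labelled pixels of one object class: an `n x 3` matrix (or
#'   length-3 vector) of RGB intensities in `[0, 255]`.
#' @param trim trimming fraction in `[0, 0.5)`; positive values discard the
#'   most extreme sample values per channel, adding robustness against
#'   mislabelled pixels.
#' @return A [ThresholdProfile].
#' @examples
#' deriveProfile(rbind(c(10, 200, 10), c(20, 220, 30)))
#' @seealso [profileContains()], [readPixelSamples()]
#' @export
deriveProfile <- function(samples, trim = 0) {
  if (length(samples) == 0L) stop("'samples' must contain at least one pixel")
  if (!is.numeric(trim) || length(trim) != 1L || is.na(trim) ||
      trim < 0 || trim >= 0.5)
    stop("'trim' must be a fraction in [0, 0.5)")
  ch <- pixelChannels(samples)
  lo <- hi <- numeric(6L)
  names(lo) <- names(hi) <- CHANNELS
  for (cc in setdiff(CHANNELS, "H")) {
    q <- stats::quantile(ch[, cc], c(trim, 1 - trim), names = FALSE)
    lo[[cc]] <- q[1L]; hi[[cc]] <- q[2L]
  }
  hint <- .circularHueInterval(ch[, "H"], trim)
  lo[["H"]] <- hint$lo; hi[["H"]] <- hint$hi
  ThresholdProfile(lo, hi, hWraps = hint$wraps)
}

#' Test pixels against a threshold profile
#'
#' A pixel satisfies a profile when every one of its six channel values lies
#' inside the corresponding closed interval; the hue test is circular when
#' the interval wraps (`h >= lo | h <= hi`).
#'
#' @param profile a [ThresholdProfile].
#' @param channels an `n x 6` channel matrix from [pixelChannels()], or raw
#'   RGB input accepted by it.
#' @return Logical vector of length `n`.
#' @examples
#' p <- deriveProfile(c(10, 200, 10))
#' profileContains(p, c(10, 200, 10))
#' @export
profileContains <- function(profile, channels) {
  if (is.null(dim(channels)) || ncol(channels) != 6L)
    channels <- pixelChannels(channels)
  ok <- rep(TRUE, nrow(channels))
  for (cc in setdiff(CHANNELS, "H"))
    ok <- ok & channels[, cc] >= profile@lo[[cc]] &
               channels[, cc] <= profile@hi[[cc]]
  h <- channels[, "H"]
  lo <- profile@lo[["H"]]; hi <- profile@hi[["H"]]
  hok <- if (profile@hWraps && lo > hi) (h >= lo | h <= hi)
         else (h >= lo & h <= hi)
  ok & hok
}

## interval [lo,hi] (possibly wrapping) as a list of plain arcs on [0,360)
.hueArcs <- function(lo, hi, wraps) {
  if (wraps && lo > hi) list(c(lo, 360), c(0, hi)) else list(c(lo, hi))
}

.profilesIntersect <- function(p1, p2) {
  for (cc in setdiff(CHANNELS, "H")) {
    if (max(p1@lo[[cc]], p2@lo[[cc]]) > min(p1@hi[[cc]], p2@hi[[cc]]))
      return(FALSE)
  }
  a1 <- .hueArcs(p1@lo[["H"]], p1@hi[["H"]], p1@hWraps)
  a2 <- .hueArcs(p2@lo[["H"]], p2@hi[["H"]], p2@hWraps)
  for (u in a1) for (v in a2)
    if (max(u[1], v[1]) <= min(u[2], v[2])) return(TRUE)
  FALSE
}

#' Diagnose problems in a view configuration
#'
#' Returns human-readable diagnostics rather than raising errors, so a
#' configuration under construction can be inspected as a whole:
#' \itemize{
#'   \item classes referencing regions that do not exist;
#'   \item pairs of classes bound to the same region whose threshold volumes
#'     intersect on all six channels (ambiguous pixels resolved only by
#'     declaration order);
#'   \item zero-area regions (degenerate rectangles);
#'   \item a non-positive millimetre-per-pixel factor.
#' }
#'
#' @param cfg a [ViewConfig].
#' @return Character vector of diagnostics; empty iff the configuration is
#'   sound.
#' @examples
#' validateConfig(defaultViewConfig("top"))  # character(0)
#' @export
validateConfig <- function(cfg) {
  out <- character()
  regionNames <- vapply(cfg@regions, function(r) r@name, character(1))
  for (cl in cfg@classes) {
    if (!is.na(cl@region) && !cl@region %in% regionNames)
      out <- c(out, sprintf(
        "class \"%s\" references missing region \"%s\"", cl@name, cl@region))
  }
  for (r in cfg@regions) {
    g <- r@geometry
    if (r@shape == "rectangle" && (g[1] == g[3] || g[2] == g[4]))
      out <- c(out, sprintf("region \"%s\" has zero area", r@name))
  }
  if (cfg@mmPerPx <= 0)
    out <- c(out, sprintf("mm_per_px must be positive (got %g)", cfg@mmPerPx))
  cls <- cfg@classes
  if (length(cls) >= 2L) {
    for (i in seq_len(length(cls) - 1L)) for (j in (i + 1L):length(cls)) {
      ri <- cls[[i]]@region; rj <- cls[[j]]@region
      if (is.na(ri) || is.na(rj) || ri != rj) next
      hit <- FALSE
      for (pi in cls[[i]]@profiles) for (pj in cls[[j]]@profiles)
        if (.profilesIntersect(pi, pj)) hit <- TRUE
      if (hit)
        out <- c(out, sprintf(
          "classes \"%s\" and \"%s\" share region \"%s\" with overlapping colour volumes",
          cls[[i]]@name, cls[[j]]@name, ri))
    }
  }
  out
}

#' Read labelled pixel samples
#'
#' Reads the plain-text calibration sample format: one pixel per line,
#' `r,g,b,label`, no header.
#'
#' @param path file path.
#' @return A `data.frame` with integer columns `r`, `g`, `b` and character
#'   column `label`.
#' @seealso [deriveProfile()]
#' @export
readPixelSamples <- function(path) {
  df <- utils::read.csv(path, header = FALSE,
                        col.names = c("r", "g", "b", "label"),
                        colClasses = c("integer", "integer", "integer",
                                       "character"),
                        strip.white = TRUE)
  if (nrow(df) == 0L) stop("no pixel samples in ", path)
  df
}

## ---- configuration file I/O (YAML, one document per view) ----

.profileToList <- function(p) {
  out <- list(h_unit = "degrees")
  for (cc in CHANNELS) out[[cc]] <- c(p@lo[[cc]], p@hi[[cc]])
  out
}

.profileFromList <- function(x) {
  unit <- if (is.null(x$h_unit)) "degrees" else x$h_unit
  if (!unit %in% c("degrees", "byte"))
    stop("profile h_unit must be \"degrees\" or \"byte\"")
  lo <- hi <- numeric(6L); names(lo) <- names(hi) <- CHANNELS
  for (cc in CHANNELS) {
    v <- x[[cc]]
    if (is.null(v) || length(v) != 2L)
      stop("profile must give [lo, hi] for channel ", cc)
    lo[[cc]] <- v[1L]; hi[[cc]] <- v[2L]
  }
  if (unit == "byte") {
    lo[["H"]] <- lo[["H"]] * 360 / 256
    hi[["H"]] <- hi[["H"]] * 360 / 256
  }
  ThresholdProfile(lo, hi, hWraps = lo[["H"]] > hi[["H"]])
}

#' Read a view configuration file
#'
#' Parses the package's YAML configuration schema (one document per view;
#' a `schema` version field is required).  Hue thresholds may be declared in
#' degrees (`h_unit: degrees`, the native unit) or as 8-bit values
#' (`h_unit: byte`), which are rescaled by 360/256 on input.  A hue interval
#' with `lo > hi` denotes a wrap-around interval.
#'
#' @param path path to the YAML file.
#' @return A [ViewConfig].
#' @seealso [writeViewConfig()], [validateConfig()], [defaultViewConfig()]
#' @export
readViewConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema) || doc$schema != 1L)
    stop("configuration file must declare 'schema: 1'")
  regions <- lapply(doc$regions, function(r)
    Region(r$name, r$shape, as.numeric(r$geometry)))
  classes <- lapply(doc$classes, function(cl) {
    ObjectClass(cl$name,
                profiles = lapply(cl$profiles, .profileFromList),
                region = if (is.null(cl$region)) NA_character_ else cl$region,
                displayColour = as.numeric(cl$display_colour))
  })
  ViewConfig(view = doc$view, classes = classes, regions = regions,
             regionScale = doc$region_scale, mmPerPx = doc$mm_per_px,
             openingRadius = doc$opening_radius,
             configId = if (is.null(doc$id)) "unnamed" else doc$id)
}

#' Write a view configuration file
#'
#' @param cfg a [ViewConfig].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readViewConfig()]
#' @export
writeViewConfig <- function(cfg, path) {
  doc <- list(
    schema = 1L,
    id = cfg@configId,
    view = cfg@view,
    mm_per_px = cfg@mmPerPx,
    region_scale = cfg@regionScale,
    opening_radius = as.integer(cfg@openingRadius),
    regions = lapply(unname(cfg@regions), function(r)
      list(name = r@name, shape = r@shape, geometry = as.numeric(r@geometry))),
    classes = lapply(cfg@classes, function(cl) {
      out <- list(name = cl@name,
                  display_colour = as.numeric(cl@displayColour))
      if (!is.na(cl@region)) out$region <- cl@region
      out$profiles <- lapply(cl@profiles, .profileToList)
      out
    })
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Packaged default view configurations
#'
#' The defaults mirror the standard automated-greenhouse scene: in top view
#' five regions (soil, carrier, cages, sticks, conveyor belt), in side view
#' three (carrier, cages, sticks), each with a region-bound object class,
#' plus the unrestricted `"plant"` class declared last.  Threshold profiles
#' are derived from the packaged reference palette (see [syntheticPalette()])
#' with a colour margin wide enough to absorb moderate illumination noise;
#' the plant profile covers green foliage tones only, so yellow and brown
#' plant parts (senescent leaf tips) fall outside it by design.
#'
#' The same configurations are shipped as YAML files under
#' `system.file("extdata", package = "phenopipe")`.
#'
#' @param view `"top"` or `"side"`.
#' @param width,height reference image size in pixels used to lay out the
#'   region geometry.
#' @param mmPerPx,regionScale,openingRadius calibration scalars.
#' @return A [ViewConfig].
#' @examples
#' defaultViewConfig("top")
#' @export
defaultViewConfig <- function(view = c("top", "side"), width = 200L,
                              height = if (match.arg(view) == "top") 200L else 240L,
                              mmPerPx = 1, regionScale = 1,
                              openingRadius = 1L) {
  view <- match.arg(view)
  paletteConfig(view, width = width, height = height, mmPerPx = mmPerPx,
                regionScale = regionScale, openingRadius = openingRadius,
                configId = paste0("default-", view))
}
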