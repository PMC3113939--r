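## Visual analysis result: plant outline, extent/diameter overlays, scale
## bar, and the per-plant processing-stage image stack.

#' Annotation style
#'
#' Colours and geometry of the visual analysis overlays.  Defaults follow
#' the conventional colour coding: red outline, light-green extent lines,
#' orange diameter, a 100 mm scale bar.
#'
#' @param outlineColour,extentColour,diameterColour RGB triples.
#' @param scaleBarMm physical scale-bar length in millimetres (positive).
#' @param lineWidth overlay line width in pixels (`>= 1`).
#' @return A list of class `"AnnotationStyle"`.
#' @seealso [renderAnnotation()]
#' @export
annotationStyle <- function(outlineColour = c(255, 0, 0),
                            extentColour = c(144, 238, 144),
                            diameterColour = c(255, 165, 0),
                            scaleBarMm = 100, lineWidth = 1L) {
  stopifnot(length(outlineColour) == 3L, length(extentColour) == 3L,
            length(diameterColour) == 3L)
  if (!is.numeric(scaleBarMm) || scaleBarMm <= 0)
    stop("'scaleBarMm' must be positive")
  if (!is.numeric(lineWidth) || lineWidth < 1)
    stop("'lineWidth' must be >= 1")
  structure(list(outlineColour = as.numeric(outlineColour),
                 extentColour = as.numeric(extentColour),
                 diameterColour = as.numeric(diameterColour),
                 scaleBarMm = as.numeric(scaleBarMm),
                 lineWidth = as.integer(lineWidth)),
            class = "AnnotationStyle")
}

#' Trace the plant outline
#'
#' The outline is the set of plant pixels with at least one 4-neighbour that
#' is background or outside the image — the boundary under 4-connectivity,
#' which draws as a closed-looking contour around 8-connected shapes.
#'
#' @param m a [PlantMask].
#' @return A [PlantMask] that is `TRUE` exactly on the boundary pixels.
#' @examples
#' b <- matrix(FALSE, 6, 6); b[2:5, 2:5] <- TRUE
#' sum(maskMatrix(traceOutline(PlantMask(b))))  # 12 border pixels
#' @export
traceOutline <- function(m) {
  src <- m@mask
  interior <- src &
    .shiftLogical(src, 1L, 0L) & .shiftLogical(src, -1L, 0L) &
    .shiftLogical(src, 0L, 1L) & .shiftLogical(src, 0L, -1L)
  PlantMask(src & !interior)
}

## paint a set of (row, col) 1-based coordinates, clipped to the image
.paintPixels <- function(img, rows, cols, colour) {
  keep <- rows >= 1L & rows <= dim(img)[1L] & cols >= 1L & cols <= dim(img)[2L]
  rows <- rows[keep]; cols <- cols[keep]
  for (k in 1:3)
    img[cbind(rows, cols, rep(k, length(rows)))] <- colour[k]
  img
}

## thicken 1-px coordinates into a square pen of the given line width
.penOffsets <- function(lineWidth) {
  r <- lineWidth %/% 2L
  lo <- -r; hi <- r - as.integer(lineWidth %% 2L == 0L)
  expand.grid(dy = lo:hi, dx = lo:hi)
}

.drawSegment <- function(img, x0, y0, x1, y1, colour, lineWidth = 1L) {
  n <- max(abs(x1 - x0), abs(y1 - y0)) + 1L
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  off <- .penOffsets(lineWidth)
  for (i in seq_len(nrow(off)))
    img <- .paintPixels(img, ys + 1L + off$dy[i], xs + 1L + off$dx[i], colour)
  img
}

#' Render the visual analysis result
#'
#' Overdraws the original image with the plant outline, the extent lines
#' (horizontal and vertical lines through the bounding-box centre, spanning
#' the box), the maximum-Feret-diameter segment in top view, and a
#' horizontal scale bar anchored 10 px from the bottom-right corner whose
#' pixel length is `round(scaleBarMm / mmPerPx)`.
#'
#' @param img the original image (`height x width x 3`, intensities 0–255).
#' @param m the refined [PlantMask]; must share dimensions with `img`.
#' @param rec the [measurePlant()] record for the mask (supplies the view).
#' @param style an [annotationStyle()].
#' @param mmPerPx millimetres per pixel edge.
#' @return The annotated image array (same dimensions as the input).
#' @export
renderAnnotation <- function(img, m, rec, style = annotationStyle(),
                             mmPerPx = 1) {
  if (!identical(dim(img)[1:2], dim(m@mask)))
    stop("'img' and 'm' must share dimensions")
  h <- dim(img)[1L]; w <- dim(img)[2L]
  out <- img
  if (any(m@mask)) {
    ob <- traceOutline(m)@mask
    idx <- which(ob, arr.ind = TRUE)
    out <- .paintPixels(out, idx[, 1L], idx[, 2L], style$outlineColour)
    xy <- .truePixelXY(m)
    x0 <- min(xy[, "x"]); x1 <- max(xy[, "x"])
    y0 <- min(xy[, "y"]); y1 <- max(xy[, "y"])
    xc <- round((x0 + x1) / 2); yc <- round((y0 + y1) / 2)
    out <- .drawSegment(out, x0, yc, x1, yc, style$extentColour,
                        style$lineWidth)
    out <- .drawSegment(out, xc, y0, xc, y1, style$extentColour,
                        style$lineWidth)
    if (identical(rec$view, "top")) {
      fe <- .feret(m)
      if (!is.null(fe$ends) && fe$d > 0)
        out <- .drawSegment(out, fe$ends[1L, "x"], fe$ends[1L, "y"],
                            fe$ends[2L, "x"], fe$ends[2L, "y"],
                            style$diameterColour, style$lineWidth)
    }
  }
  ## scale bar, bottom-right, 10 px margin
  barLen <- round(style$scaleBarMm / mmPerPx)
  if (barLen > w) warning("scale bar longer than image width; drawn clipped")
  xEnd <- w - 1L - 10L
  xStart <- xEnd - barLen + 1L
  yBar <- h - 1L - 10L
  out <- .drawSegment(out, max(0L, xStart), yBar, max(0L, xEnd), yBar,
                      c(255, 255, 255), style$lineWidth)
  out
}

#' Build the per-plant processing-stage image stack
#'
#' Collects the processing-stage images of one plant (original, regions
#' overlay, colour-coded labels, extracted plant, opened plant, annotated
#' result — in pipeline order) into one multi-page TIFF, or a numbered PNG
#' series, so every analysis step can be checked against the original.
#'
#' @param stages ordered list of `height x width x 3` image arrays sharing
#'   dimensions.
#' @param path output path: a `.tif`/`.tiff` file for a multi-page stack, or
#'   a `.png` path used as template for a numbered series
#'   (`name_01.png`, ...).
#' @return Character vector of the file(s) written, invisibly.
#' @export
buildStack <- function(stages, path) {
  if (!length(stages)) stop("'stages' must contain at least one image")
  dims <- lapply(stages, function(s) dim(s)[1:2])
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("all stage images must share dimensions")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(lapply(stages, function(s) s / 255), path)
    invisible(path)
  } else if (ext == "png") {
    base <- sub("\\.png$", "", path, ignore.case = TRUE)
    files <- sprintf("%s_%02d.png", base, seq_along(stages))
    for (i in seq_along(stages)) writePlantImage(stages[[i]], files[i])
    invisible(files)
  } else stop("unsupported stack format: ", ext)
}

#' Regions overlay image
#'
#' Renders the configuration's scaled regions on top of an image (region
#' boundaries drawn in each class's display colour), the second stage of the
#' processing stack.
#'
#' @param img the original image array.
#' @param cfg a [ViewConfig].
#' @return The overlay image array.
#' @seealso [buildStack()]
#' @export
regionOverlayImage <- function(img, cfg) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  out <- img
  masks <- regionMasks(cfg, w, h)
  for (cl in cfg@classes) {
    if (is.na(cl@region)) next
    rm <- masks[[cl@region]]
    if (is.null(rm) || !any(rm)) next
    border <- traceOutline(PlantMask(rm))@mask
    idx <- which(border, arr.ind = TRUE)
    out <- .paintPixels(out, idx[, 1L], idx[, 2L], cl@displayColour)
  }
  out
}
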