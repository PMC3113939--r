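#' Scale a region about its centroid
#'
#' Regions grow and shrink automatically with a user-defined scaling factor
#' (compensating for camera settings).  Scaling is performed about the region
#' centroid: a rectangle's half-widths and half-heights, or a circle's radius,
#' are multiplied by `factor` while the centroid stays fixed.  Scaled regions
#' may extend beyond the image; they are clipped at rasterization.
#'
#' @param r a [Region].
#' @param factor positive scalar.
#' @return A `Region` with scaled geometry.
#' @examples
#' scaleRegion(Region("carrier", "rectangle", c(0, 0, 10, 20)), 2)
#' @export
setMethod("scaleRegion", "Region", function(r, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor <= 0)
    stop("'factor' must be a positive scalar")
  g <- r@geometry
  if (r@shape == "rectangle") {
    cx <- (g[1] + g[3]) / 2; cy <- (g[2] + g[4]) / 2
    hw <- (g[3] - g[1]) / 2 * factor; hh <- (g[4] - g[2]) / 2 * factor
    Region(r@name, "rectangle", c(cx - hw, cy - hh, cx + hw, cy + hh))
  } else {
    Region(r@name, "circle", c(g[1], g[2], g[3] * factor))
  }
})

#' Rasterize a region to a binary mask
#'
#' A pixel with 0-based integer coordinate `(x, y)` (x = column, y = row,
#' origin top-left) is inside iff it satisfies the closed region inequality:
#' `x0 <= x <= x1 & y0 <= y <= y1` for rectangles,
#' `(x - cx)^2 + (y - cy)^2 <= radius^2` for circles.  Geometry outside the
#' image is clipped; a region fully outside yields an all-`FALSE` mask.
#'
#' @param r a [Region].
#' @param width,height image dimensions in pixels.
#' @return A `height x width` logical matrix.
#' @examples
#' sum(rasterize(Region("a", "rectangle", c(0, 0, 1, 1)), 4, 4))  # 4 pixels
#' @export
setMethod("rasterize", "Region", function(r, width, height) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width <= 0 || height <= 0)
    stop("'width' and 'height' must be positive")
  mask <- matrix(FALSE, nrow = height, ncol = width)
  g <- r@geometry
  if (r@shape == "rectangle") {
    x0 <- max(0L, ceiling(g[1])); x1 <- min(width - 1L, floor(g[3]))
    y0 <- max(0L, ceiling(g[2])); y1 <- min(height - 1L, floor(g[4]))
    if (x0 <= x1 && y0 <= y1)
      mask[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)] <- TRUE
  } else {
    dx2 <- (seq_len(width) - 1L - g[1])^2
    dy2 <- (seq_len(height) - 1L - g[2])^2
    mask <- outer(dy2, dx2, "+") <= g[3]^2
  }
  mask
})
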