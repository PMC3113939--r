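## RGB <-> HSV conversion for 8-bit pixels.
##
## Conventions fixed for the whole package: hue in degrees [0, 360),
## saturation and value in [0, 1], achromatic pixels (s = 0) get h = 0.
## Hue is numerically unstable at low saturation, which is exactly why
## segmentation combines both colour spaces rather than relying on HSV alone.

.asRgbMatrix <- function(rgb) {
  if (is.null(dim(rgb))) {
    if (length(rgb) %% 3L != 0L)
      stop("RGB input must have length a multiple of 3")
    rgb <- matrix(rgb, ncol = 3L, byrow = TRUE)
  }
  if (ncol(rgb) != 3L) stop("RGB input must have 3 columns")
  if (anyNA(rgb) || any(rgb < 0 | rgb > 255) || any(rgb != round(rgb)))
    stop("RGB channels must be integers in [0, 255]")
  rgb
}

#' Convert 8-bit RGB pixels to HSV
#'
#' Standard hexcone transform of the RGB cube.  Hue is returned in degrees
#' `[0, 360)`, saturation and value in `[0, 1]`.  Achromatic pixels
#' (`r == g == b`) have undefined hue in the continuous transform; the
#' package fixes `h = 0` for them so that threshold tests are deterministic.
#'
#' @param rgb an RGB pixel as a length-3 vector, or an `n x 3` matrix of
#'   pixels; integer intensities in `[0, 255]`.
#' @return An `n x 3` matrix with columns `H`, `S`, `V` (a `1 x 3` matrix for
#'   a single pixel).
#' @examples
#' rgbToHsv(c(255, 0, 0))        # pure red: h = 0, s = 1, v = 1
#' rgbToHsv(c(128, 128, 128))    # grey: s = 0, h = 0 by convention
#' @seealso [hsvToRgb()], [pixelChannels()]
#' @export
rgbToHsv <- function(rgb) {
  rgb <- .asRgbMatrix(rgb)
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 255))
  hsv[, 1L] <- (hsv[, 1L] * 360) %% 360
  colnames(hsv) <- c("H", "S", "V")
  hsv
}

#' Convert HSV pixels back to 8-bit RGB
#'
#' Inverse hexcone transform, with each channel rounded to the nearest
#' integer intensity.  Needed by annotation rendering and synthetic scene
#' construction; converting any valid RGB pixel to HSV and back reproduces
#' each channel within one intensity unit.
#'
#' @param hsv an HSV pixel as a length-3 vector `(h, s, v)` with `h` in
#'   degrees `[0, 360)` and `s`, `v` in `[0, 1]`, or an `n x 3` matrix.
#' @return An `n x 3` integer matrix with columns `R`, `G`, `B`.
#' @examples
#' hsvToRgb(c(0, 1, 1))      # (255, 0, 0)
#' hsvToRgb(c(0, 0, 0.5))    # (128, 128, 128)
#' @export
hsvToRgb <- function(hsv) {
  if (is.null(dim(hsv))) {
    if (length(hsv) %% 3L != 0L)
      stop("HSV input must have length a multiple of 3")
    hsv <- matrix(hsv, ncol = 3L, byrow = TRUE)
  }
  if (ncol(hsv) != 3L) stop("HSV input must have 3 columns")
  h <- hsv[, 1L]; s <- hsv[, 2L]; v <- hsv[, 3L]
  if (anyNA(hsv) || any(h < 0 | h >= 360) || any(s < 0 | s > 1) ||
      any(v < 0 | v > 1))
    stop("HSV fields must satisfy 0 <= h < 360, 0 <= s <= 1, 0 <= v <= 1")
  rgb <- t(grDevices::col2rgb(grDevices::hsv(h / 360, s, v)))
  colnames(rgb) <- c("R", "G", "B")
  storage.mode(rgb) <- "integer"
  rgb
}

#' Six-channel representation of RGB pixels
#'
#' Binds the raw RGB intensities to their HSV transform, giving the
#' `n x 6` channel matrix (`R, G, B, H, S, V`) on which threshold profiles
#' operate.
#'
#' @inheritParams rgbToHsv
#' @return An `n x 6` numeric matrix with columns `R, G, B, H, S, V`.
#' @seealso [profileContains()], [deriveProfile()]
#' @export
pixelChannels <- function(rgb) {
  rgb <- .asRgbMatrix(rgb)
  out <- cbind(rgb, rgbToHsv(rgb))
  colnames(out) <- CHANNELS
  out
}
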