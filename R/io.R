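## Image I/O.  Internally an image is a height x width x 3 integer array of
## 8-bit intensities (row 1 = top image row); PNG and TIFF go through the
## png and tiff packages, JPEG input through EBImage when available.

.toRgb255 <- function(a, path) {
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  out <- round(a * 255)
  storage.mode(out) <- "integer"
  out
}

#' Read a plant image
#'
#' Reads an 8-bit colour raster image (PNG, TIFF or JPEG) into the package's
#' internal representation: a `height x width x 3` integer array of
#' intensities in `[0, 255]`.  Greyscale images are expanded to three equal
#' channels; an alpha channel is dropped.
#'
#' @param path image file path; format chosen by extension.
#' @return A `height x width x 3` integer array.
#' @seealso [writePlantImage()], [segmentImage()]
#' @export
readPlantImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG input requires the EBImage package")
      img <- EBImage::readImage(path)
      aperm(array(img, dim = dim(img)), c(2L, 1L, 3L)[seq_along(dim(img))])
    },
    stop("unsupported image format: ", ext)
  )
  .toRgb255(a, path)
}

#' Write a plant image
#'
#' Writes a `height x width x 3` integer array (intensities in `[0, 255]`)
#' as PNG or TIFF.
#'
#' @param img the image array.
#' @param path output path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return `path`, invisibly.
#' @export
writePlantImage <- function(img, path) {
  if (anyNA(img) || any(img < 0 | img > 255))
    stop("'img' must contain intensities in [0, 255]")
  a <- img / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(a, path),
    tif = , tiff = tiff::writeTIFF(a, path),
    stop("unsupported output format: ", ext)
  )
  invisible(path)
}
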