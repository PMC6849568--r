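#' Calibrated 8-bit greyscale image
#'
#' An `Image8` is an integer matrix with values in `[0, 255]` plus a spatial
#' calibration (`pixel_size`, micrometres per pixel, isotropic). Rows index
#' image rows (y), columns index image columns (x). The calibration is
#' metadata only: no operation in the package rescales pixel arithmetic by
#' it.
#'
#' @param pixels integer or numeric matrix with values in `[0, 255]`.
#' @param pixel_size micrometres per pixel (positive scalar). The default is
#'   the calibration of a 1600x1200 px field imaging 1.19 x 0.89 mm
#'   (1190/1600 um/px).
#' @return An object of class `Image8`.
#' @export
image8 <- function(pixels, pixel_size = DEFAULT_PIXEL_SIZE) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("zero-sized raster", call. = FALSE)
  px <- pixels
  storage.mode(px) <- "integer"
  if (anyNA(px) || min(px) < 0L || max(px) > 255L)
    stop("Image8 values must be integers in [0, 255]", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a positive scalar (um/px)", call. = FALSE)
  structure(px, pixel_size = as.numeric(pixel_size),
            class = c("Image8", class(px)))
}

#' Default spatial calibration (um/px)
#'
#' 1190 um / 1600 px = 0.74375 um per pixel, the calibration of a
#' 1600 x 1200 pixel field covering 1.19 x 0.89 mm.
#' @export
DEFAULT_PIXEL_SIZE <- 1190 / 1600

#' Real-valued intermediate image
#'
#' `ImageF` carries the signed, real-valued intermediates of the pipeline
#' (mean-filtered images and their difference) with the geometry and
#' calibration of the source [image8()].
#'
#' @param pixels numeric matrix of finite values.
#' @param pixel_size micrometres per pixel.
#' @return An object of class `ImageF`.
#' @export
imagef <- function(pixels, pixel_size = DEFAULT_PIXEL_SIZE) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  px <- pixels
  storage.mode(px) <- "double"
  if (any(!is.finite(px))) stop("ImageF values must be finite", call. = FALSE)
  structure(px, pixel_size = as.numeric(pixel_size),
            class = c("ImageF", class(px)))
}

#' Binary mask
#'
#' A `BinaryMask` is a 0/1 integer matrix with the geometry and calibration
#' of its source image.
#'
#' @param pixels matrix; any nonzero value is foreground.
#' @param pixel_size micrometres per pixel.
#' @return An object of class `BinaryMask`.
#' @export
binary_mask <- function(pixels, pixel_size = DEFAULT_PIXEL_SIZE) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  px <- (pixels != 0) * 1L
  dim(px) <- dim(pixels)
  structure(px, pixel_size = as.numeric(pixel_size),
            class = c("BinaryMask", class(px)))
}

#' Spatial calibration of an image
#' @param x an [image8()], [imagef()], [binary_mask()] or labeled-regions
#'   object.
#' @return micrometres per pixel.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size", exact = TRUE)
  if (is.null(ps)) DEFAULT_PIXEL_SIZE else ps
}

# strip classes/attributes down to a plain matrix
as_plain_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "pixel_size") <- NULL
  m
}

#' @export
print.Image8 <- function(x, ...) {
  cat(sprintf("<Image8> %d x %d px, %.5f um/px, range [%d, %d]\n",
              ncol(x), nrow(x), pixel_size(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.ImageF <- function(x, ...) {
  cat(sprintf("<ImageF> %d x %d px, %.5f um/px, range [%.3f, %.3f]\n",
              ncol(x), nrow(x), pixel_size(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("<BinaryMask> %d x %d px, %d foreground px\n",
              ncol(x), nrow(x), sum(x)))
  invisible(x)
}
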