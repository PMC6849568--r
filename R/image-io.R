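#' Read a calibrated greyscale image
#'
#' Reads a TIFF or PNG raster into an [image8()]. Multi-channel inputs are
#' converted to greyscale by the unweighted channel average, and rasters
#' deeper than 8 bits are rescaled to `[0, 255]` by max-normalisation; both
#' conversions emit a warning so unusual lab exports are visible in logs.
#'
#' @param path path to a TIFF (`.tif`/`.tiff`) or PNG file.
#' @param pixel_size micrometres per pixel to attach as calibration.
#' @return An [image8()].
#' @export
read_image <- function(path, pixel_size = DEFAULT_PIXEL_SIZE) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    round(png::readPNG(path) * 255)
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(px)) == 3L) {
    warning("multi-channel image '", basename(path),
            "' converted to greyscale by channel average")
    px <- apply(px, c(1L, 2L), mean)
  }
  if (!is.matrix(px) || nrow(px) < 1L || ncol(px) < 1L)
    stop("zero-sized or undecodable raster: ", path, call. = FALSE)
  mx <- max(px)
  if (mx > 255) {
    warning("image '", basename(path),
            "' is deeper than 8 bits; rescaled to [0,255] by max-normalisation")
    px <- px / mx * 255
  }
  image8(round(px), pixel_size = pixel_size)
}

#' Write an 8-bit greyscale image
#'
#' Round-trips bit-exactly through [read_image()].
#'
#' @param image an [image8()].
#' @param path output path; `.png` selects PNG, anything else TIFF.
#' @export
write_image <- function(image, path) {
  m <- as_plain_matrix(image) / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  }
  invisible(NULL)
}

#' Write a binary mask
#'
#' Foreground pixels are stored as 255 so the file is viewable; reading it
#' back with [read_mask()] reproduces the written mask bit-exactly. A
#' labeled image may be passed: any positive label is written as foreground.
#'
#' @param mask a [binary_mask()], or an integer label matrix.
#' @param path output path (TIFF, or PNG if the extension is `.png`).
#' @export
write_mask <- function(mask, path) {
  m <- (as_plain_matrix(mask) > 0) * 1.0
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  }
  invisible(NULL)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path path to the mask file.
#' @param pixel_size micrometres per pixel.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, pixel_size = DEFAULT_PIXEL_SIZE) {
  img <- read_image(path, pixel_size = pixel_size)
  binary_mask(as_plain_matrix(img) > 0, pixel_size = pixel_size)
}
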