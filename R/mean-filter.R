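#' Disk mean filter with replicated borders
#'
#' Replaces every pixel by the arithmetic mean of the input pixels inside
#' the disk kernel `{(dx, dy): dx^2 + dy^2 <= r^2}` centred on it. Borders
#' are handled by edge replication, so a constant image stays constant and
#' no dark rim is introduced that could create a spurious threshold class.
#' `radius = 0` returns the input unchanged (as an [imagef()]).
#'
#' The filter is computed from per-row running sums (an integral-image
#' decomposition of the disk into horizontal chords), so cost grows with
#' the kernel diameter rather than its area.
#'
#' @param image an [image8()] or [imagef()].
#' @param radius kernel radius in pixels (integer >= 0).
#' @return An [imagef()] with the geometry and calibration of `image`.
#' @export
mean_filter <- function(image, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius < 0 || radius != floor(radius))
    stop("`radius` must be a non-negative integer", call. = FALSE)
  r <- as.integer(radius)
  ps <- pixel_size(image)
  m <- as_plain_matrix(image)
  storage.mode(m) <- "double"
  if (r == 0L) return(imagef(m, pixel_size = ps))

  h <- nrow(m); w <- ncol(m)
  # pad by edge replication
  ri <- c(rep(1L, r), seq_len(h), rep(h, r))
  ci <- c(rep(1L, r), seq_len(w), rep(w, r))
  p <- m[ri, ci, drop = FALSE]

  # cumulative sums along x with a leading zero column:
  # cs[, j + 1] = sum of p[, 1..j]
  cs <- cbind(0, t(apply(p, 1L, cumsum)))

  # chord half-widths per row offset
  dys <- -r:r
  hw <- as.integer(floor(sqrt(r^2 - dys^2)))
  npx <- sum(2L * hw + 1L)

  out <- matrix(0, h, w)
  cols <- seq_len(w) + r            # padded column index of each output col
  for (k in seq_along(dys)) {
    rows <- seq_len(h) + r + dys[k] # padded row index at this offset
    wk <- hw[k]
    out <- out + cs[rows, cols + wk + 1L, drop = FALSE] -
                 cs[rows, cols - wk,      drop = FALSE]
  }
  imagef(out / npx, pixel_size = ps)
}

# 3x3 box mean with replicated borders (used by the nuclei pipeline)
box_mean3 <- function(image) {
  ps <- pixel_size(image)
  m <- as_plain_matrix(image)
  storage.mode(m) <- "double"
  h <- nrow(m); w <- ncol(m)
  ri <- c(1L, seq_len(h), h)
  ci <- c(1L, seq_len(w), w)
  p <- m[ri, ci, drop = FALSE]
  out <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2)
    out <- out + p[dy + seq_len(h), dx + seq_len(w), drop = FALSE]
  imagef(out / 9, pixel_size = ps)
}

#' Subtract small- and large-radius mean filters
#'
#' Computes `mean_filter(image, r_large) - mean_filter(image, r_small)`.
#' With radii spanning the bright halo ring, a cell's dark interior is
#' brightened by the large filter and left dark by the small one, so cell
#' interiors become positive in the difference and a global threshold can
#' isolate them.
#'
#' @param image an [image8()].
#' @param params a [segmentation_params()].
#' @return A signed [imagef()].
#' @export
dual_filter_subtract <- function(image, params) {
  params <- as_segmentation_params(params)
  lg <- mean_filter(image, params$r_large)
  sm <- mean_filter(image, params$r_small)
  imagef(as_plain_matrix(lg) - as_plain_matrix(sm),
         pixel_size = pixel_size(image))
}

#' Mean in-cell intensity as a function of filter radius
#'
#' For each radius, mean-filters the image and averages the filtered value
#' over the supplied sample points (typically points inside cell
#' cytoplasm). On phase-contrast images of halo-ringed cells the profile
#' rises to a maximum near the radius at which the kernel first spans the
#' bright cell edge, which guides the choice of the large filter radius.
#'
#' @param image an [image8()].
#' @param sample_points two-column matrix or data.frame of pixel
#'   coordinates (`x` = column, `y` = row), 1-based.
#' @param radii vector of kernel radii (pixels), strictly increasing.
#' @return A list of class `IntensityProfile` with `radii` and
#'   `mean_intensities`.
#' @export
probe_intensity_vs_radius <- function(image, sample_points, radii) {
  if (length(radii) < 1L) stop("`radii` must be non-empty", call. = FALSE)
  if (is.unsorted(radii, strictly = TRUE))
    stop("`radii` must be strictly increasing", call. = FALSE)
  pts <- as.matrix(as.data.frame(sample_points))
  if (ncol(pts) != 2L) stop("`sample_points` needs columns x, y", call. = FALSE)
  x <- as.integer(pts[, 1L]); y <- as.integer(pts[, 2L])
  if (any(x < 1L | x > ncol(image) | y < 1L | y > nrow(image)))
    stop("sample point out of image bounds", call. = FALSE)
  mi <- vapply(radii, function(r) {
    f <- as_plain_matrix(mean_filter(image, r))
    mean(f[cbind(y, x)])
  }, numeric(1))
  structure(list(radii = as.integer(radii), mean_intensities = mi),
            class = "IntensityProfile")
}

#' @export
print.IntensityProfile <- function(x, ...) {
  cat(sprintf("<IntensityProfile> %d radii, peak %.2f at r=%d\n",
              length(x$radii), max(x$mean_intensities),
              x$radii[which.max(x$mean_intensities)]))
  invisible(x)
}
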