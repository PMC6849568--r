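#' Count cells across a set of images and extrapolate to the culture
#'
#' Segments each image with the given parameters, optionally applies a
#' trained noise filter, and extrapolates the mean per-image count to the
#' whole culture with [estimate_total()]. A blank field of view (constant
#' difference image) is counted as 0 with a warning; an unreadable file is
#' skipped with a warning; if every image fails the call errors.
#'
#' @param paths character vector of image paths, or a list of [image8()]
#'   objects.
#' @param params a [segmentation_params()].
#' @param noise_model optional [train_lda()] model (or path to a JSON model
#'   written by [write_lda_model()]).
#' @param a_total,a_image culture and field areas (mm^2).
#' @param pixel_size calibration attached to images read from disk.
#' @return A list of class `CountRun`: `counts` (data.frame `image`,
#'   `count`), `estimate` ([estimate_total()]), `params`.
#' @export
run_count <- function(paths, params = segmentation_params(),
                      noise_model = NULL, a_total = dish_area(35),
                      a_image = 1.19 * 0.89,
                      pixel_size = DEFAULT_PIXEL_SIZE) {
  if (length(paths) < 1L) stop("no images supplied", call. = FALSE)
  params <- as_segmentation_params(params)
  if (is.character(noise_model)) noise_model <- read_lda_model(noise_model)

  names_out <- if (is.character(paths)) basename(paths)
               else sprintf("image_%d", seq_along(paths))
  counts <- rep(NA_real_, length(paths))
  for (i in seq_along(paths)) {
    img <- tryCatch({
      if (is.character(paths)) read_image(paths[[i]], pixel_size = pixel_size)
      else paths[[i]]
    }, error = function(e) {
      warning("skipping unreadable image ", names_out[i], ": ",
              conditionMessage(e)); NULL
    })
    if (is.null(img)) next
    counts[i] <- tryCatch({
      regions <- segment_cells(img, params)
      if (!is.null(noise_model))
        regions <- apply_noise_filter(regions, img, noise_model)
      region_count(regions)
    }, error = function(e) {
      warning("blank or degenerate field ", names_out[i],
              ": counted as 0 (", conditionMessage(e), ")")
      0
    })
  }
  ok <- !is.na(counts)
  if (!any(ok)) stop("all images failed to count", call. = FALSE)
  est <- estimate_total(mean(counts[ok]), a_total, a_image,
                        n_images = sum(ok),
                        sd_per_image = if (sum(ok) > 1L)
                          stats::sd(counts[ok]) else NA_real_)
  structure(list(counts = data.frame(image = names_out[ok],
                                     count = counts[ok]),
                 estimate = est, params = params),
            class = "CountRun")
}

#' @export
print.CountRun <- function(x, ...) {
  cat(sprintf("<CountRun> %d images, mean %.2f cells/image -> N_total %.0f\n",
              nrow(x$counts), x$estimate$mean_per_image, x$estimate$N_total))
  invisible(x)
}
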