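#' Area of a circular culture dish
#'
#' @param diameter dish diameter in mm.
#' @return Area in mm^2 (`pi * (d/2)^2`); a 35 mm dish gives 962.11 mm^2.
#' @export
dish_area <- function(diameter) {
  if (!is.numeric(diameter) || any(diameter <= 0))
    stop("`diameter` must be positive", call. = FALSE)
  pi * (diameter / 2)^2
}

#' Extrapolate a per-image mean count to the whole culture
#'
#' `N_total = (A_total / A_image) * mean_per_image`: the mean count over
#' fields of view imaged at random locations, scaled by the ratio of
#' substrate area to field area. For a 35 mm dish imaged with a
#' 1.19 x 0.89 mm field the multiplier is 962.11 / 1.06 = 907.65.
#'
#' @param mean_per_image mean cell count per image.
#' @param a_total culture substrate area (mm^2).
#' @param a_image field-of-view area (mm^2).
#' @param n_images,sd_per_image optional sampling metadata carried through.
#' @return A list of class `CultureEstimate`.
#' @export
estimate_total <- function(mean_per_image, a_total = dish_area(35),
                           a_image = 1.19 * 0.89,
                           n_images = NA_integer_, sd_per_image = NA_real_) {
  if (!is.finite(a_total) || !is.finite(a_image) || a_image <= 0 ||
      a_total < a_image)
    stop("areas must satisfy A_total >= A_image > 0", call. = FALSE)
  if (!is.finite(mean_per_image) || mean_per_image < 0)
    stop("`mean_per_image` must be a non-negative number", call. = FALSE)
  structure(list(N_total = a_total / a_image * mean_per_image,
                 A_total = a_total, A_image = a_image,
                 mean_per_image = mean_per_image,
                 n_images = n_images, sd_per_image = sd_per_image),
            class = "CultureEstimate")
}

#' @export
print.CultureEstimate <- function(x, ...) {
  cat(sprintf(
    "<CultureEstimate> N_total %.1f (%.3f x mean %.2f cells/image, n=%s)\n",
    x$N_total, x$A_total / x$A_image, x$mean_per_image,
    ifelse(is.na(x$n_images), "?", x$n_images)))
  invisible(x)
}

#' How many fields of view are enough: running-mean convergence
#'
#' For each `n >= 2`, `delta_c(n)` is the magnitude of the relative change
#' in the running mean count when the n-th image is added, as a percentage
#' of the running mean at n:
#' `|mean(1..n) - mean(1..n-1)| / mean(1..n) * 100`.
#' `recommended_n` is the smallest n from which `delta_c` stays at or below
#' the threshold for every later observed n (so a single lucky dip does not
#' qualify). Returns `NA` with a warning when no n qualifies.
#'
#' @param counts per-image cell counts, in acquisition order.
#' @param threshold_percent stabilisation threshold (default 1.5).
#' @return A list of class `ConvergenceCurve`: `n`, `delta_c`,
#'   `recommended_n`, `threshold_percent`.
#' @export
convergence_analysis <- function(counts, threshold_percent = 1.5) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need at least 2 counts", call. = FALSE)
  means <- cumsum(counts) / seq_along(counts)
  n <- 2:length(counts)
  if (any(means[n] == 0))
    stop("running mean of zero: percentage change undefined", call. = FALSE)
  delta_c <- abs(means[n] - means[n - 1L]) / means[n] * 100
  ok <- rev(cumprod(rev(delta_c <= threshold_percent))) == 1
  rec <- if (any(ok)) n[which(ok)[1L]] else NA_integer_
  if (is.na(rec))
    warning("no n satisfies the stabilisation threshold for all later n")
  structure(list(n = n, delta_c = delta_c, recommended_n = rec,
                 threshold_percent = threshold_percent),
            class = "ConvergenceCurve")
}

#' @export
print.ConvergenceCurve <- function(x, ...) {
  cat(sprintf("<ConvergenceCurve> n=2..%d, recommended n=%s (<= %.2f%%)\n",
              max(x$n), ifelse(is.na(x$recommended_n), "NA", x$recommended_n),
              x$threshold_percent))
  invisible(x)
}

#' Through-origin regression of image counts on reference counts
#'
#' Fits `count_image = gradient * count_reference` by least squares with no
#' intercept; `R^2` is computed against the through-origin model
#' (`1 - SS_res / sum(y^2)`).
#'
#' @param reference reference counts (e.g. manual counts), length >= 2.
#' @param image_counts matching image-analysis counts.
#' @return A list of class `ValidationFit`: `gradient`, `r_squared`,
#'   `count_image`, `count_reference`.
#' @export
validation_regression <- function(reference, image_counts) {
  x <- as.numeric(reference); y <- as.numeric(image_counts)
  if (length(x) < 2L || length(x) != length(y))
    stop("need >= 2 paired counts", call. = FALSE)
  if (all(x == 0)) stop("all reference counts are zero", call. = FALSE)
  gradient <- sum(x * y) / sum(x * x)
  ss_res <- sum((y - gradient * x)^2)
  ss_tot <- sum(y^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(gradient = gradient, r_squared = r2,
                 count_image = y, count_reference = x),
            class = "ValidationFit")
}

#' @export
print.ValidationFit <- function(x, ...) {
  cat(sprintf("<ValidationFit> gradient %.3f, R^2 %.4f (%d pairs)\n",
              x$gradient, x$r_squared, length(x$count_image)))
  invisible(x)
}

#' Growth curve from per-time, per-replicate image counts
#'
#' For each replicate at each time point the per-image counts are averaged
#' and extrapolated with [estimate_total()]; the curve reports the mean and
#' standard deviation of the replicate estimates at each time.
#'
#' @param series data.frame with columns `time` (hours post-seeding),
#'   `replicate`, `count` (one row per image).
#' @param a_total,a_image culture and field areas (mm^2).
#' @return A list of class `GrowthCurve`: `curve` (data.frame `time`,
#'   `mean_total`, `sd_total`, `n_replicates`) and `estimates`
#'   (per time x replicate data.frame).
#' @export
growth_curve <- function(series, a_total = dish_area(35),
                         a_image = 1.19 * 0.89) {
  need <- c("time", "replicate", "count")
  if (!all(need %in% names(series)))
    stop("`series` needs columns time, replicate, count", call. = FALSE)
  if (any(!is.finite(series$time)))
    stop("non-finite time values", call. = FALSE)
  if (any(!is.finite(series$count)))
    stop("empty or non-finite replicate counts", call. = FALSE)
  if (!nrow(series)) stop("empty series", call. = FALSE)

  est <- stats::aggregate(count ~ time + replicate, data = series, FUN = mean)
  est$n_total <- vapply(est$count, function(m)
    estimate_total(m, a_total, a_image)$N_total, numeric(1))
  est <- est[order(est$time, est$replicate), ]

  agg_m <- stats::aggregate(n_total ~ time, data = est, FUN = mean)
  agg_s <- stats::aggregate(n_total ~ time, data = est,
                            FUN = function(v) if (length(v) > 1L)
                              stats::sd(v) else 0)
  agg_n <- stats::aggregate(n_total ~ time, data = est, FUN = length)
  curve <- data.frame(time = agg_m$time, mean_total = agg_m$n_total,
                      sd_total = agg_s$n_total, n_replicates = agg_n$n_total)
  curve <- curve[order(curve$time), ]
  rownames(curve) <- rownames(est) <- NULL
  structure(list(curve = curve, estimates = est), class = "GrowthCurve")
}

#' @export
print.GrowthCurve <- function(x, ...) {
  cat(sprintf("<GrowthCurve> %d time points, %.0f -> %.0f cells\n",
              nrow(x$curve), x$curve$mean_total[1L],
              x$curve$mean_total[nrow(x$curve)]))
  invisible(x)
}

#' Doubling time from a growth curve
#'
#' Least-squares fit of `log2(mean_total)` on time; the doubling time is
#' the reciprocal slope.
#'
#' @param gc a [growth_curve()] result.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(gc) {
  cv <- gc$curve
  if (nrow(cv) < 2L) stop("need >= 2 time points", call. = FALSE)
  if (any(cv$mean_total <= 0)) stop("non-positive totals", call. = FALSE)
  fit <- stats::lm(log2(mean_total) ~ time, data = cv)
  1 / unname(stats::coef(fit)[2L])
}
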