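#' Segmentation parameters
#'
#' The pair of mean-filter radii plus the minimum region area. Defaults are
#' the optimal values found for H400 oral keratinocytes imaged with a x10
#' objective: `r_small = 7`, `r_large = 22`, `min_area = 8`. An alternative
#' published configuration for U2OS osteosarcoma cells is `r_small = 9`,
#' `r_large = 30`.
#'
#' @param r_small small kernel radius (pixels, integer >= 1).
#' @param r_large large kernel radius (pixels, integer > `r_small`).
#' @param min_area minimum region area kept (pixels^2); regions with area
#'   strictly less than this are removed.
#' @return A list of class `SegmentationParams`.
#' @export
segmentation_params <- function(r_small = 7L, r_large = 22L, min_area = 8L) {
  r_small <- as.integer(r_small); r_large <- as.integer(r_large)
  min_area <- as.integer(min_area)
  if (is.na(r_small) || r_small < 1L)
    stop("`r_small` must be an integer >= 1", call. = FALSE)
  if (is.na(r_large) || r_large <= r_small)
    stop("`r_large` must be an integer > r_small", call. = FALSE)
  if (is.na(min_area) || min_area < 1L)
    stop("`min_area` must be an integer >= 1", call. = FALSE)
  structure(list(r_small = r_small, r_large = r_large, min_area = min_area),
            class = "SegmentationParams")
}

as_segmentation_params <- function(p) {
  if (inherits(p, "SegmentationParams")) return(p)
  do.call(segmentation_params, as.list(p))
}

#' Otsu binarisation of a real-valued image
#'
#' The image is linearly rescaled from its (min, max) range onto 256
#' histogram bins; the threshold maximising the between-class variance is
#' found by exhaustive search over bin boundaries, ties broken by the
#' lowest threshold; pixels strictly above the threshold become foreground.
#'
#' @param image an [imagef()] (or [image8()]) with at least two distinct
#'   values.
#' @return A [binary_mask()].
#' @export
otsu_binarize <- function(image) {
  m <- as_plain_matrix(image)
  lo <- min(m); hi <- max(m)
  if (hi <= lo)
    stop("constant image: no Otsu threshold exists", call. = FALSE)
  bins <- pmin(as.integer(floor((m - lo) / (hi - lo) * 256)), 255L)
  t <- otsu_threshold_bins(tabulate(bins + 1L, nbins = 256L))
  binary_mask(matrix(bins > t, nrow(m), ncol(m)),
              pixel_size = pixel_size(image))
}

# Otsu on a 256-bin histogram: returns the bin index t (0-based) maximising
# between-class variance of classes {<= t} vs {> t}; lowest t wins ties.
otsu_threshold_bins <- function(counts) {
  counts <- as.numeric(counts)   # avoid integer overflow in the moments
  n <- sum(counts)
  lv <- 0:255
  w0 <- cumsum(counts)              # class sizes for t = 0..255
  s0 <- cumsum(counts * lv)
  tot <- s0[256L]
  w1 <- n - w0
  ok <- which(w0 > 0 & w1 > 0)      # both classes non-empty
  mu0 <- s0[ok] / w0[ok]
  mu1 <- (tot - s0[ok]) / w1[ok]
  bcv <- w0[ok] * w1[ok] * (mu0 - mu1)^2
  ok[which.max(bcv)] - 1L           # which.max returns the first maximum
}

#' Remove small connected components from a mask
#'
#' Components (8-connectivity) with area strictly less than `min_area` are
#' set to background; all other pixels are preserved exactly.
#'
#' @param mask a [binary_mask()].
#' @param min_area minimum area in pixels.
#' @return A [binary_mask()].
#' @export
remove_small_regions <- function(mask, min_area = 8L) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(binary_mask(lab, pixel_size = pixel_size(mask)))
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- c(FALSE, areas >= min_area)[lab + 1L]
  binary_mask(matrix(keep, nrow(mask), ncol(mask)),
              pixel_size = pixel_size(mask))
}

#' 8-connected component labeling
#'
#' Labels connected foreground components under 8-connectivity (the
#' particle-analysis convention). Built on [EBImage::bwlabel()] (which is
#' 4-connected) followed by a union-find merge of labels that touch
#' diagonally; labels are renumbered contiguously in raster order.
#'
#' @param mask a [binary_mask()] or any matrix (nonzero = foreground).
#' @return Integer label matrix (0 = background).
#' @export
label_components <- function(mask) {
  m <- (as_plain_matrix(mask) > 0) * 1L
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(as.integer(EBImage::bwlabel(m)), h, w)
  n <- max(lab)
  if (n > 1L && h > 1L && w > 1L) {
    # diagonal neighbour label pairs: down-right and down-left
    a <- c(lab[-h, -w], lab[-h, -1L])
    b <- c(lab[-1L, -1L], lab[-1L, -w])
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      pa <- a[sel]; pb <- b[sel]
      for (k in seq_along(pa)) {
        ra <- find(pa[k]); rb <- find(pb[k])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  # contiguous relabeling in first-pixel order
  u <- sort(unique(lab[lab > 0L]))
  if (length(u)) lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Labeled regions of an image
#'
#' Wraps an integer label matrix (0 = background, labels 1..n are
#' 8-connected components) together with per-region pixel index sets and a
#' reference to the source image.
#'
#' @param labels integer label matrix.
#' @param source the originating [image8()] (optional but required by
#'   feature extraction).
#' @param role free-text role marker (`"cell"` or `"nucleus"`).
#' @return A list of class `LabeledRegions` with elements `labels`,
#'   `regions` (list of linear pixel indices per label), `source`, `role`.
#' @export
labeled_regions <- function(labels, source = NULL, role = "cell") {
  lab <- labels
  storage.mode(lab) <- "integer"
  n <- max(lab, 0L)
  regions <- if (n > 0L) split(which(lab > 0L), lab[lab > 0L]) else list()
  names(regions) <- NULL
  structure(list(labels = lab, regions = regions, source = source,
                 role = role,
                 pixel_size = if (!is.null(source)) pixel_size(source)
                              else pixel_size(labels)),
            class = "LabeledRegions")
}

#' @export
print.LabeledRegions <- function(x, ...) {
  cat(sprintf("<LabeledRegions:%s> %d regions in %d x %d px\n",
              x$role, length(x$regions), ncol(x$labels), nrow(x$labels)))
  invisible(x)
}

#' Number of regions
#' @param regions a [labeled_regions()].
#' @return integer count.
#' @export
region_count <- function(regions) length(regions$regions)

#' Segment cells in a phase-contrast image
#'
#' The full localisation workflow: dual mean-filter subtraction, Otsu
#' binarisation of the difference, removal of components smaller than
#' `min_area`, and 8-connected component labeling. The number of labeled
#' regions is the image's cell-count estimate.
#'
#' A blank field of view (constant difference image) makes the Otsu step
#' fail; that error propagates so callers can report a zero count
#' explicitly.
#'
#' @param image an [image8()].
#' @param params a [segmentation_params()].
#' @return A [labeled_regions()] with `role = "cell"`.
#' @export
segment_cells <- function(image, params = segmentation_params()) {
  params <- as_segmentation_params(params)
  diff <- dual_filter_subtract(image, params)
  mask <- otsu_binarize(diff)
  mask <- remove_small_regions(mask, params$min_area)
  out <- labeled_regions(label_components(mask), source = image, role = "cell")
  out$params <- params
  out
}
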