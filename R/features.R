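#' Morphological and greyscale features of one region
#'
#' The standard particle-analysis feature set measured per segmented
#' region: area, perimeter (8-connected boundary walk, diagonal steps
#' weighted sqrt(2)), circularity `4*pi*A/P^2` clamped to 1, maximum and
#' minimum Feret diameters with their ratio, solidity (area over
#' pixel-corner convex-hull area), and greyscale statistics (mean, sd, min,
#' max, median, skewness, kurtosis) measured on the original phase-contrast
#' image inside the region.
#'
#' Feret diameters use rotating calipers on the convex hull of pixel
#' centres plus one pixel, so a single pixel measures 1 x 1 and an
#' axis-aligned w x h block measures exactly max(w,h) x min(w,h).
#'
#' @param region integer vector of linear pixel indices into `source`.
#' @param source the source [image8()].
#' @return Named numeric vector of 14 features.
#' @export
extract_region_features <- function(region, source) {
  if (!length(region)) stop("empty region", call. = FALSE)
  dims <- dim(source)
  if (min(region) < 1L || max(region) > prod(dims))
    stop("region indices out of image bounds", call. = FALSE)
  rc <- arrayInd(region, dims)              # row (y), col (x)
  area <- nrow(rc)

  per <- boundary_perimeter(rc)
  circ <- min(4 * pi * area / per^2, 1)

  fer <- feret_diameters(rc)

  # solidity against the pixel-corner hull (always >= pixel-count area)
  corners <- rbind(cbind(rc[, 2L] - 0.5, rc[, 1L] - 0.5),
                   cbind(rc[, 2L] + 0.5, rc[, 1L] - 0.5),
                   cbind(rc[, 2L] - 0.5, rc[, 1L] + 0.5),
                   cbind(rc[, 2L] + 0.5, rc[, 1L] + 0.5))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  solidity <- min(area / polygon_area(hull), 1)

  g <- as.numeric(as_plain_matrix(source)[region])
  gsd <- if (area > 1L) stats::sd(g) else 0
  gsk <- if (gsd > 0) e1071::skewness(g, type = 2) else 0
  gku <- if (gsd > 0) e1071::kurtosis(g, type = 2) else 0

  c(area = area, perimeter = per, circularity = circ,
    feret_max = fer[1L], feret_min = fer[2L],
    aspect_ratio = fer[1L] / fer[2L], solidity = solidity,
    grey_mean = mean(g), grey_sd = gsd, grey_min = min(g),
    grey_max = max(g), grey_median = stats::median(g),
    grey_skewness = gsk, grey_kurtosis = gku)
}

# Perimeter by Moore-neighbour boundary tracing of the outer contour;
# axis steps count 1, diagonal steps sqrt(2). Single pixel: unit square, 4.
boundary_perimeter <- function(rc) {
  if (nrow(rc) == 1L) return(4)
  r0 <- min(rc[, 1L]) - 1L; c0 <- min(rc[, 2L]) - 1L
  h <- max(rc[, 1L]) - r0 + 2L; w <- max(rc[, 2L]) - c0 + 2L
  m <- matrix(FALSE, h, w)
  m[cbind(rc[, 1L] - r0, rc[, 2L] - c0)] <- TRUE

  # start: topmost of leftmost pixels
  start_c <- min(rc[, 2L] - c0)
  start_r <- min(rc[rc[, 2L] - c0 == start_c, 1L] - r0)
  # Moore neighbourhood, clockwise from W (image rows grow downward)
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  steplen <- ifelse(dr != 0L & dc != 0L, sqrt(2), 1)

  per <- 0
  cr <- start_r; cc <- start_c
  backtrack <- 1L   # came from the W neighbour
  first_dir <- NA_integer_
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((backtrack - 1L + k) %% 8L) + 1L
      nr <- cr + dr[d]; nc <- cc + dc[d]
      if (nr >= 1L && nr <= h && nc >= 1L && nc <= w && m[nr, nc]) {
        if (cr == start_r && cc == start_c) {
          if (!is.na(first_dir) && d == first_dir) return(per)
          if (is.na(first_dir)) first_dir <- d
        }
        per <- per + steplen[d]
        # new backtrack: direction pointing back toward the previous pixel,
        # advanced one position clockwise
        backtrack <- ((d + 4L - 1L + 1L) %% 8L) + 1L
        cr <- nr; cc <- nc
        found <- TRUE
        break
      }
    }
    if (!found) return(max(per, 4))        # isolated pixel reached by trace
    if (per > 8 * (h + w)) return(per)     # safety: cannot loop forever
  }
}

# (feret_max, feret_min) from rotating calipers on pixel-centre hull, + 1 px
feret_diameters <- function(rc) {
  pts <- unique(cbind(rc[, 2L], rc[, 1L]))   # (x, y)
  if (nrow(pts) == 1L) return(c(1, 1))
  hi <- grDevices::chull(pts)
  hull <- pts[hi, , drop = FALSE]
  n <- nrow(hull)
  if (n == 2L) {
    d <- sqrt(sum((hull[1L, ] - hull[2L, ])^2))
    return(c(d + 1, 1))
  }
  # max caliper: max pairwise distance over hull vertices
  dmax <- max(stats::dist(hull))
  # min caliper: min over hull edges of the max vertex distance to the edge
  wmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2L], e[1L]) / len
    dists <- abs((hull[, 1L] - hull[i, 1L]) * nrm[1L] +
                 (hull[, 2L] - hull[i, 2L]) * nrm[2L])
    wmin <- min(wmin, max(dists))
  }
  c(dmax + 1, wmin + 1)
}

# shoelace area of a polygon given as an ordered vertex matrix (x, y)
polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])) / 2
}

#' Feature table for all regions of a segmentation
#'
#' @param regions a [labeled_regions()] whose `source` is set.
#' @param source optional [image8()] overriding `regions$source`.
#' @return data.frame with one row per region (column `region` = label id,
#'   then the 14 features of [extract_region_features()]).
#' @export
region_feature_table <- function(regions, source = NULL) {
  src <- if (is.null(source)) regions$source else source
  if (is.null(src)) stop("no source image available", call. = FALSE)
  n <- length(regions$regions)
  if (n == 0L) {
    ft <- as.data.frame(as.list(stats::setNames(numeric(14),
            names(extract_region_features(1L, image8(matrix(0L, 2, 2)))))))
    return(cbind(region = integer(), ft[0, , drop = FALSE]))
  }
  rows <- t(vapply(regions$regions,
                   function(px) extract_region_features(px, src),
                   numeric(14)))
  data.frame(region = seq_len(n), rows)
}
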