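# Brute-force oracles kept deliberately independent of the package
# implementations they check.

# O(N k^2) disk mean filter with edge replication
brute_mean_filter <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    s <- 0; n <- 0L
    for (dy in -r:r) for (dx in -r:r) {
      if (dx^2 + dy^2 > r^2) next
      yy <- min(max(y + dy, 1L), h)
      xx <- min(max(x + dx, 1L), w)
      s <- s + m[yy, xx]; n <- n + 1L
    }
    out[y, x] <- s / n
  }
  out
}

# exhaustive-search Otsu on a 256-bin histogram (independent formulation:
# minimises within-class variance instead of maximising between-class)
brute_otsu_bin <- function(counts) {
  counts <- as.numeric(counts)
  lv <- 0:255
  best_t <- NA_integer_; best_w <- Inf
  for (t in 0:254) {
    c0 <- counts[1:(t + 1)]; c1 <- counts[(t + 2):256]
    n0 <- sum(c0); n1 <- sum(c1)
    if (n0 == 0 || n1 == 0) next
    v0 <- sum(c0 * (lv[1:(t + 1)] - sum(c0 * lv[1:(t + 1)]) / n0)^2)
    v1 <- sum(c1 * (lv[(t + 2):256] - sum(c1 * lv[(t + 2):256]) / n1)^2)
    wcv <- v0 + v1
    if (wcv < best_w - 1e-9) { best_w <- wcv; best_t <- t }
  }
  best_t
}

# RCC5 by direct set comparison on sorted unique index vectors
brute_rcc5 <- function(x, y) {
  x <- sort(unique(x)); y <- sort(unique(y))
  inter <- intersect(x, y)
  if (length(inter) == 0L) return("DR")
  if (identical(x, y)) return("EQ")
  if (identical(inter, x)) return("PP")
  if (identical(inter, y)) return("PPi")
  "PO"
}

# rotate-and-measure Feret oracle on pixel centres (+1 px), 360 angles
brute_feret <- function(rc) {
  pts <- cbind(rc[, 2L], rc[, 1L])
  if (nrow(pts) == 1L) return(c(1, 1))
  ang <- seq(0, pi, length.out = 361L)[-361L]
  widths <- vapply(ang, function(a) {
    p <- pts[, 1L] * cos(a) + pts[, 2L] * sin(a)
    max(p) - min(p)
  }, numeric(1))
  c(max(widths) + 1, min(widths) + 1)
}

# small, easily segmented scene: bright cells, no flats/mottle/debris/texture
easy_spec <- function(n_cells = 12L, seed = 1L, width = 300L, height = 220L,
                      cell_radius_mean = 10, ...) {
  args <- list(width = width, height = height, n_cells = n_cells,
               cell_radius_mean = cell_radius_mean, cell_radius_sd = 0.5,
               halo_width = 3, background_noise_sd = 5, mottle_amplitude = 0,
               texture_contrast = 0, n_noise_blobs = 0L, n_debris = 0L,
               flat_fraction = 0, halo_gap_fraction = 0.25,
               colony_fraction = 0, contrast_range = c(1, 1),
               min_center_spacing = 2 * (cell_radius_mean + 5) + 2,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_spec, args)
}

# matched radii for easy_spec cells (R = 10, halo 3)
easy_params <- function() segmentation_params(3L, 14L, 8L)

# strip image classes/attributes for exact matrix comparison
as_plain <- function(x) {
  m <- unclass(x)
  attr(m, "pixel_size") <- NULL
  m
}
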