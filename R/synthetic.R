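#' Specification of a synthetic phase-contrast scene
#'
#' Describes a field of nonoverlapping epithelial-like cells as the
#' segmentation model assumes them: on a mid-grey background each cell is a
#' dark interior disc ringed by a bright halo annulus (the phase-contrast
#' edge artifact), with optional small bright/dark noise blobs, plus a
#' paired fluorescence channel holding one bright nucleus disc strictly
#' inside each cell. Defaults mirror the imaging scale the method was
#' developed at (x10 objective): cell radius about 13 px with a 3 px halo,
#' nuclei at half the cell radius, an 800 x 600 px field.
#'
#' @param width,height field size in pixels.
#' @param n_cells number of cells to place.
#' @param cell_radius_mean,cell_radius_sd cell radius distribution (px).
#' @param halo_width halo annulus width (px).
#' @param halo_brightness,interior_darkness intensity offsets from the
#'   background (positive numbers; the interior is darkened). These are the
#'   offsets of the strongest cells; each cell draws a contrast factor from
#'   `contrast_range`, emulating the brightness spread of real cultures
#'   (thin spread cells image much fainter than rounded ones).
#' @param contrast_range per-cell multiplicative contrast factor range
#'   `c(min, max)` applied to both halo and interior offsets; factors are
#'   drawn skewed toward the faint end (`min + (max-min) * u^1.7`,
#'   `u ~ U(0,1)`), since spread cells at interphase dominate a culture and
#'   image faintly while rounded mitotic or freshly seeded cells are rare
#'   and bright.
#' @param halo_gap_fraction fraction of each cell's halo perimeter left
#'   unrendered as one randomly oriented arc per cell; additionally, cells
#'   placed in contact by colony growth lose their halos over the arc facing
#'   the contact partner (phase gradients vanish at shared membranes).
#'   0 draws complete rings.
#' @param flat_fraction fraction of cells rendered "flat": thinly spread
#'   cells with no halo, subdued texture and a soft edge (their darkness
#'   ramps up over roughly half the radius instead of stepping). They are
#'   visible only as diffuse dark patches, so only a large radius spanning
#'   the whole cell converts them into positive contrast; small radii see
#'   neither a halo nor a sharp edge to respond to.
#' @param background_level background grey level.
#' @param background_noise_sd Gaussian pixel noise sd.
#' @param mottle_amplitude amplitude of smooth large-scale background
#'   mottle (uneven illumination, condensation, out-of-focus debris),
#'   rendered as broad Gaussian bumps tens of pixels across. The mean-filter
#'   difference responds to such structure increasingly with kernel radius,
#'   which is what penalises needlessly large radii on real images.
#' @param texture_contrast intensity amplitude of intracellular speckle
#'   (small bright/dark organelle-scale spots rendered inside every cell;
#'   the fine detail the small filter radius exists to smooth away). Set to
#'   0 for optically flat cells.
#' @param texture_spot_radius speckle spot radius (px).
#' @param n_noise_blobs number of spurious bright/dark blobs.
#' @param n_debris number of large soft dark debris clumps (dead cells,
#'   detached material about 1.5x a cell across) attached to colony edges.
#'   A mean-filter pair only converts such a clump into positive contrast
#'   once the large kernel exceeds the clump, at which point its response
#'   merges with the neighbouring cell's; keeping the large radius near the
#'   cell size avoids this. Default scales with the cell count.
#' @param noise_blob_area_range blob area range (px^2), `c(min, max)`.
#' @param nucleus_radius_fraction nucleus radius / cell radius, in (0, 1).
#' @param min_center_spacing minimum distance between cell centres (px);
#'   default lets neighbouring cell bodies just touch.
#' @param colony_fraction probability that each cell after the first is
#'   placed adjacent to an existing cell (at 1-1.2x the minimum spacing)
#'   rather than uniformly at random, emulating colony growth of epithelial
#'   cultures.
#' @param seed RNG seed driving all randomness of the scene.
#' @return A list of class `SceneSpec`.
#' @export
scene_spec <- function(width = 800L, height = 600L, n_cells = 50L,
                       cell_radius_mean = 13, cell_radius_sd = 1.5,
                       halo_width = 3, halo_brightness = 60,
                       interior_darkness = 45, background_level = 128,
                       background_noise_sd = 8, mottle_amplitude = 16,
                       texture_contrast = 40,
                       texture_spot_radius = 3, n_noise_blobs = 0L,
                       n_debris = NULL,
                       noise_blob_area_range = c(9, 40),
                       nucleus_radius_fraction = 0.5,
                       contrast_range = c(0.55, 1), halo_gap_fraction = 0.35,
                       flat_fraction = 0.4, colony_fraction = 0.85,
                       min_center_spacing = NULL, seed = 1L) {
  if (is.null(min_center_spacing))
    min_center_spacing <- 2 * cell_radius_mean + 1
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_cells = as.integer(n_cells),
               cell_radius_mean = cell_radius_mean,
               cell_radius_sd = cell_radius_sd, halo_width = halo_width,
               halo_brightness = halo_brightness,
               interior_darkness = interior_darkness,
               background_level = background_level,
               background_noise_sd = background_noise_sd,
               mottle_amplitude = mottle_amplitude,
               texture_contrast = texture_contrast,
               texture_spot_radius = texture_spot_radius,
               n_noise_blobs = as.integer(n_noise_blobs),
               n_debris = if (is.null(n_debris))
                 max(2L, as.integer(round(n_cells / 10)))
               else as.integer(n_debris),
               noise_blob_area_range = noise_blob_area_range,
               nucleus_radius_fraction = nucleus_radius_fraction,
               contrast_range = contrast_range,
               halo_gap_fraction = halo_gap_fraction,
               flat_fraction = flat_fraction,
               colony_fraction = colony_fraction,
               min_center_spacing = min_center_spacing,
               seed = as.integer(seed))
  stopifnot(spec$width >= 1L, spec$height >= 1L, spec$n_cells >= 0L,
            spec$cell_radius_mean > 0, spec$halo_width >= 0,
            spec$nucleus_radius_fraction > 0,
            spec$nucleus_radius_fraction < 1,
            spec$min_center_spacing >= 0)
  structure(spec, class = "SceneSpec")
}

#' Generate a paired phase-contrast / nuclei scene with ground truth
#'
#' Cells are placed by rejection sampling under the minimum centre spacing
#' (nonoverlapping monolayer); the phase-contrast channel renders each cell
#' as a darkened interior disc with a raised halo annulus over a noisy
#' background, plus any spurious blobs; the fluorescence channel renders
#' one bright nucleus disc per cell, strictly inside the cell, so
#' PP(nucleus, cell) holds by construction. All randomness comes from
#' `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return A list of class `SyntheticScene`: `pc` and `fluor` ([image8()]),
#'   and `truth` (cell `centers` matrix (x, y), `radii`, `nucleus_radii`,
#'   `nuclei` label matrix, `noise_mask`, `true_count`).
#' @export
generate_scene <- function(spec = scene_spec()) {
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)

  w <- spec$width; h <- spec$height
  margin <- spec$cell_radius_mean + 4 * spec$cell_radius_sd +
            spec$halo_width + 1
  if (spec$n_cells > 0L && (w <= 2 * margin || h <= 2 * margin))
    stop("field too small for the requested cell size", call. = FALSE)

  # --- placement by rejection sampling
  centers <- matrix(numeric(0), 0L, 2L)
  radii <- numeric(0)
  anchors <- integer(0)               # colony contact partner (0 = none)
  tries <- 0L; cap <- 400L * max(spec$n_cells, 1L)
  while (nrow(centers) < spec$n_cells) {
    tries <- tries + 1L
    if (tries > cap)
      stop("infeasible packing: could not place ", spec$n_cells,
           " cells at spacing ", spec$min_center_spacing, call. = FALSE)
    anchor_i <- 0L
    if (nrow(centers) > 0L && stats::runif(1) < spec$colony_fraction) {
      # colony growth: bud off an existing cell at just over minimum spacing
      anchor_i <- sample.int(nrow(centers), 1L)
      anchor <- centers[anchor_i, ]
      ang <- stats::runif(1, 0, 2 * pi)
      dist <- spec$min_center_spacing * stats::runif(1, 1, 1.12)
      cx <- min(max(anchor[1L] + dist * cos(ang), margin), w - margin)
      cy <- min(max(anchor[2L] + dist * sin(ang), margin), h - margin)
    } else {
      cx <- stats::runif(1, margin, w - margin)
      cy <- stats::runif(1, margin, h - margin)
    }
    if (nrow(centers) == 0L ||
        min(sqrt((centers[, 1L] - cx)^2 + (centers[, 2L] - cy)^2)) >=
        spec$min_center_spacing) {
      r <- max(3, stats::rnorm(1, spec$cell_radius_mean, spec$cell_radius_sd))
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
      anchors <- c(anchors, anchor_i)
    }
  }

  # halo gap arcs: one random arc per cell plus mutual arcs at colony
  # contacts (cells touching an anchor lose the halo facing it, and the
  # anchor loses the halo facing them)
  gap_arcs <- rep(list(matrix(numeric(0), 0L, 2L)), max(nrow(centers), 1L))
  add_arc <- function(i, center_ang, width) {
    gap_arcs[[i]] <<- rbind(gap_arcs[[i]], c(center_ang %% (2 * pi), width))
  }
  if (spec$halo_gap_fraction > 0 && nrow(centers) > 0L) {
    gapw <- spec$halo_gap_fraction * 2 * pi
    for (i in seq_len(nrow(centers))) {
      add_arc(i, stats::runif(1, 0, 2 * pi), gapw)
      j <- anchors[i]
      if (j > 0L) {
        ang_ij <- atan2(centers[j, 2L] - centers[i, 2L],
                        centers[j, 1L] - centers[i, 1L])
        add_arc(i, ang_ij, gapw)
        add_arc(j, ang_ij + pi, gapw)
      }
    }
  }

  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)

  pc <- matrix(spec$background_level, h, w) +
        if (spec$background_noise_sd > 0)
          matrix(stats::rnorm(h * w, 0, spec$background_noise_sd), h, w)
        else 0
  fluor <- matrix(8, h, w) +
           if (spec$background_noise_sd > 0)
             matrix(stats::rnorm(h * w, 0, min(spec$background_noise_sd, 3)),
                    h, w)
           else 0
  # smooth background mottle: broad gaussian bumps across the field
  if (spec$mottle_amplitude > 0) {
    n_mottle <- max(3L, round(w * h / 12000))
    for (k in seq_len(n_mottle)) {
      mx <- stats::runif(1, 1, w); my <- stats::runif(1, 1, h)
      sg <- stats::runif(1, 10, 25)
      amp <- sample(c(-1, 1), 1L) * stats::runif(1, 0.5, 1) *
             spec$mottle_amplitude
      pc <- pc + amp * exp(-((xg - mx)^2 + (yg - my)^2) / (2 * sg^2))
    }
  }

  # large soft debris clumps attached to colony edges
  debris_mask <- matrix(0L, h, w)
  if (spec$n_debris > 0L && nrow(centers) > 0L) {
    for (k in seq_len(spec$n_debris)) {
      j <- sample.int(nrow(centers), 1L)
      rd <- stats::runif(1, 1.5, 1.9) * spec$cell_radius_mean
      ang <- stats::runif(1, 0, 2 * pi)
      dx <- centers[j, 1L] + (radii[j] + 0.85 * rd) * cos(ang)
      dy <- centers[j, 2L] + (radii[j] + 0.85 * rd) * sin(ang)
      dxc <- min(max(dx, 2), w - 1); dyc <- min(max(dy, 2), h - 1)
      dd <- sqrt((xg - dxc)^2 + (yg - dyc)^2)
      depth <- pmin(pmax((rd - dd) / (0.65 * rd), 0), 1)
      pc <- pc - stats::runif(1, 0.8, 1) * spec$interior_darkness * depth
      debris_mask[dd <= rd] <- 1L
      # the clump obscures the halo of the cell it leans on
      arc <- atan2(dyc - centers[j, 2L], dxc - centers[j, 1L])
      gap_arcs[[j]] <- rbind(gap_arcs[[j]], c(arc %% (2 * pi), pi / 2))
    }
  }


  nuclei <- matrix(0L, h, w)
  nuc_radii <- numeric(nrow(centers))

  for (i in seq_len(nrow(centers))) {
    d2 <- (xg - centers[i, 1L])^2 + (yg - centers[i, 2L])^2
    r <- radii[i]
    ctr <- spec$contrast_range[1L] +
           diff(spec$contrast_range) * stats::runif(1)^1.7
    # interleaved deterministic share so every scene carries the stated
    # proportion of flat cells (placement order is already random)
    flat <- floor(i * spec$flat_fraction) >
            floor((i - 1) * spec$flat_fraction)
    interior <- d2 <= r^2
    if (flat) {
      # soft dark patch: darkest core fading over ~70% of the radius, so
      # there is no sharp rim for a band-pass filter pair to respond to;
      # spread cells also image fainter overall than rounded ones
      depth <- pmin(pmax((r - sqrt(d2[interior])) / (0.7 * r), 0), 1)
      pc[interior] <- pc[interior] - ctr * spec$interior_darkness * depth
    } else {
      halo <- d2 > r^2 & d2 <= (r + spec$halo_width)^2
      arcs <- gap_arcs[[i]]
      if (nrow(arcs) && any(halo)) {
        ang <- atan2(yg[halo] - centers[i, 2L], xg[halo] - centers[i, 1L])
        keep <- rep(TRUE, sum(halo))
        for (a in seq_len(nrow(arcs)))
          keep <- keep &
            !(((ang - (arcs[a, 1L] - arcs[a, 2L] / 2)) %% (2 * pi)) <
              arcs[a, 2L])
        halo[halo] <- keep
      }
      pc[interior] <- pc[interior] - ctr * spec$interior_darkness
      pc[halo] <- pc[halo] + ctr * spec$halo_brightness
    }
    rn <- max(2, spec$nucleus_radius_fraction * r)
    nuc_radii[i] <- rn
    nd <- d2 <= rn^2
    fluor[nd] <- 200
    nuclei[nd] <- i

    # intracellular speckle: organelle-scale spots the small filter smooths
    if (spec$texture_contrast > 0) {
      n_spots <- max(1L, round(pi * r^2 / 35))
      spot_r <- stats::runif(n_spots, 0.6, 1.5) * spec$texture_spot_radius
      rin <- pmax(r - spot_r - 1, 1)
      rho <- rin * sqrt(stats::runif(n_spots))
      th <- stats::runif(n_spots, 0, 2 * pi)
      amp <- sample(c(-1, 1), n_spots, replace = TRUE) *
             ctr * spec$texture_contrast * (if (flat) 0.15 else 1)
      for (k in seq_len(n_spots)) {
        sx <- centers[i, 1L] + rho[k] * cos(th[k])
        sy <- centers[i, 2L] + rho[k] * sin(th[k])
        sp <- (xg - sx)^2 + (yg - sy)^2 <= spot_r[k]^2
        pc[sp] <- pc[sp] + amp[k]
      }
    }
  }

  noise_mask <- matrix(0L, h, w)
  placed <- 0L; tries <- 0L
  clearance <- max(radii, 0) + spec$halo_width
  while (placed < spec$n_noise_blobs && tries < 400L * spec$n_noise_blobs) {
    tries <- tries + 1L
    a <- stats::runif(1, spec$noise_blob_area_range[1L],
                      spec$noise_blob_area_range[2L])
    rb <- sqrt(a / pi)
    bx <- stats::runif(1, rb + 1, w - rb - 1)
    by <- stats::runif(1, rb + 1, h - rb - 1)
    if (nrow(centers) > 0L &&
        min(sqrt((centers[, 1L] - bx)^2 + (centers[, 2L] - by)^2)) <
        clearance + rb + 2) next
    d2 <- (xg - bx)^2 + (yg - by)^2
    blob <- d2 <= rb^2
    sign <- if (stats::runif(1) < 0.5) 1 else -1
    pc[blob] <- pc[blob] + sign * spec$halo_brightness
    noise_mask[blob] <- 1L
    placed <- placed + 1L
  }

  pc8 <- image8(pmin(pmax(round(pc), 0), 255))
  fl8 <- image8(pmin(pmax(round(fluor), 0), 255))
  structure(list(
    pc = pc8, fluor = fl8,
    truth = list(centers = centers, radii = radii,
                 nucleus_radii = nuc_radii, nuclei = nuclei,
                 noise_mask = noise_mask, debris_mask = debris_mask,
                 true_count = nrow(centers)),
    spec = spec
  ), class = "SyntheticScene")
}

#' Ground-truth nuclei as labeled regions
#' @param scene a [generate_scene()] result.
#' @return A [labeled_regions()] with `role = "nucleus"`.
#' @export
truth_nuclei <- function(scene) {
  labeled_regions(scene$truth$nuclei, source = scene$fluor, role = "nucleus")
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic growth experiment
#'
#' Emulates a longitudinal imaging experiment: the expected number of cells
#' per field grows exponentially as `n_cells * 2^(t / doubling_time)`, each
#' image's cell count is Poisson-distributed around the expectation
#' (truncated to packing feasibility), and every (time, replicate, image)
#' triple is rendered with [generate_scene()] under a seed derived from
#' `seed`. When `out_dir` is given the TIFF pairs and a YAML manifest are
#' written; otherwise scenes are returned in memory.
#'
#' @param doubling_time doubling time in hours.
#' @param times imaging times (hours post-seeding), strictly increasing.
#' @param replicates number of replicate cultures.
#' @param images_per_timepoint fields of view per culture per time.
#' @param base_spec a [scene_spec()]; its `n_cells` is the expected count
#'   per field at t = 0 (default 3, so a 48-98 h window at a 24 h doubling
#'   time spans roughly 12-50 cells per field).
#' @param seed master seed.
#' @param out_dir optional directory for TIFFs plus `manifest.yaml`.
#' @return A list of class `SyntheticExperiment`: `manifest` (data.frame
#'   `time`, `replicate`, `image`, `true_count`, and paths if written) and
#'   `scenes` (list, `NULL` entries when written to disk).
#' @export
generate_experiment <- function(doubling_time = 24, times = c(48, 64, 81, 98),
                                replicates = 2L, images_per_timepoint = 11L,
                                base_spec = scene_spec(n_cells = 3L), seed = 1L,
                                out_dir = NULL) {
  if (doubling_time <= 0) stop("`doubling_time` must be positive", call. = FALSE)
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  rows <- list(); scenes <- list(); k <- 0L
  for (t in times) for (rep_i in seq_len(replicates)) {
    expected <- base_spec$n_cells * 2^(t / doubling_time)
    for (im in seq_len(images_per_timepoint)) {
      k <- k + 1L
      n <- stats::rpois(1L, expected)
      sub_seed <- (seed * 10000L + k * 7L) %% .Machine$integer.max
      spec_k <- base_spec
      spec_k$n_cells <- n
      spec_k$seed <- as.integer(sub_seed)
      scene <- tryCatch(generate_scene(spec_k), error = function(e)
        stop("field overcrowded at t=", t, " (", n, " cells); ",
             "shrink cells or the expected count: ", conditionMessage(e),
             call. = FALSE))
      row <- data.frame(time = t, replicate = rep_i, image = im,
                        true_count = scene$truth$true_count)
      if (!is.null(out_dir)) {
        base <- sprintf("t%03d_r%d_i%02d", as.integer(t), rep_i, im)
        row$pc_path <- file.path(out_dir, paste0(base, "_pc.tif"))
        row$fluor_path <- file.path(out_dir, paste0(base, "_fluor.tif"))
        write_image(scene$pc, row$pc_path)
        write_image(scene$fluor, row$fluor_path)
        scenes[k] <- list(NULL)
      } else {
        scenes[[k]] <- scene
      }
      rows[[k]] <- row
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    yaml::write_yaml(list(doubling_time = doubling_time,
                          times = as.numeric(times),
                          replicates = as.integer(replicates),
                          images_per_timepoint = as.integer(images_per_timepoint),
                          seed = as.integer(seed),
                          images = lapply(seq_len(nrow(manifest)), function(i)
                            as.list(manifest[i, ]))),
                     file.path(out_dir, "manifest.yaml"))
  }
  structure(list(manifest = manifest, scenes = scenes,
                 doubling_time = doubling_time),
            class = "SyntheticExperiment")
}
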