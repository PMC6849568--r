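test_that("scene generation is deterministic and honours the spec", {
  spec <- scene_spec(width = 300, height = 220, n_cells = 15,
                     n_noise_blobs = 4, seed = 42)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(as_plain(a$pc), as_plain(b$pc))
  expect_identical(as_plain(a$fluor), as_plain(b$fluor))
  expect_equal(a$truth$true_count, 15)
  expect_equal(max(a$truth$nuclei), 15)
  expect_equal(region_count(truth_nuclei(a)), 15)

  # empty scene with no structure and no noise is constant background
  flat <- generate_scene(scene_spec(n_cells = 0, n_noise_blobs = 0,
                                    n_debris = 0, mottle_amplitude = 0,
                                    background_noise_sd = 0,
                                    width = 60, height = 50,
                                    background_level = 77, seed = 1))
  expect_true(all(as_plain(flat$pc) == 77))
})

test_that("nuclei are proper parts of their cells by construction", {
  sc <- generate_scene(scene_spec(width = 300, height = 220, n_cells = 12,
                                  seed = 3))
  for (i in seq_len(12)) {
    nuc_px <- which(sc$truth$nuclei == i)
    ctr <- sc$truth$centers[i, ]
    rc <- arrayInd(nuc_px, dim(sc$truth$nuclei))
    d <- sqrt((rc[, 2] - ctr[1])^2 + (rc[, 1] - ctr[2])^2)
    expect_lt(max(d), sc$truth$radii[i])   # strictly inside the cell disc
  }
  # perfect cell masks vs generated nuclei give a perfect detection rate
  xg <- matrix(seq_len(300), 220, 300, byrow = TRUE)
  yg <- matrix(seq_len(220), 220, 300)
  cells <- matrix(0L, 220, 300)
  for (i in seq_len(12))
    cells[(xg - sc$truth$centers[i, 1])^2 +
          (yg - sc$truth$centers[i, 2])^2 <= sc$truth$radii[i]^2] <- i
  rep <- classify_detections(
    labeled_regions(cells, source = sc$pc),
    truth_nuclei(sc))
  expect_equal(rep$correct_detection_rate, 1)
})

test_that("matched radii recover the true count within 5% on average", {
  err <- vapply(1:20, function(s) {
    sc <- generate_scene(easy_spec(n_cells = 14L, seed = 100 + s))
    n <- region_count(segment_cells(sc$pc, easy_params()))
    abs(n - 14) / 14
  }, numeric(1))
  expect_lte(mean(err), 0.05)
})

test_that("infeasible packing fails with a clear error", {
  expect_error(generate_scene(scene_spec(width = 100, height = 100,
                                         n_cells = 200, seed = 1)),
               "packing|too small")
})

test_that("experiments scale expected counts with the growth model", {
  ex <- generate_experiment(doubling_time = 24, times = c(0, 24),
                            replicates = 1L, images_per_timepoint = 30L,
                            base_spec = scene_spec(width = 240, height = 180,
                                                   n_cells = 4L),
                            seed = 5)
  m <- tapply(ex$manifest$true_count, ex$manifest$time, mean)
  expect_equal(unname(m[2] / m[1]), 2, tolerance = 0.35)  # Poisson noise
  expect_equal(nrow(ex$manifest), 60)

  ex2 <- generate_experiment(times = c(48, 60), replicates = 2L,
                             images_per_timepoint = 11L,
                             base_spec = scene_spec(width = 240, height = 180,
                                                    n_cells = 2L),
                             seed = 6)
  expect_equal(sum(ex2$manifest$time == 48), 22)  # 2 replicates x 11 images
  expect_error(generate_experiment(times = c(10, 5)), "increasing")
  expect_error(generate_experiment(doubling_time = -2), "positive")
})

test_that("written experiments produce a consumable manifest", {
  dir <- withr::local_tempdir()
  ex <- generate_experiment(doubling_time = 24, times = c(48, 72),
                            replicates = 1L, images_per_timepoint = 2L,
                            base_spec = scene_spec(width = 200, height = 150,
                                                   n_cells = 2L),
                            seed = 9, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(length(man$images), 4)
  expect_true(all(file.exists(ex$manifest$pc_path)))
  img <- read_image(ex$manifest$pc_path[1])
  expect_equal(dim(img), c(150L, 200L))
})
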