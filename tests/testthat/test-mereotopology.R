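test_that("RCC5 relations on explicit pixel sets", {
  s <- 1:10
  expect_equal(rcc5_relation(s, s), "EQ")
  expect_equal(rcc5_relation(2:4, 1:10), "PP")    # nucleus inside cell
  expect_equal(rcc5_relation(1:10, 2:4), "PPi")
  expect_equal(rcc5_relation(8:12, 1:10), "PO")   # straddles the boundary
  expect_equal(rcc5_relation(11:12, 1:10), "DR")
  expect_error(rcc5_relation(integer(), 1:3), "non-empty")
})

test_that("RCC5 matches exhaustive set comparison on all 3x3 subset pairs", {
  cells <- 1:9
  subsets <- lapply(1:511, function(b) cells[bitwAnd(b, 2^(0:8)) > 0])
  set.seed(99)
  idx <- expand.grid(a = 1:511, b = 1:511)
  # full exhaustive comparison via the bitmask oracle
  pop <- vapply(1:511, function(b) sum(bitwAnd(b, 2^(0:8)) > 0), numeric(1))
  inter <- matrix(0L, 511, 511)
  for (a in 1:511) inter[a, ] <- vapply(1:511, function(b)
    sum(bitwAnd(bitwAnd(a, b), 2^(0:8)) > 0), numeric(1))
  oracle <- matrix("", 511, 511)
  for (a in 1:511) for (b in 1:511)
    oracle[a, b] <- pccount:::rcc5_from_counts(pop[a], pop[b], inter[a, b])
  # spot-verify the count-based path against direct set comparison
  sub_idx <- cbind(sample(511, 400, TRUE), sample(511, 400, TRUE))
  for (k in seq_len(nrow(sub_idx))) {
    a <- sub_idx[k, 1]; b <- sub_idx[k, 2]
    expect_equal(rcc5_relation(subsets[[a]], subsets[[b]]), oracle[a, b])
    expect_equal(brute_rcc5(subsets[[a]], subsets[[b]]), oracle[a, b])
  }
  # symmetry / antisymmetry over the full table
  expect_true(all((oracle == "PP") == t(oracle == "PPi")))
  for (rel in c("DR", "PO", "EQ"))
    expect_true(all((oracle == rel) == t(oracle == rel)))
})

make_regions <- function(mat, role = "cell")
  labeled_regions(mat, source = image8(matrix(100L, nrow(mat), ncol(mat))),
                  role = role)

test_that("detection taxonomy covers the canonical cases", {
  # 1 nucleus strictly inside 1 region
  cells <- matrix(0L, 12, 12); cells[3:9, 3:9] <- 1L
  nucs <- matrix(0L, 12, 12); nucs[5:7, 5:7] <- 1L
  rep <- classify_detections(make_regions(cells), make_regions(nucs, "nucleus"))
  expect_equal(rep$counts$correct_cell, 1)
  expect_equal(rep$correct_detection_rate, 1)
  expect_equal(unname(rep$pair_relations$relation), "PP")

  # one region covering two nuclei -> merged
  nucs2 <- matrix(0L, 12, 12); nucs2[4:5, 4:5] <- 1L; nucs2[7:8, 7:8] <- 2L
  rep2 <- classify_detections(make_regions(cells), make_regions(nucs2, "nucleus"))
  expect_equal(rep2$counts$merged, 1)
  expect_equal(rep2$counts$in_merged, 2)
  expect_equal(rep2$correct_detection_rate, 0)

  # 3 nuclei: 2 correct, 1 missed, plus 1 nucleus-free region
  cells3 <- matrix(0L, 20, 20)
  cells3[2:5, 2:5] <- 1L; cells3[10:13, 10:13] <- 2L; cells3[16:19, 2:5] <- 3L
  nucs3 <- matrix(0L, 20, 20)
  nucs3[3:4, 3:4] <- 1L; nucs3[11:12, 11:12] <- 2L; nucs3[3:4, 16:17] <- 3L
  rep3 <- classify_detections(make_regions(cells3), make_regions(nucs3, "nucleus"))
  expect_equal(rep3$correct_detection_rate, 2 / 3)
  expect_equal(rep3$counts$noise, 1)
  expect_equal(rep3$counts$missed, 1)

  # one nucleus split over two regions
  cells4 <- matrix(0L, 12, 12); cells4[3:5, 3:8] <- 1L; cells4[7:9, 3:8] <- 2L
  nucs4 <- matrix(0L, 12, 12); nucs4[4:8, 5:6] <- 1L
  rep4 <- classify_detections(make_regions(cells4), make_regions(nucs4, "nucleus"))
  expect_equal(rep4$counts$split, 2)
  expect_equal(rep4$counts$in_split, 1)

  # region strictly inside the nucleus -> PPi, kept out of correct counts
  cells5 <- matrix(0L, 12, 12); cells5[5:6, 5:6] <- 1L
  nucs5 <- matrix(0L, 12, 12); nucs5[3:9, 3:9] <- 1L
  rep5 <- classify_detections(make_regions(cells5), make_regions(nucs5, "nucleus"))
  expect_equal(rep5$counts$ppi, 1)
  expect_equal(rep5$counts$in_ppi, 1)
  expect_equal(rep5$correct_detection_rate, 0)

  expect_error(classify_detections(make_regions(cells),
                                   make_regions(matrix(0L, 5, 5), "nucleus")),
               "geometry")
})

test_that("category sums always equal the totals on random scenes", {
  for (s in 1:8) {
    set.seed(s)
    cells <- label_components(binary_mask(matrix(rbinom(900, 1, 0.35), 30, 30)))
    nucs <- label_components(binary_mask(matrix(rbinom(900, 1, 0.2), 30, 30)))
    rep <- classify_detections(make_regions(cells), make_regions(nucs, "nucleus"))
    ct <- rep$counts
    expect_equal(ct$correct_cell + ct$merged + ct$split + ct$noise + ct$ppi,
                 rep$n_regions)
    expect_equal(ct$detected + ct$missed + ct$in_merged + ct$in_split +
                 ct$in_ppi, rep$n_nuclei)
    expect_equal(ct$detected, ct$correct_cell)   # bijection
    expect_gte(rep$correct_detection_rate, 0)
    expect_lte(rep$correct_detection_rate, 1)
  }
})

test_that("error contributions reproduce the published worked example", {
  rep <- list(counts = list(correct_cell = 1175L, noise = 280L, split = 0L,
                            in_split = 0L, merged = 0L, in_merged = 0L,
                            missed = 0L))
  class(rep) <- "DetectionReport"
  contrib <- error_contributions(rep)
  expect_equal(round(contrib[["noise"]]), 24)     # 280 / 1175 = +23.8%
  expect_equal(contrib[["split"]], 0)

  rep2 <- rep
  rep2$counts <- list(correct_cell = 10L, noise = 0L, split = 0L,
                      in_split = 0L, merged = 1L, in_merged = 2L, missed = 0L)
  expect_equal(error_contributions(rep2)[["merged"]], -10)  # -(2-1)/10

  rep3 <- rep
  rep3$counts$correct_cell <- 0L
  expect_error(error_contributions(rep3), "denominator")

  rep4 <- rep
  rep4$counts <- list(correct_cell = 5L, noise = 0L, split = 0L,
                      in_split = 0L, merged = 0L, in_merged = 0L, missed = 0L)
  expect_true(all(error_contributions(rep4) == 0))
})
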