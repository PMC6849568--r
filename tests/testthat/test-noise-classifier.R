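sim_table <- function(n, sep, seed = 1, p_noise = 0.5) {
  set.seed(seed)
  n1 <- round(n * (1 - p_noise)); n0 <- n - n1
  data.frame(
    f1 = c(rnorm(n1, sep / 2), rnorm(n0, -sep / 2)),
    f2 = c(rnorm(n1, 0), rnorm(n0, 0)),
    class = factor(rep(c("cell", "noise"), c(n1, n0)),
                   levels = c("cell", "noise"))
  )
}

test_that("training-set construction maps the taxonomy onto two classes", {
  labs <- c(rep("correct_cell", 5), rep("merged", 2), rep("split", 3),
            rep("noise", 4), rep("ppi", 1))
  rep <- structure(list(region_labels = stats::setNames(labs, seq_along(labs))),
                   class = "DetectionReport")
  ft <- data.frame(region = seq_along(labs), area = seq_along(labs),
                   grey_mean = 100 + seq_along(labs))
  tab <- build_training_set(rep, ft)
  expect_equal(sum(tab$class == "cell"), 10)   # correct + merged + split
  expect_equal(sum(tab$class == "noise"), 4)
  expect_equal(nrow(tab), 14)                  # ppi excluded
  expect_false("region" %in% names(tab))

  rep2 <- structure(list(region_labels = c(`1` = "correct_cell")),
                    class = "DetectionReport")
  expect_error(build_training_set(rep2, ft[1, ]), "degenerate")
})

test_that("the discriminant separates well-separated classes", {
  tab <- sim_table(400, sep = 10, seed = 2)
  model <- train_lda(tab)
  expect_gte(model$training_accuracy, 0.99)

  # identical class distributions: accuracy near the larger prior
  tab0 <- sim_table(600, sep = 0, seed = 3, p_noise = 0.4)
  m0 <- train_lda(tab0)
  expect_lt(abs(m0$training_accuracy - 0.6), 0.05)

  # 1-D classes at -1 / +1: threshold between them
  tab1 <- data.frame(f1 = c(rnorm(100, 1, 0.1), rnorm(100, -1, 0.1)),
                     class = factor(rep(c("cell", "noise"), each = 100),
                                    levels = c("cell", "noise")))
  m1 <- train_lda(tab1)
  thr_f1 <- m1$threshold / m1$weights[["f1"]] * m1$scale[["f1"]] +
            m1$center[["f1"]]
  expect_gt(thr_f1, -0.5)
  expect_lt(thr_f1, 0.5)
})

test_that("the discriminant agrees with the MASS reference implementation", {
  skip_if_not_installed("MASS")
  tab <- sim_table(500, sep = 2.5, seed = 11)
  ours <- predict_lda(train_lda(tab), tab)
  ref <- predict(MASS::lda(class ~ f1 + f2, data = tab))$class
  expect_gte(mean(ours == ref), 0.98)
})

test_that("model JSON serialisation round-trips predictions", {
  tab <- sim_table(200, sep = 3, seed = 7)
  model <- train_lda(tab)
  f <- withr::local_tempfile(fileext = ".json")
  write_lda_model(model, f)
  back <- read_lda_model(f)
  expect_equal(predict_lda(back, tab), predict_lda(model, tab))
  expect_equal(back$training_accuracy, model$training_accuracy)
})

test_that("noise filtering removes planted artifacts and keeps cells", {
  mk <- function(seed) generate_scene(easy_spec(
    n_cells = 18L, width = 420L, height = 320L, seed = seed,
    n_noise_blobs = 8L))
  train_one <- function(sc) {
    reg <- segment_cells(sc$pc, easy_params())
    rep <- classify_detections(reg, truth_nuclei(sc))
    list(rep = rep, ft = region_feature_table(reg), reg = reg)
  }
  tr <- lapply(1:3, function(s) train_one(mk(s)))
  tab <- build_training_set(lapply(tr, `[[`, "rep"), lapply(tr, `[[`, "ft"))
  model <- train_lda(tab)

  held <- train_one(mk(99))
  filtered <- apply_noise_filter(held$reg, model = model)
  truth_lab <- ifelse(held$rep$region_labels == "noise", "noise", "cell")
  kept <- held$rep$region_labels[
    seq_along(held$rep$region_labels) %in%
      unique(held$reg$labels[filtered$labels > 0])]
  n_cells_before <- sum(truth_lab == "cell")
  n_noise_before <- sum(truth_lab == "noise")
  expect_gte(sum(kept != "noise"), round(0.85 * n_cells_before))
  expect_lte(sum(kept == "noise"), round(0.4 * n_noise_before))

  # idempotence
  twice <- apply_noise_filter(filtered, model = model)
  expect_identical(twice$labels, filtered$labels)

  # empty input passes through
  empty <- labeled_regions(matrix(0L, 10, 10),
                           source = image8(matrix(1L, 10, 10)))
  expect_equal(region_count(apply_noise_filter(empty, model = model)), 0)
})

test_that("classification metrics implement the standard formulas", {
  m <- classification_metrics(rep("cell", 5), rep("cell", 5))
  expect_equal(m$precision, 1); expect_equal(m$recall, 1)
  expect_equal(m$F1, 1)

  # when p == r, F1 equals them
  pred <- c(rep("cell", 8), rep("noise", 2), "cell", "noise")
  truth <- c(rep("cell", 8), rep("cell", 2), "noise", "noise")
  m2 <- classification_metrics(pred, truth)
  expect_equal(m2$precision, 8 / 9)
  expect_equal(m2$recall, 8 / 10)

  m3 <- metrics_from_counts(TP = 50, TN = 50, FP = 10, FN = 10)
  expect_equal(m3$precision, m3$recall)
  expect_equal(m3$F1, m3$precision)

  # F1 ignores TN entirely
  a <- metrics_from_counts(10, 0, 3, 2)
  b <- metrics_from_counts(10, 1000, 3, 2)
  expect_equal(a$F1, b$F1)
  expect_error(metrics_from_counts(0, 5, 0, 2), "precision")
  expect_error(metrics_from_counts(0, 5, 2, 0), "recall")
})

test_that("the published confusion matrix yields the published F1", {
  # 1286 cell regions, 96.3% retained; 280 noise regions, 78.9% removed
  TP <- round(1286 * 0.963)
  FN <- 1286 - TP
  TN <- round(280 * 0.789)
  FP <- 280 - TN
  m <- metrics_from_counts(TP, TN, FP, FN)
  expect_equal(m$F1, 0.959, tolerance = 0.002)
})
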