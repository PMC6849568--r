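test_that("dish area and the culture multiplier match the worked example", {
  expect_equal(dish_area(35), 962.11, tolerance = 1e-5)
  expect_equal(dish_area(2 / sqrt(pi)), 1)
  expect_equal(dish_area(1), pi / 4)
  est <- estimate_total(10, a_total = 962.11, a_image = 1.06)
  expect_equal(est$N_total, 9076.5, tolerance = 1e-4)
  expect_equal(est$A_total / est$A_image, 907.65, tolerance = 1e-4)
  expect_equal(estimate_total(0, 100, 1)$N_total, 0)
  expect_equal(estimate_total(7.3, 5, 5)$N_total, 7.3)
  expect_error(estimate_total(5, 1, 2), "A_total")
  expect_error(estimate_total(-1, 10, 1), "non-negative")
})

test_that("extrapolation is linear in the mean count", {
  set.seed(2)
  for (k in 1:5) {
    m <- runif(1, 1, 50); a <- runif(1, 2, 10)
    expect_equal(estimate_total(a * m, 500, 2)$N_total,
                 a * estimate_total(m, 500, 2)$N_total)
  }
})

test_that("running-mean convergence follows the stated definition", {
  cv <- convergence_analysis(c(5, 5, 5, 5))
  expect_true(all(cv$delta_c == 0))
  expect_equal(cv$recommended_n, 2)

  cv2 <- suppressWarnings(convergence_analysis(c(10, 20)))
  expect_equal(cv2$delta_c, abs(15 - 10) / 15 * 100, tolerance = 1e-9)

  # a mid-series spike disqualifies earlier stabilisation
  cv3 <- convergence_analysis(c(10, 10, 10, 40, 10, 10, 10, 10),
                              threshold_percent = 5)
  expect_equal(cv3$recommended_n, 7)

  expect_warning(cv4 <- convergence_analysis(c(1, 100), threshold_percent = 1),
                 "threshold")
  expect_true(is.na(cv4$recommended_n))
  expect_error(convergence_analysis(5), "at least 2")
  expect_error(convergence_analysis(c(0, 0, 0)), "zero")
})

test_that("mean delta_c decreases with n on iid counts", {
  set.seed(7)
  curves <- replicate(300, suppressWarnings(
    convergence_analysis(rpois(20, 30))$delta_c))
  avg <- rowMeans(curves)
  expect_lt(cor(seq_along(avg), avg, method = "spearman"), 0)
  # and the tail is far below the head
  expect_lt(mean(avg[15:19]), mean(avg[1:3]))
})

test_that("through-origin validation regression", {
  x <- c(10, 50, 120, 400, 900)
  f <- validation_regression(x, x)
  expect_equal(f$gradient, 1); expect_equal(f$r_squared, 1)
  f2 <- validation_regression(x, 2 * x)
  expect_equal(f2$gradient, 2); expect_equal(f2$r_squared, 1)

  set.seed(12)
  reps <- replicate(50, {
    ref <- runif(9, 20, 600)          # nine validation images
    img <- 1.04 * ref + rnorm(9, 0, 5)
    validation_regression(ref, img)$gradient
  })
  expect_lt(max(abs(reps - 1.04)), 0.05)

  expect_error(validation_regression(c(0, 0), c(1, 2)), "zero")
  expect_error(validation_regression(1, 1), "paired counts|>= 2")
})

test_that("growth curves aggregate replicates and recover doubling time", {
  ser <- data.frame(time = rep(c(24, 48), each = 4),
                    replicate = rep(c(1, 1, 2, 2), 2),
                    count = c(10, 12, 11, 11, 21, 23, 22, 22))
  gc <- growth_curve(ser, a_total = 10, a_image = 10)
  expect_equal(nrow(gc$curve), 2)
  expect_equal(gc$curve$n_replicates, c(2, 2))
  ser1 <- data.frame(time = 10, replicate = c(1, 2), count = c(5, 5))
  gc1 <- growth_curve(ser1, a_total = 10, a_image = 10)
  expect_equal(gc1$curve$sd_total, 0)
  expect_error(growth_curve(data.frame(time = 1, replicate = 1,
                                       count = NA_real_)), "non-finite")

  set.seed(30)
  times <- c(48, 60, 72, 84, 96)
  ser2 <- do.call(rbind, lapply(times, function(t)
    data.frame(time = t, replicate = rep(1:2, each = 11),
               count = rpois(22, 8 * 2^(t / 24)))))
  gc2 <- growth_curve(ser2)
  dt <- doubling_time(gc2)
  expect_lt(abs(dt - 24) / 24, 0.15)
})
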