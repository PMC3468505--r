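test_that("rmse matches brute-force evaluation", {
  expect_identical(rmse(c(100, 110), c(100, 110)), 0)
  expect_equal(rmse(c(100, 100), c(103, 97)), 3.0)
  withr::with_seed(3, {
    o <- rnorm(10, 100, 5); p <- rnorm(10, 100, 5)
    brute <- sqrt(sum((o - p)^2) / 10)
    expect_equal(rmse(o, p), brute, tolerance = 1e-12)
  })
  expect_error(rmse(1:3, 1:4), class = "bb_validation_error")
  expect_error(rmse(c(1, NA), c(1, 2)), "horizon",
               class = "bb_validation_error")
})

test_that("model efficiency is 1 for perfect fits and 0 for the mean", {
  o <- c(100, 105, 110, 120)
  expect_equal(model_efficiency(o, o), 1.0)
  expect_equal(model_efficiency(o, rep(mean(o), 4)), 0.0)
  expect_lt(model_efficiency(o, rep(200, 4)), 0)
  expect_error(model_efficiency(rep(5, 3), c(4, 5, 6)),
               class = "bb_validation_error")
})

test_that("AIC follows the residual-sum-of-squares form", {
  expect_equal(aic(90, 10, 3), 10 * log(9) + 8, tolerance = 1e-12)
  # same fit, TTM (3 params) vs UM (9): penalty difference exactly 2 * 6
  expect_equal(aic(90, 20, 9) - aic(90, 20, 3), 12, tolerance = 1e-12)
  expect_lt(aic(45, 10, 3), aic(90, 10, 3))
  expect_error(aic(0, 10, 3), "perfect", class = "bb_validation_error")
  expect_error(aic(10, 4, 3), class = "bb_validation_error")
})

test_that("ME reconstructs from RMSE and the total sum of squares", {
  withr::with_seed(9, {
    for (i in 1:10) {
      o <- rnorm(12, 100, 8); p <- o + rnorm(12, 0, 4)
      t <- length(o)
      tss <- sum((o - mean(o))^2)
      expect_equal(model_efficiency(o, p), 1 - t * rmse(o, p)^2 / tss,
                   tolerance = 1e-10)
    }
  })
})

test_that("perfect internal fits report RMSE 0 and an undefined AIC", {
  o <- c(100, 104, 110, 118)
  m <- budburst:::evaluation_metrics(o, o, n_params = 3)
  expect_identical(m$rmse, 0)
  expect_true(is.na(m$aic))
  expect_identical(m$aic_note, "undefined-perfect-fit")
})

test_that("the external split is stratified, exhaustive and reproducible", {
  obs <- generate_observations(beech_stress_design(seed = 5L),
                               climate_config(seed = 6L))
  expect_identical(nrow(obs), 48L)
  halves <- split_dataset(obs, fraction = 0.5, seed = 2L)
  expect_identical(nrow(halves$train), 24L)
  expect_identical(nrow(halves$test), 24L)
  # every treatment in both halves
  expect_setequal(unique(halves$train$treatment), unique(obs$treatment))
  expect_setequal(unique(halves$test$treatment), unique(obs$treatment))
  # union is the original multiset
  key <- function(d) sort(paste(d$treatment, d$chamber, d$sapling))
  expect_identical(sort(c(key(halves$train), key(halves$test))), key(obs))
  halves2 <- split_dataset(obs, fraction = 0.5, seed = 2L)
  expect_identical(halves$train$sapling, halves2$train$sapling)

  lone <- data.frame(species = "x", treatment = c("A", "A", "B"),
                     bb_index = c(200, 210, 205))
  expect_warning(sp <- split_dataset(lone, 0.5, seed = 1L), "single sapling")
  expect_true("B" %in% sp$train$treatment)
  expect_error(split_dataset(obs, fraction = 1.2), class = "bb_validation_error")
})

test_that("cross-validation reports one metrics row per mode", {
  bench <- make_ttm_benchmark(seed = 81L)
  cfg <- mcmc_config(n_iterations = 1500L, burn_in = 500L, seed = 4L)
  internal <- cross_validate("TTM", bench$obs, bench$series,
                             mode = "internal", config = cfg)
  external <- cross_validate("TTM", bench$obs, bench$series,
                             mode = "external", config = cfg)
  expect_identical(nrow(internal$metrics), 1L)
  expect_identical(internal$metrics$mode, "internal")
  expect_false(is.na(internal$metrics$aic))
  expect_true(is.na(external$metrics$aic))
  expect_identical(external$metrics$n, 24L)
  expect_lt(internal$metrics$rmse, 5)
})

test_that("external validation error exceeds internal on average", {
  int_rmse <- numeric(0); ext_rmse <- numeric(0)
  for (r in 1:10) {
    bench <- make_ttm_benchmark(seed = 900L + r, sigma_obs = 2)
    cfg <- mcmc_config(n_iterations = 1200L, burn_in = 400L,
                       seed = 30L + r, n_starts = 50L)
    int_rmse <- c(int_rmse,
                  cross_validate("TTM", bench$obs, bench$series,
                                 mode = "internal", config = cfg)$metrics$rmse)
    ext_rmse <- c(ext_rmse,
                  cross_validate("TTM", bench$obs, bench$series,
                                 mode = "external", config = cfg)$metrics$rmse)
  }
  expect_gte(mean(ext_rmse), mean(int_rmse))
})

test_that("sensitivity slopes recover hand-computed values", {
  # two treatments: (0 degC, 0 d) and (6 degC, -21 d) -> -3.5 d/degC
  obs <- data.frame(species = "birch",
                    treatment = rep(c("W0S0", "W6S6"), each = 3),
                    bb_index = c(220, 221, 219, 199, 200, 198))
  res <- sensitivity_slope(obs, c(W0S0 = 0, W6S6 = 6))
  expect_equal(res$slopes$slope, -3.5, tolerance = 1e-12)
  ctrl <- res$treatments[res$treatments$treatment == "W0S0", ]
  expect_identical(ctrl$delta_T, 0)
  expect_identical(ctrl$advancement, 0)

  # flat response -> slope 0
  flat <- data.frame(species = "x", treatment = rep(c("A", "B"), each = 2),
                     bb_index = rep(200, 4))
  expect_equal(sensitivity_slope(flat, c(A = 0, B = 4),
                                 control_label = "A")$slopes$slope, 0)

  # exact line with slope -5.2 through three treatment means
  line <- data.frame(species = "y", treatment = c("A", "B", "C"),
                     bb_index = c(200, 200 - 5.2 * 2, 200 - 5.2 * 4))
  expect_equal(sensitivity_slope(line, c(A = 0, B = 2, C = 4),
                                 control_label = "A")$slopes$slope,
               -5.2, tolerance = 1e-9)

  expect_error(sensitivity_slope(flat, c(A = 2, B = 2), control_label = "A"),
               class = "bb_validation_error")
  expect_error(sensitivity_slope(flat, c(A = 0, B = 4), control_label = "Z"),
               class = "bb_validation_error")
})

test_that("warming deltas follow the December-to-budburst definition", {
  ctrl <- flat_series(5)
  sbt <- list(W0S0 = ctrl,
              W6S6 = apply_treatment(ctrl, treatment_schedule("W6S6", 6, 6)))
  obs <- data.frame(species = "x", treatment = c("W0S0", "W6S6"),
                    bb_index = c(241, 241))
  d <- observed_warming_deltas(obs, sbt)
  expect_equal(d[["W0S0"]], 0)
  expect_equal(d[["W6S6"]], 6)  # fully warmed window
})
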