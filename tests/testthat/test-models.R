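test_that("rate functions match their closed forms", {
  tol <- 1e-9
  expect_equal(rate_forcing_linear(5, 5), 0, tolerance = tol)
  expect_equal(rate_forcing_linear(7, 5), 2, tolerance = tol)
  expect_equal(rate_forcing_linear(0, 5), 0, tolerance = tol)

  expect_equal(rate_chilling_triangular(3, -4, 3, 10), 1, tolerance = tol)
  expect_equal(rate_chilling_triangular(-4, -4, 3, 10), 0, tolerance = tol)
  expect_equal(rate_chilling_triangular(10, -4, 3, 10), 0, tolerance = tol)
  expect_equal(rate_chilling_triangular(-0.5, -4, 3, 10), 0.5, tolerance = tol)
  expect_error(rate_chilling_triangular(0, 3, 3, 10),
               class = "bb_parameter_error")

  expect_equal(rate_forcing_sigmoid(10, 0.2, 10, 1), 0.5, tolerance = tol)
  expect_equal(rate_forcing_sigmoid(20, 0.2, 10, 1), 1 / (1 + exp(-2)),
               tolerance = tol)
  expect_equal(rate_forcing_sigmoid(1e6, 0.2, 10, 2), 2, tolerance = tol)
  expect_equal(rate_forcing_sigmoid(-1e6, 0.2, 10, 2), 0, tolerance = tol)

  expect_identical(rate_chilling_chill_day(2, 5), 1)
  expect_identical(rate_chilling_chill_day(5, 5), 0)  # strict inequality
  expect_identical(rate_chilling_chill_day(7, 5), 0)

  expect_equal(forcing_requirement_am(0, 20, 100, -0.05), 120, tolerance = tol)
  expect_equal(forcing_requirement_am(1e9, 20, 100, -0.05), 20, tolerance = tol)
  expect_equal(forcing_requirement_am(50, 20, 100, -0.05),
               20 + 100 * exp(-2.5), tolerance = tol)

  expect_equal(rate_chilling_unified(2, 0.1, 0, 2), 0.5, tolerance = tol)
  expect_equal(rate_chilling_unified(200, 0.1, 0, 2), 0, tolerance = tol)
  expect_equal(rate_chilling_unified(4, 0.1, 0, 2), 1 / (1 + exp(0.4)),
               tolerance = tol)

  expect_equal(rate_forcing_unified(8, 0.5, 8), 0.5, tolerance = tol)
  expect_equal(rate_forcing_unified(1e6, 0.5, 8), 1, tolerance = tol)
  expect_equal(rate_forcing_unified(12, 0.5, 8), 1 / (1 + exp(-2)),
               tolerance = tol)

  expect_equal(forcing_requirement_um(0, 200, -0.01), 200, tolerance = tol)
  expect_equal(forcing_requirement_um(123, 200, 0), 200, tolerance = tol)
  expect_equal(forcing_requirement_um(100, 200, -0.01), 200 * exp(-1),
               tolerance = tol)
})

test_that("model registry has the exact parameter counts", {
  counts <- c(TTM = 3L, SM = 8L, PM = 9L, AM = 8L, UM = 9L)
  for (m in model_ids()) {
    spec <- model_spec(m)
    expect_identical(spec$n_parameters, counts[[m]])
    expect_identical(nrow(spec$bounds), counts[[m]])
  }
  # AM day anchors are fixed, not calibrated
  am <- model_spec("AM")
  expect_false(any(am$calibrated[c("t1f", "t1c", "t2c")]))
  expect_identical(am$defaults[["t1f"]], 123)
  expect_identical(am$defaults[["t1c"]], 62)
  expect_error(parameter_vector("SM", c(Tmin = 5, Topt = 0, Tmax = 20)),
               class = "bb_parameter_error")
  expect_error(parameter_vector("TTM", c(Tb = 99)),
               class = "bb_parameter_error")
  expect_error(parameter_vector("TTM", c(bogus = 1)),
               class = "bb_parameter_error")
})

test_that("the first forcing day counts in full (day-counting convention)", {
  s <- flat_series(6)  # Tb + 1 everywhere
  p <- predict_budburst("TTM", c(t1f = 100, Tb = 5, Fstar = 10), s)
  expect_identical(p$bb_index, 109L)  # 10th forcing day, d0 counted as day 1
  expect_false(p$none)
  expect_equal(p$sf_final, 10)
})

test_that("a NONE prediction is a first-class outcome", {
  # constant temperature above Tmax: no chilling can accumulate
  p <- predict_budburst(
    "SM", c(Tmin = -4, Topt = 3, Tmax = 10, a = 0.3, b = 10, c = 1,
            Cstar = 50, Fstar = 10), flat_series(15))
  expect_true(p$none)
  expect_identical(p$bb_index, NA_integer_)
  expect_equal(p$sc_final, 0)
})

test_that("TTM warming monotonicity holds; SM warming can delay budburst", {
  withr::with_seed(21, {
    for (i in 1:15) {
      s <- random_series(seed = 300 + i)
      p <- draw_params(model_spec("TTM"))
      base <- predict_budburst("TTM", p, s)
      warmed <- temperature_series(s$temps + runif(1, 0, 6))
      warm <- predict_budburst("TTM", p, warmed)
      if (!base$none) {
        expect_false(warm$none)
        expect_lte(warm$bb_index, base$bb_index)
      }
    }
  })
  # the central chilling mechanism: uniform warming can delay or abolish
  # budburst in a chilling-gated model
  p_sm <- c(Tmin = -5, Topt = 2, Tmax = 10, a = 0.35, b = 10, c = 1,
            Cstar = 60, Fstar = 15)
  s <- synthesize_daily_temperature(climate_config(noise_sd = 0), HORIZON)
  cool <- predict_budburst("SM", p_sm, s)
  hot <- predict_budburst("SM", p_sm, temperature_series(s$temps + 8))
  expect_false(cool$none)
  expect_true(hot$none || hot$bb_index > cool$bb_index)
})

test_that("models reduce to their limiting cases", {
  withr::with_seed(31, {
    for (i in 1:10) {
      s <- random_series(seed = 400 + i)
      # PM with Km = 1: competence always 1, so forcing is ungated; equals
      # SM whose chilling gate opens on day one (wide triangle so the first
      # September day already chills)
      shared <- c(Tmin = -10, Topt = 3, Tmax = 30, a = runif(1, 0.1, 0.6),
                  b = runif(1, 5, 12), c = 1)
      fstar <- runif(1, 5, 25)
      pm <- predict_budburst("PM", c(shared, Cstar = 50, Fstar = fstar, Km = 1), s)
      sm <- predict_budburst("SM", c(shared, Cstar = 1e-3, Fstar = fstar), s)
      expect_identical(pm$bb_index, sm$bb_index)
      # AM with b = 0: constant threshold a, linear forcing from 1 January
      tb <- runif(1, 0, 8); a_req <- runif(1, 30, 120)
      am <- predict_budburst("AM", c(Tb = tb, Tc = 5, a = a_req, b = 1e-3,
                                     c = -1), s)
      ttm <- predict_budburst("TTM", c(t1f = 123, Tb = tb, Fstar = a_req), s)
      if (!am$none || !ttm$none) {
        expect_true(abs(am$bb_index - ttm$bb_index) <= 1)
      }
    }
  })
})

test_that("fast and reference engines agree exactly on random draws", {
  withr::with_seed(41, {
    for (m in model_ids()) {
      spec <- model_spec(m)
      for (i in 1:20) {
        p <- draw_params(spec)
        s <- random_series(seed = 500 + i)
        f <- predict_budburst(spec, p, s, engine = "fast")
        r <- predict_budburst(spec, p, s, engine = "reference")
        expect_identical(f$bb_index, r$bb_index)
        expect_identical(f$sf_final, r$sf_final)
        expect_identical(f$sc_final, r$sc_final)
      }
    }
  })
})

test_that("state trajectories are monotone and bracket the threshold", {
  withr::with_seed(51, {
    for (m in c("TTM", "SM", "PM", "UM")) {
      spec <- model_spec(m)
      for (i in 1:10) {
        p <- draw_params(spec)
        s <- random_series(seed = 600 + i)
        pr <- predict_budburst(spec, p, s, trace = TRUE)
        tr <- pr$trajectory
        expect_true(all(tr$Sf >= 0) && all(diff(tr$Sf) >= -1e-12))
        if (!is.null(tr$Rc)) expect_true(all(tr$Rc >= 0))
        if (!is.null(tr$Rf)) expect_true(all(tr$Rf >= 0))
        if (!pr$none) {
          pos <- pr$bb_index - pr$forcing_start + 1L
          expect_gte(tr$Sf[pos], pr$fstar)
          if (pos > 1L) expect_lt(tr$Sf[pos - 1L], pr$fstar)
        }
      }
    }
  })
})

test_that("prediction validates its inputs", {
  s <- flat_series(6)
  expect_error(predict_budburst("TTM", c(t1f = 100, Tb = 5, Fstar = 10),
                                flat_series(6, n = 100)),
               class = "bb_range_error")
  expect_error(predict_budburst("TTM", c(t1f = 100, Tb = 5, Fstar = 10),
                                temperature_series(rep(6, 310), start_index = 5L)),
               class = "bb_range_error")
  expect_error(predict_budburst("TTM", c(t1f = 100, Tb = 99, Fstar = 10), s),
               class = "bb_parameter_error")
})
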