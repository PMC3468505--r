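test_that("the default design mirrors the chamber experiment bookkeeping", {
  des <- default_design()
  expect_identical(length(des$species), 3L)
  expect_setequal(names(des$species), c("beech", "oak", "birch"))
  expect_identical(length(des$treatments), 7L)
  expect_setequal(names(des$treatments),
                  c("W0S0", "W6S0", "W0S6", "W6S6", "W2S0", "W2S2", "W2S6"))
  cstar <- vapply(des$species, function(sp) sp$params[["Cstar"]], numeric(1))
  expect_gt(cstar[["beech"]], cstar[["oak"]])
  expect_gt(cstar[["oak"]], cstar[["birch"]])
  # 4 chambers x 3 saplings = 12 per treatment; 48 over the main factorial
  expect_identical(des$chambers_per_treatment * des$saplings_per_chamber, 12L)
  obs <- generate_observations(default_design(seed = 1L))
  main <- obs[obs$species == "beech" &
                obs$treatment %in% c("W0S0", "W6S0", "W0S6", "W6S6"), ]
  expect_identical(nrow(main), 48L)
  expect_identical(sum(obs$species == "oak"), 84L)  # 7 treatments x 12
})

test_that("monitoring visits censor forward by less than one interval", {
  # true day 200 with visits {..., 199, 202, ...} records 202
  expect_identical(next_visit_day(200L, 3L, monitoring_start = 154L), 202L)
  expect_identical(next_visit_day(199L, 3L, monitoring_start = 154L), 199L)
  withr::with_seed(77, {
    day <- sample(100:300, 200, replace = TRUE)
    for (interval in c(1L, 2L, 3L, 5L)) {
      rec <- next_visit_day(day, interval)
      expect_true(all(rec >= day))
      expect_true(all(rec - day < interval | rec == 303L))
    }
  })
})

test_that("a noise-free design degenerates to identical within-treatment dates", {
  des <- default_design(seed = 3L)
  des$sapling_jitter_sd <- 0
  des$chamber_jitter_sd <- 0
  des$monitoring_interval <- 1L
  obs <- generate_observations(des, climate_config(seed = 4L))
  per <- tapply(obs$bb_index, interaction(obs$species, obs$treatment),
                function(x) length(unique(x)))
  expect_true(all(per == 1L))
})

test_that("warming advances budburst in the generated experiment", {
  obs <- generate_observations(default_design(seed = 1L))
  for (sp in c("beech", "oak", "birch")) {
    sub <- obs[obs$species == sp, ]
    mn <- tapply(sub$bb_index, sub$treatment, mean)
    expect_lt(mn[["W6S6"]], mn[["W0S0"]])
  }
  expect_true(all(obs$budburst_doy >= 1 & obs$budburst_doy <= 181))
})

test_that("generated ranges bracket the observed per-species spans", {
  # reported budburst windows: birch DOY 60-95, oak 78-125, beech 95-140
  windows <- list(beech = c(95, 140), oak = c(78, 125), birch = c(60, 95))
  obs <- generate_observations(default_design(seed = 1L))
  for (sp in names(windows)) {
    rng <- range(obs$budburst_doy[obs$species == sp])
    expect_lte(abs(rng[1] - windows[[sp]][1]), 15)
    expect_lte(abs(rng[2] - windows[[sp]][2]), 15)
  }
})

test_that("zero warming makes treatments statistically exchangeable", {
  rejections <- 0L
  for (seed in 1:20) {
    des <- synthetic_design(
      species = list(birch = default_design()$species$birch),
      treatments = list(
        A = treatment_schedule("A", 0, 0),
        B = treatment_schedule("B", 0, 0)),
      seed = seed)
    obs <- generate_observations(des, climate_config(seed = 1000L + seed))
    p <- suppressWarnings(
      stats::ks.test(obs$bb_index[obs$treatment == "A"],
                     obs$bb_index[obs$treatment == "B"])$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  # allow the expected false-positive rate at alpha = 0.01 over 20 seeds
  expect_lte(rejections, 2L)
})

test_that("a species that cannot flush in the control is a design error", {
  des <- beech_stress_design(seed = 1L)
  des$species$beech$params[["Fstar"]] <- 500
  expect_error(generate_observations(des, climate_config(seed = 2L)),
               class = "bb_design_error")
})

test_that("observation CSV round-trips and rejects corrupt files", {
  obs <- generate_observations(beech_stress_design(seed = 9L),
                               climate_config(seed = 10L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations_csv(obs, path)
  back <- read_observations_csv(path)
  expect_identical(back$bb_index, as.integer(obs$bb_index))
  expect_identical(back$budburst_doy, as.integer(obs$budburst_doy))
  expect_identical(back$treatment, obs$treatment)

  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path)  # duplicate key
  expect_error(read_observations_csv(path), class = "bb_integrity_error")

  tampered <- lines
  tampered[3] <- sub(",([0-9]+)$", ",999", tampered[3])  # bad day index
  writeLines(tampered, path)
  expect_error(read_observations_csv(path), "inconsistent",
               class = "bb_parse_error")

  tampered <- lines
  tampered[4] <- sub("^(\"?[a-z]+\"?,\"?[A-Z0-9]+\"?,[0-9]+,[0-9]+,)[0-9]+",
                     "\\1oops", tampered[4])
  writeLines(tampered, path)
  expect_error(read_observations_csv(path), class = "bb_parse_error")
})

test_that("designs serialize losslessly with generation metadata", {
  des <- default_design(seed = 42L)
  path <- withr::local_tempfile(fileext = ".json")
  design_to_json(des, path)
  back <- design_from_json(path)
  expect_identical(back$seed, des$seed)
  expect_equal(back$species$beech$params, des$species$beech$params)
  expect_identical(back$treatments$W6S0$winter_offset,
                   des$treatments$W6S0$winter_offset)

  obs <- generate_observations(des)
  meta <- attr(obs, "meta")
  expect_identical(meta$true_models$beech, "SM")
  expect_identical(meta$design_seed, 42L)
  # repeated generation is deterministic
  obs2 <- generate_observations(default_design(seed = 42L))
  expect_identical(obs$bb_index, obs2$bb_index)
})
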