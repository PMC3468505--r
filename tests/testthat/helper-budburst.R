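# Shared fixtures, generated in code.

HORIZON <- 303L

# Constant-temperature series starting 1 September.
flat_series <- function(temp, n = HORIZON) {
  temperature_series(rep(temp, n), start_index = 1L)
}

# A seasonal series with optional noise, for property-style tests.
random_series <- function(seed, noise_sd = 3) {
  synthesize_daily_temperature(
    climate_config(annual_mean = runif(1, 7, 12),
                   annual_amplitude = runif(1, 5, 9),
                   ar1_coefficient = runif(1, 0, 0.9),
                   noise_sd = noise_sd, seed = seed),
    HORIZON)
}

# Uniform parameter draw inside the spec's bounds, rejecting draws that
# violate structural orderings.
draw_params <- function(spec, max_tries = 200L) {
  b <- spec$bounds
  for (i in seq_len(max_tries)) {
    p <- b[, "lower"] + runif(nrow(b)) * (b[, "upper"] - b[, "lower"])
    names(p) <- spec$parameter_names
    p[!spec$calibrated] <- spec$defaults[!spec$calibrated]
    if (budburst:::parameters_valid(spec, p)) return(p)
  }
  stop("could not draw valid parameters")
}

# Batch-means Monte-Carlo standard error of a chain mean.
mcse_batch <- function(x, n_batches = 30L) {
  n <- length(x)
  bs <- n %/% n_batches
  means <- vapply(seq_len(n_batches), function(i) {
    mean(x[((i - 1) * bs + 1):(i * bs)])
  }, numeric(1))
  sd(means) / sqrt(n_batches)
}

# Small TTM benchmark: noise-free generating dates + jittered observations
# across the four main treatments.
make_ttm_benchmark <- function(seed, sigma_obs = 1, n_per_trt = 12L,
                               truth = c(t1f = 123, Tb = 4, Fstar = 30)) {
  climate <- climate_config(seed = seed)
  control <- synthesize_daily_temperature(climate, HORIZON)
  trts <- standard_treatments()[c("W0S0", "W6S0", "W0S6", "W6S6")]
  sbt <- treatment_series(control, trts)
  true_day <- vapply(sbt, function(s) {
    predict_budburst("TTM", truth, s)$bb_index
  }, integer(1))
  stopifnot(!anyNA(true_day))
  obs <- with_seed(seed + 1L, {
    do.call(rbind, lapply(names(sbt), function(trt) {
      data.frame(species = "ttm_test", treatment = trt,
                 chamber = rep(1:4, each = n_per_trt / 4),
                 sapling = seq_len(n_per_trt),
                 bb_index = true_day[[trt]] +
                   round(rnorm(n_per_trt, 0, sigma_obs)))
    }))
  })
  list(obs = obs, series = sbt, true_day = true_day, truth = truth)
}
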