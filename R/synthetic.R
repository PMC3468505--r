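#' Design of a synthetic warming experiment
#'
#' Describes the factorial chamber experiment the generator emulates: which
#' species (each with a true generating model and parameters), which
#' warming treatments, the replication structure (chambers per treatment,
#' saplings per chamber), measurement noise, and the phenology monitoring
#' grid that censors observed budburst to the next visit.
#'
#' @param species named list; each element a list with \code{model_id} and
#'   \code{params} (the species' true generating model).
#' @param treatments named list of \code{\link{treatment_schedule}}s.
#' @param chambers_per_treatment chambers replicating each treatment.
#' @param saplings_per_chamber saplings of each species per chamber.
#' @param sapling_jitter_sd between-sapling noise on the true budburst day,
#'   days (>= 0).
#' @param chamber_jitter_sd between-chamber temperature offset, degrees C
#'   (>= 0); the chambers' realized warming is close to, not exactly, the
#'   prescribed value.
#' @param monitoring_interval days between phenology visits (>= 1).
#' @param monitoring_start day index anchoring the visit grid (default 154
#'   = 1 February).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return An object of class \code{synthetic_design}.
#' @export
synthetic_design <- function(species, treatments,
                             chambers_per_treatment = 4L,
                             saplings_per_chamber = 3L,
                             sapling_jitter_sd = 2,
                             chamber_jitter_sd = 0.3,
                             monitoring_interval = 2L,
                             monitoring_start = 154L,
                             seed = 1L) {
  if (sapling_jitter_sd < 0 || chamber_jitter_sd < 0) {
    bb_stop("jitter standard deviations must be >= 0", "bb_validation_error")
  }
  if (monitoring_interval < 1) {
    bb_stop("monitoring_interval must be >= 1", "bb_validation_error")
  }
  if (is.null(names(species)) || is.null(names(treatments))) {
    bb_stop("species and treatments must be named lists", "bb_validation_error")
  }
  structure(list(species = species, treatments = treatments,
                 chambers_per_treatment = as.integer(chambers_per_treatment),
                 saplings_per_chamber = as.integer(saplings_per_chamber),
                 sapling_jitter_sd = sapling_jitter_sd,
                 chamber_jitter_sd = chamber_jitter_sd,
                 monitoring_interval = as.integer(monitoring_interval),
                 monitoring_start = as.integer(monitoring_start),
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

# True Sequential-model parameters of the default design.  The per-species
# chilling requirements keep the reported ordering beech (120) > oak (100) >
# birch (50) chill-day-equivalents; the chilling triangles are wide enough
# that every treatment still meets its requirement (the design is
# forcing-dominated, as in the experiment, where chilling occurred even in
# the warmed chambers), but narrow enough that winter warming slows chilling
# and delays the forcing trigger by two to four weeks -- which is what keeps
# winter-warmed saplings from flushing in mid winter.  The shared sigmoid
# forcing (midpoint 10 degC) plus the forcing requirements place control
# budburst in mid May (beech), early May (oak) and mid April (birch).
.default_species_params <- function() {
  list(
    beech = list(model_id = "SM",
                 params = c(Tmin = -25, Topt = 6, Tmax = 30,
                            a = 0.35, b = 9, c = 1,
                            Cstar = 120, Fstar = 39)),
    oak   = list(model_id = "SM",
                 params = c(Tmin = -12, Topt = 3.5, Tmax = 22,
                            a = 0.35, b = 9, c = 1,
                            Cstar = 100, Fstar = 32)),
    birch = list(model_id = "SM",
                 params = c(Tmin = -10, Topt = 3, Tmax = 13,
                            a = 0.35, b = 10, c = 1,
                            Cstar = 50, Fstar = 15))
  )
}

#' Default synthetic warming-experiment design
#'
#' Three species (beech, oak, birch) generated from the Sequential model
#' with chilling requirements 120, 100 and 50 chill-day-equivalents, under
#' the seven chamber treatments W0S0, W6S0, W0S6, W6S6, W2S0, W2S2, W2S6
#' (transfer on 22 February, index 175), with 4 chambers x 3 saplings = 12
#' saplings per treatment per species (48 per species over the main 2x2
#' factorial).
#'
#' @param seed integer seed.
#' @return A \code{\link{synthetic_design}}.
#' @export
default_design <- function(seed = 1L) {
  synthetic_design(species = .default_species_params(),
                   treatments = standard_treatments(),
                   seed = seed)
}

#' Chilling-limited variant of the beech design
#'
#' A single-species design in which the chilling triangle is narrow
#' (feet -5/12 degC) and the chilling requirement high, so the continuously
#' warmed W6S6 treatment satisfies chilling only late in spring.  Budburst
#' in W6S6 is then much later than a purely forcing-driven model expects:
#' the Sequential model can reproduce it, the Thermal Time model cannot.
#' Only the main 2x2 factorial treatments are used (48 saplings).
#'
#' @param seed integer seed.
#' @return A \code{\link{synthetic_design}}.
#' @export
beech_stress_design <- function(seed = 1L) {
  species <- list(
    beech = list(model_id = "SM",
                 params = c(Tmin = -5, Topt = 2, Tmax = 16,
                            a = 0.35, b = 10, c = 1,
                            Cstar = 95, Fstar = 18)))
  synthetic_design(species = species,
                   treatments = standard_treatments()[c("W0S0", "W6S0",
                                                        "W0S6", "W6S6")],
                   seed = seed)
}

#' Next phenology visit on the monitoring grid
#'
#' Visits fall on every day congruent to \code{monitoring_start} modulo
#' \code{interval}; an observed budburst is recorded at the first visit on
#' or after the true day (censoring never moves a date earlier, and the
#' recording gap is < \code{interval}).  Days past the last visit are
#' recorded at the horizon.
#'
#' @param day true day index (vectorized).
#' @param interval days between visits.
#' @param monitoring_start day index anchoring the grid.
#' @param horizon last recordable day index.
#' @return Integer vector of recorded day indices.
#' @export
next_visit_day <- function(day, interval, monitoring_start = 154L,
                           horizon = 303L) {
  v <- monitoring_start + interval * ceiling((day - monitoring_start) / interval)
  as.integer(pmin(v, horizon))
}

#' Generate a synthetic budburst observation set
#'
#' Simulates the chamber experiment: for each treatment chamber a realized
#' temperature offset is drawn (sd \code{chamber_jitter_sd}) and added to
#' the scheduled treatment series from the warming start onward; each
#' sapling's budburst is the species' true-model prediction on its chamber
#' series plus rounded Gaussian sapling jitter, censored to the next
#' monitoring visit.  Generation is deterministic given the design and
#' climate seeds.
#'
#' A species whose true parameters yield no budburst in the control
#' treatment is a design error.  In warmed treatments a missing budburst is
#' recorded at the horizon day and flagged \code{censored_at_horizon}.
#'
#' @param design a \code{\link{synthetic_design}}.
#' @param climate a \code{\link{climate_config}} for the ambient series.
#' @param horizon last day index of the simulation (default 303 = 30 June).
#' @return An \code{observation_set}: data frame with columns
#'   \code{species}, \code{treatment}, \code{chamber}, \code{sapling},
#'   \code{bb_index}, \code{budburst_doy}, \code{censored_at_horizon}, with
#'   generation metadata (true models and parameters, seeds) in attribute
#'   \code{meta}.
#' @export
generate_observations <- function(design, climate = climate_config(),
                                  horizon = 303L) {
  if (!inherits(design, "synthetic_design")) {
    bb_stop("design must be a synthetic_design", "bb_validation_error")
  }
  control <- synthesize_daily_temperature(climate, horizon)
  specs <- lapply(design$species, function(sp) model_spec(sp$model_id))
  rows <- vector("list", 0L)
  control_labels <- names(which(vapply(design$treatments, function(s) {
    s$winter_offset == 0 && s$spring_offset == 0
  }, logical(1))))
  with_seed(design$seed, {
    for (trt in names(design$treatments)) {
      sched <- design$treatments[[trt]]
      base <- apply_treatment(control, sched)
      d <- series_days(base)
      for (ch in seq_len(design$chambers_per_treatment)) {
        offset <- stats::rnorm(1, 0, design$chamber_jitter_sd)
        temps <- base$temps
        temps[d >= sched$winter_start] <- temps[d >= sched$winter_start] + offset
        chamber_series <- temperature_series(temps, base$start_index)
        for (sp in names(design$species)) {
          p <- parameter_vector(specs[[sp]], design$species[[sp]]$params)
          bb_true <- .predict_bb_day(specs[[sp]]$model_id, p,
                                     chamber_series$temps, horizon)
          at_horizon <- is.na(bb_true)
          if (at_horizon && trt %in% control_labels) {
            bb_stop(sprintf(
              "species '%s' never reaches budburst in control treatment '%s'",
              sp, trt), "bb_design_error")
          }
          jitter <- round(stats::rnorm(design$saplings_per_chamber, 0,
                                       design$sapling_jitter_sd))
          day <- if (at_horizon) rep(horizon, design$saplings_per_chamber)
                 else pmin(pmax(bb_true + jitter, 1L), horizon)
          recorded <- next_visit_day(day, design$monitoring_interval,
                                     design$monitoring_start, horizon)
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, treatment = trt, chamber = ch,
            sapling = seq_len(design$saplings_per_chamber),
            bb_index = recorded,
            budburst_doy = index_to_doy(recorded),
            censored_at_horizon = at_horizon,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  obs <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(obs, "meta") <- list(
    true_models = lapply(design$species, function(sp) sp$model_id),
    true_parameters = lapply(design$species, function(sp) sp$params),
    design_seed = design$seed, climate = unclass(climate))
  class(obs) <- c("observation_set", "data.frame")
  obs
}

#' Treatment temperature series used by an experiment
#'
#' Convenience wrapper building the nominal (jitter-free) per-treatment
#' series from an ambient series and a list of schedules; these are the
#' series used for calibration and evaluation.
#'
#' @param control ambient \code{\link{temperature_series}}.
#' @param treatments named list of \code{\link{treatment_schedule}}s.
#' @return Named list of \code{temperature_series}.
#' @export
treatment_series <- function(control, treatments) {
  out <- lapply(treatments, function(s) apply_treatment(control, s))
  names(out) <- names(treatments)
  out
}

#' Read and write budburst observation CSV files
#'
#' Columns: \code{species}, \code{treatment}, \code{chamber},
#' \code{sapling}, \code{budburst_doy} and optionally
#' \code{budburst_day_index} (checked for consistency with the DOY via
#' DOY = index - 122).  The (species, treatment, chamber, sapling) key must
#' be unique.
#'
#' @param obs observation data frame.
#' @param path file path.
#' @return \code{read_observations_csv} returns an \code{observation_set}
#'   data frame; \code{write_observations_csv} returns \code{path}
#'   invisibly.
#' @export
write_observations_csv <- function(obs, path) {
  obs <- as_observation_frame(obs)
  df <- data.frame(species = obs$species, treatment = obs$treatment,
                   chamber = obs$chamber, sapling = obs$sapling,
                   budburst_doy = index_to_doy(obs$bb_index),
                   budburst_day_index = obs$bb_index,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species", "treatment", "chamber", "sapling", "budburst_doy")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    bb_stop(sprintf("observation CSV lacks column(s): %s",
                    paste(missing, collapse = ", ")), "bb_parse_error")
  }
  doy <- suppressWarnings(as.integer(df$budburst_doy))
  if (anyNA(doy)) {
    bb_stop(sprintf("unparseable budburst_doy at data line %d",
                    which(is.na(doy))[1]), "bb_parse_error")
  }
  key <- paste(df$species, df$treatment, df$chamber, df$sapling, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    bb_stop(sprintf(
      "duplicate observation key (species %s, treatment %s, chamber %s, sapling %s) at data line %d",
      df$species[i], df$treatment[i], df$chamber[i], df$sapling[i], i),
      "bb_integrity_error")
  }
  idx <- doy_to_index(doy)
  if ("budburst_day_index" %in% names(df)) {
    stored <- suppressWarnings(as.integer(df$budburst_day_index))
    bad <- which(is.na(stored) | stored != idx)
    if (length(bad)) {
      bb_stop(sprintf(
        "budburst_day_index inconsistent with budburst_doy at data line %d",
        bad[1]), "bb_parse_error")
    }
  }
  out <- data.frame(species = df$species, treatment = df$treatment,
                    chamber = df$chamber, sapling = df$sapling,
                    bb_index = idx, budburst_doy = doy,
                    stringsAsFactors = FALSE)
  class(out) <- c("observation_set", "data.frame")
  out
}

#' Serialize a synthetic design to JSON
#'
#' Round-trips the full design -- true models and parameters, treatment
#' schedules, replication, noise levels and seed -- for provenance.
#'
#' @param design a \code{\link{synthetic_design}}.
#' @param path file path.
#' @return \code{design_from_json} returns a \code{synthetic_design};
#'   \code{design_to_json} returns \code{path} invisibly.
#' @export
design_to_json <- function(design, path) {
  out <- unclass(design)
  out$species <- lapply(out$species, function(sp) {
    list(model_id = sp$model_id, params = as.list(sp$params))
  })
  out$treatments <- lapply(out$treatments, unclass)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname design_to_json
#' @export
design_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  species <- lapply(raw$species, function(sp) {
    list(model_id = sp$model_id, params = unlist(sp$params))
  })
  treatments <- lapply(raw$treatments, function(s) {
    treatment_schedule(s$label, s$winter_offset, s$spring_offset,
                       s$winter_start, s$transfer_day)
  })
  names(treatments) <- vapply(treatments, function(s) s$label, character(1))
  synthetic_design(species = species, treatments = treatments,
                   chambers_per_treatment = raw$chambers_per_treatment,
                   saplings_per_chamber = raw$saplings_per_chamber,
                   sapling_jitter_sd = raw$sapling_jitter_sd,
                   chamber_jitter_sd = raw$chamber_jitter_sd,
                   monitoring_interval = raw$monitoring_interval,
                   monitoring_start = raw$monitoring_start,
                   seed = raw$seed)
}
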