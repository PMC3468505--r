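#' Daily mean temperature series
#'
#' Container for an ordered sequence of daily mean air temperatures on the
#' fixed day axis (see \code{\link{day_anchors}}).
#'
#' @param temps numeric vector of mean daily air temperature (degrees C);
#'   must be non-empty and finite (no gaps within the support).
#' @param start_index integer day index of the first element (1 =
#'   1 September of the year preceding budburst).
#' @return An object of class \code{temperature_series}: a list with fields
#'   \code{start_index} and \code{temps}.
#' @examples
#' s <- temperature_series(rep(5, 10))
#' series_days(s)
#' @export
temperature_series <- function(temps, start_index = 1L) {
  if (length(temps) == 0L) {
    bb_stop("temps must be non-empty", "bb_validation_error")
  }
  temps <- as.numeric(temps)
  if (anyNA(temps) || !all(is.finite(temps))) {
    bb_stop("temps must contain no missing or non-finite values",
            "bb_validation_error")
  }
  if (length(start_index) != 1L || !is.finite(start_index)) {
    bb_stop("start_index must be a single finite integer", "bb_validation_error")
  }
  structure(list(start_index = as.integer(start_index), temps = temps),
            class = "temperature_series")
}

#' @rdname temperature_series
#' @param series a \code{temperature_series}.
#' @return \code{series_days}: the integer day indices covered by the series.
#' @export
series_days <- function(series) {
  seq.int(series$start_index, length.out = length(series$temps))
}

#' @export
print.temperature_series <- function(x, ...) {
  d <- series_days(x)
  cat(sprintf(
    "<temperature_series> days %d..%d (n = %d), mean %.2f degC, range [%.2f, %.2f]\n",
    d[1], d[length(d)], length(d), mean(x$temps), min(x$temps), max(x$temps)))
  invisible(x)
}

# Extract temperatures for day indices start..end (inclusive).
series_window <- function(series, start, end) {
  d0 <- series$start_index
  n <- length(series$temps)
  if (start < d0 || end > d0 + n - 1L || start > end) {
    bb_stop(sprintf("window [%d, %d] outside series support [%d, %d]",
                    start, end, d0, d0 + n - 1L), "bb_range_error")
  }
  series$temps[(start - d0 + 1L):(end - d0 + 1L)]
}

#' Configuration of the synthetic climate generator
#'
#' The generator emulates a mild maritime (Belgian) climate as an annual
#' sinusoid plus AR(1) day-to-day noise.  Defaults reproduce the site
#' climatology: 9.6 degC annual mean and monthly means from 2.2 degC
#' (January) to 17.0 degC (July), hence an amplitude of (17.0 - 2.2)/2 =
#' 7.4 degC with the coldest day in mid January.
#'
#' @param annual_mean annual mean temperature, degrees C.
#' @param annual_amplitude half-range of the annual cycle, degrees C.
#' @param coldest_day_index day index on which the sinusoid minimum falls
#'   (default 137 = 15 January).
#' @param ar1_coefficient lag-1 autocorrelation of the noise, in [0, 1);
#'   default 0.7 gives the day-to-day persistence typical of mid-latitude
#'   weather.
#' @param noise_sd marginal standard deviation of the noise, degrees C
#'   (>= 0).
#' @param seed integer seed; synthesis is bit-reproducible given the seed.
#' @return An object of class \code{climate_config}.
#' @export
climate_config <- function(annual_mean = 9.6, annual_amplitude = 7.4,
                           coldest_day_index = 137L, ar1_coefficient = 0.7,
                           noise_sd = 3.0, seed = 1L) {
  vals <- c(annual_mean, annual_amplitude, coldest_day_index,
            ar1_coefficient, noise_sd, seed)
  if (!all(is.finite(vals))) {
    bb_stop("climate_config values must all be finite", "bb_validation_error")
  }
  if (noise_sd < 0) {
    bb_stop("noise_sd must be >= 0", "bb_validation_error")
  }
  if (abs(ar1_coefficient) >= 1) {
    bb_stop("|ar1_coefficient| must be < 1", "bb_validation_error")
  }
  structure(list(annual_mean = annual_mean,
                 annual_amplitude = annual_amplitude,
                 coldest_day_index = as.integer(coldest_day_index),
                 ar1_coefficient = ar1_coefficient,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "climate_config")
}

#' Synthesize a daily temperature series
#'
#' Generates \code{n_days} of daily mean temperature starting at day index 1
#' (1 September): an annual cosine with its minimum on
#' \code{coldest_day_index}, plus stationary AR(1) noise with marginal
#' standard deviation \code{noise_sd}.
#'
#' @param config a \code{\link{climate_config}}.
#' @param n_days number of days to generate (>= 1).
#' @return A \code{\link{temperature_series}} starting at index 1.
#' @examples
#' s <- synthesize_daily_temperature(climate_config(noise_sd = 0), 365)
#' mean(s$temps)  # 9.6
#' @export
synthesize_daily_temperature <- function(config, n_days) {
  if (!inherits(config, "climate_config")) {
    bb_stop("config must be a climate_config", "bb_validation_error")
  }
  if (n_days < 1) {
    bb_stop("n_days must be >= 1", "bb_validation_error")
  }
  n_days <- as.integer(n_days)
  d <- seq_len(n_days)
  base <- config$annual_mean -
    config$annual_amplitude * cos(2 * pi * (d - config$coldest_day_index) / 365)
  if (config$noise_sd > 0) {
    phi <- config$ar1_coefficient
    e <- with_seed(config$seed, {
      z <- rnorm(n_days)
      out <- numeric(n_days)
      out[1] <- config$noise_sd * z[1]
      innov_sd <- sqrt(1 - phi^2) * config$noise_sd
      for (i in seq_len(n_days)[-1]) {
        out[i] <- phi * out[i - 1] + innov_sd * z[i]
      }
      out
    })
    base <- base + e
  }
  temperature_series(base, start_index = 1L)
}

#' Chamber warming treatment schedule
#'
#' A treatment adds a constant winter offset on
#' \code{[winter_start, transfer_day)} and a spring offset from
#' \code{transfer_day} onward (the transfer day itself counts as spring: the
#' saplings were moved on that day, so its exposure is post-move).
#'
#' @param label treatment name, e.g. \code{"W6S0"} (winter +6 degC, spring
#'   +0 degC).
#' @param winter_offset degrees C added on \code{[winter_start, transfer_day)}.
#' @param spring_offset degrees C added from \code{transfer_day} to the end
#'   of the series.
#' @param winter_start day index of the warming start (default 92 =
#'   1 December).
#' @param transfer_day day index of the chamber transfer (default 175 =
#'   22 February).
#' @return An object of class \code{treatment_schedule}.
#' @export
treatment_schedule <- function(label, winter_offset, spring_offset,
                               winter_start = 92L, transfer_day = 175L) {
  if (!is.finite(winter_offset) || !is.finite(spring_offset)) {
    bb_stop("treatment offsets must be finite", "bb_validation_error")
  }
  if (winter_start >= transfer_day) {
    bb_stop("winter_start must be < transfer_day", "bb_validation_error")
  }
  structure(list(label = as.character(label),
                 winter_offset = as.numeric(winter_offset),
                 spring_offset = as.numeric(spring_offset),
                 winter_start = as.integer(winter_start),
                 transfer_day = as.integer(transfer_day)),
            class = "treatment_schedule")
}

#' The factorial warming treatments of the chamber experiment
#'
#' Seven treatments: the 2x2 factorial W0S0 / W6S0 / W0S6 / W6S6 (winter
#' warming 1 December -- 22 February, spring warming 22 February onward) and
#' the auxiliary +2 degC winter treatments W2S0 / W2S2 / W2S6.
#'
#' @param winter_start,transfer_day day indices passed to
#'   \code{\link{treatment_schedule}}.
#' @return Named list of \code{treatment_schedule} objects.
#' @export
standard_treatments <- function(winter_start = 92L, transfer_day = 175L) {
  defs <- list(W0S0 = c(0, 0), W6S0 = c(6, 0), W0S6 = c(0, 6), W6S6 = c(6, 6),
               W2S0 = c(2, 0), W2S2 = c(2, 2), W2S6 = c(2, 6))
  out <- lapply(names(defs), function(lab) {
    treatment_schedule(lab, defs[[lab]][1], defs[[lab]][2],
                       winter_start = winter_start,
                       transfer_day = transfer_day)
  })
  names(out) <- names(defs)
  out
}

#' Apply a warming treatment to a temperature series
#'
#' Returns a new series with the schedule's winter offset added on
#' \code{[winter_start, transfer_day)} and the spring offset from
#' \code{transfer_day} to the end of the series; days before
#' \code{winter_start} are unchanged.  The input series is not modified.
#'
#' @param series a \code{\link{temperature_series}} whose support contains
#'   the schedule window.
#' @param schedule a \code{\link{treatment_schedule}}.
#' @return A new \code{temperature_series} on the same day axis.
#' @export
apply_treatment <- function(series, schedule) {
  if (!inherits(series, "temperature_series") ||
      !inherits(schedule, "treatment_schedule")) {
    bb_stop("apply_treatment needs a temperature_series and a treatment_schedule",
            "bb_validation_error")
  }
  d <- series_days(series)
  last <- d[length(d)]
  if (schedule$winter_start < d[1] || schedule$transfer_day > last) {
    bb_stop(sprintf(
      "schedule window [%d, %d] outside series support [%d, %d]",
      schedule$winter_start, schedule$transfer_day, d[1], last),
      "bb_range_error")
  }
  offsets <- numeric(length(d))
  offsets[d >= schedule$winter_start & d < schedule$transfer_day] <-
    schedule$winter_offset
  offsets[d >= schedule$transfer_day] <- schedule$spring_offset
  temperature_series(series$temps + offsets, start_index = series$start_index)
}

#' Mean warming experienced over a window
#'
#' Arithmetic mean of (treated - control) over day indices
#' \code{[start, end]}, inclusive: the "delta temperature" of the
#' sensitivity analysis (conventionally 1 December to the day of observed
#' budburst).
#'
#' @param treated,control \code{\link{temperature_series}} objects covering
#'   the window.
#' @param start,end day indices, \code{start <= end}.
#' @return Mean warming, degrees C.
#' @export
mean_warming_delta <- function(treated, control, start, end) {
  if (start > end) {
    bb_stop("start must be <= end", "bb_validation_error")
  }
  a <- tryCatch(series_window(treated, start, end),
                bb_range_error = function(e) {
                  bb_stop(paste0("treated series: ", conditionMessage(e)),
                          "bb_alignment_error")
                })
  b <- tryCatch(series_window(control, start, end),
                bb_range_error = function(e) {
                  bb_stop(paste0("control series: ", conditionMessage(e)),
                          "bb_alignment_error")
                })
  mean(a - b)
}

#' Read and write daily temperature CSV files
#'
#' The file has a header and two columns: \code{day_index} (integer) or
#' \code{date} (ISO-8601, mapped so that 1 September = index 1) plus
#' \code{tmean_c} (degrees C).  Temperatures are written with 17 significant
#' digits so that \code{read_temperature_csv(write_temperature_csv(s))}
#' reproduces \code{s} exactly.
#'
#' @param path file path.
#' @param series a \code{\link{temperature_series}}.
#' @return \code{read_temperature_csv} returns a \code{temperature_series};
#'   \code{write_temperature_csv} returns \code{path} invisibly.
#' @export
read_temperature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("tmean_c" %in% names(df))) {
    bb_stop("temperature CSV must have a tmean_c column", "bb_parse_error")
  }
  if ("day_index" %in% names(df)) {
    idx <- suppressWarnings(as.integer(df$day_index))
  } else if ("date" %in% names(df)) {
    dates <- as.Date(df$date)
    if (anyNA(dates)) {
      bad <- which(is.na(dates))[1]
      bb_stop(sprintf("unparseable date at data line %d", bad), "bb_parse_error")
    }
    if (any(format(dates, "%m-%d") == "02-29")) {
      bb_stop("leap days are not supported on the 365-day axis", "bb_parse_error")
    }
    first <- dates[1]
    yr <- as.integer(format(first, "%Y"))
    if (as.integer(format(first, "%m")) < 9L) yr <- yr - 1L
    anchor <- as.Date(sprintf("%d-09-01", yr))
    idx <- as.integer(dates - anchor) + 1L
  } else {
    bb_stop("temperature CSV must have a day_index or date column",
            "bb_parse_error")
  }
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    bb_stop(sprintf("unparseable day_index at data line %d", bad),
            "bb_parse_error")
  }
  if (anyDuplicated(idx)) {
    dup <- idx[duplicated(idx)][1]
    bb_stop(sprintf("duplicate day_index %d", dup), "bb_parse_error")
  }
  if (length(idx) > 1L && any(diff(idx) != 1L)) {
    gap_at <- which(diff(idx) != 1L)[1]
    bb_stop(sprintf("missing day %d in temperature CSV", idx[gap_at] + 1L),
            "bb_parse_error")
  }
  tm <- suppressWarnings(as.numeric(df$tmean_c))
  if (anyNA(tm)) {
    bad <- which(is.na(tm))[1]
    bb_stop(sprintf("unparseable tmean_c at data line %d", bad),
            "bb_parse_error")
  }
  temperature_series(tm, start_index = idx[1])
}

#' @rdname read_temperature_csv
#' @export
write_temperature_csv <- function(series, path) {
  lines <- c("day_index,tmean_c",
             sprintf("%d,%.17g", series_days(series), series$temps))
  writeLines(lines, path)
  invisible(path)
}
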