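#' Goodness-of-fit statistics for budburst predictions
#'
#' \code{rmse}: root mean square error, days.
#' \code{model_efficiency}: Nash--Sutcliffe model efficiency,
#' \code{1 - RSS / TSS}; 1 = perfect, 0 = no better than predicting the
#' observed mean, negative = worse than the mean.
#' \code{aic}: Akaike's information criterion in the residual-sum-of-squares
#' form \code{t ln(rss / t) + 2 (n_params + 1)} (the "+1" counts the
#' residual variance).
#'
#' @param observed,predicted numeric vectors of budburst days, equal
#'   length, no missing values.  If NONE predictions occur, replace them by
#'   the horizon day before scoring (\code{\link{cross_validate}} does this
#'   and flags the rows).
#' @param rss residual sum of squares, days^2 (> 0: a perfect fit has no
#'   defined AIC under this form).
#' @param t number of observations (> \code{n_params + 1}).
#' @param n_params number of model parameters (see
#'   \code{\link{model_spec}}).
#' @return Scalar statistic.
#' @name fit_statistics
NULL

check_pair <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    bb_stop("observed and predicted must have equal length",
            "bb_validation_error")
  }
  if (length(observed) == 0L) {
    bb_stop("need at least one observation", "bb_validation_error")
  }
  if (anyNA(observed) || anyNA(predicted)) {
    bb_stop(paste("missing values present; replace NONE predictions by the",
                  "horizon day (index 303) before scoring"),
            "bb_validation_error")
  }
}

#' @rdname fit_statistics
#' @export
rmse <- function(observed, predicted) {
  check_pair(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' @rdname fit_statistics
#' @export
model_efficiency <- function(observed, predicted) {
  check_pair(observed, predicted)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) {
    bb_stop("model efficiency undefined: observed values are all equal",
            "bb_validation_error")
  }
  1 - sum((observed - predicted)^2) / tss
}

#' @rdname fit_statistics
#' @export
aic <- function(rss, t, n_params) {
  if (rss <= 0) {
    bb_stop("AIC undefined for a perfect fit (rss must be > 0)",
            "bb_validation_error")
  }
  if (t <= n_params + 1) {
    bb_stop("AIC requires more observations than parameters + 1",
            "bb_validation_error")
  }
  t * log(rss / t) + 2 * (n_params + 1)
}

#' Split an observation set into calibration and validation halves
#'
#' Seed-reproducible random split, stratified by species x treatment so
#' that every treatment appears in both halves whenever it has at least two
#' saplings; a single-sapling stratum goes to the training half with a
#' warning.
#'
#' @param observations observation data frame.
#' @param fraction training fraction, in (0, 1).
#' @param seed integer seed.
#' @return List with data frames \code{train} and \code{test}; the two are
#'   disjoint and their union is the input.
#' @export
split_dataset <- function(observations, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    bb_stop("fraction must be in (0, 1)", "bb_validation_error")
  }
  obs <- as_observation_frame(observations)
  strata <- if ("species" %in% names(obs)) {
    interaction(obs$species, obs$treatment, drop = TRUE)
  } else {
    factor(obs$treatment)
  }
  idx_by <- split(seq_len(nrow(obs)), strata)
  train_idx <- with_seed(seed, {
    unlist(lapply(idx_by, function(ix) {
      n <- length(ix)
      if (n == 1L) {
        warning("stratum with a single sapling assigned to the training half",
                call. = FALSE)
        return(ix)
      }
      n_train <- min(max(1L, as.integer(round(n * fraction))), n - 1L)
      sample(ix, n_train)
    }), use.names = FALSE)
  })
  list(train = obs[sort(train_idx), , drop = FALSE],
       test = obs[sort(setdiff(seq_len(nrow(obs)), train_idx)), ,
                  drop = FALSE])
}

#' Predict budburst for every observation row
#'
#' Applies a fitted model to each observation's treatment series.  NONE
#' predictions are replaced by the horizon day and flagged, so scoring
#' stays total while heavily penalizing chilling-failure misfits.
#'
#' @inheritParams log_likelihood
#' @return The observation frame with columns \code{predicted} (day index)
#'   and \code{pred_none} (logical flag) appended.
#' @export
predict_observations <- function(spec, params, observations,
                                 series_by_treatment, horizon = 303L) {
  if (is.character(spec)) spec <- model_spec(spec)
  obs <- as_observation_frame(observations)
  p <- parameter_vector(spec, params)
  trts <- unique(obs$treatment)
  missing <- setdiff(trts, names(series_by_treatment))
  if (length(missing)) {
    bb_stop(sprintf("no temperature series for treatment(s): %s",
                    paste(missing, collapse = ", ")), "bb_lookup_error")
  }
  pred_by_trt <- vapply(trts, function(trt) {
    .predict_bb_day(spec$model_id, p, series_by_treatment[[trt]]$temps,
                    horizon)
  }, integer(1))
  names(pred_by_trt) <- trts
  obs$predicted <- unname(pred_by_trt[obs$treatment])
  obs$pred_none <- is.na(obs$predicted)
  obs$predicted[obs$pred_none] <- horizon
  obs
}

# Metric block shared by cross_validate and the pipeline.  AIC is reported
# as NA (flagged) when the fit is numerically perfect, since the RSS form
# is undefined at rss = 0.
evaluation_metrics <- function(observed, predicted, n_params,
                               with_aic = TRUE) {
  check_pair(observed, predicted)
  t <- length(observed)
  rss <- sum((observed - predicted)^2)
  out <- list(n = t, rmse = sqrt(rss / t),
              me = model_efficiency(observed, predicted),
              pearson_r = if (stats::sd(predicted) > 0)
                stats::cor(observed, predicted) else NA_real_,
              aic = NA_real_, aic_note = NA_character_)
  if (with_aic) {
    out$aic <- tryCatch(aic(rss, t, n_params),
                        bb_validation_error = function(e) NA_real_)
    if (is.na(out$aic) && rss == 0) out$aic_note <- "undefined-perfect-fit"
  }
  out
}

#' Internal or external validation of one model
#'
#' Internal mode calibrates and scores on the full observation set (and
#' reports AIC, which is defined for whole-dataset fits); external mode
#' calibrates on a random stratified half and scores on the held-out half.
#'
#' @inheritParams metropolis_hastings
#' @param mode \code{"internal"} or \code{"external"}.
#' @param config an \code{\link{mcmc_config}}.
#' @param fraction training fraction for the external split.
#' @return List with \code{metrics} (one-row data frame: model, mode, n,
#'   rmse, me, aic, pearson_r, n_none), \code{chain}, \code{fit} (best-fit
#'   parameters) and \code{predictions} (scored rows with predictions).
#' @export
cross_validate <- function(spec, observations, series_by_treatment,
                           mode = c("internal", "external"),
                           config = mcmc_config(), fraction = 0.5,
                           horizon = 303L) {
  if (is.character(spec)) spec <- model_spec(spec)
  mode <- match.arg(mode)
  obs <- as_observation_frame(observations)
  if (mode == "internal") {
    fit_obs <- obs
    score_obs <- obs
  } else {
    halves <- split_dataset(obs, fraction = fraction,
                            seed = derive_seed(config$seed, 17L))
    fit_obs <- halves$train
    score_obs <- halves$test
  }
  chain <- metropolis_hastings(spec, fit_obs, series_by_treatment,
                               config = config, horizon = horizon)
  fit <- best_fit(chain)
  scored <- predict_observations(spec, fit, score_obs, series_by_treatment,
                                 horizon = horizon)
  m <- evaluation_metrics(scored$bb_index, scored$predicted,
                          spec$n_parameters,
                          with_aic = (mode == "internal"))
  metrics <- data.frame(model = spec$model_id, mode = mode, n = m$n,
                        rmse = m$rmse, me = m$me, aic = m$aic,
                        pearson_r = m$pearson_r,
                        n_none = sum(scored$pred_none),
                        stringsAsFactors = FALSE)
  list(metrics = metrics, chain = chain, fit = fit, predictions = scored)
}

#' Mean warming experienced by each treatment
#'
#' The "delta temperature" of the sensitivity analysis: for each treatment,
#' the mean difference between the treatment and control series from
#' 1 December (index 92) to the treatment's mean observed budburst day.
#'
#' @param observations observation data frame.
#' @param series_by_treatment named list of \code{temperature_series}.
#' @param control_label label of the unwarmed control treatment.
#' @param start day index starting the averaging window (default 92 =
#'   1 December).
#' @return Named numeric vector of mean warming per treatment, degrees C.
#' @export
observed_warming_deltas <- function(observations, series_by_treatment,
                                    control_label = "W0S0", start = 92L) {
  obs <- as_observation_frame(observations)
  trts <- unique(obs$treatment)
  if (!(control_label %in% trts)) {
    bb_stop(sprintf("control treatment '%s' absent from observations",
                    control_label), "bb_validation_error")
  }
  control <- series_by_treatment[[control_label]]
  out <- vapply(trts, function(trt) {
    end <- as.integer(round(mean(obs$bb_index[obs$treatment == trt])))
    mean_warming_delta(series_by_treatment[[trt]], control, start, end)
  }, numeric(1))
  names(out) <- trts
  out
}

#' Temperature sensitivity of budburst advancement
#'
#' For each species, regresses the mean budburst advancement of each
#' treatment (treatment mean minus control mean, days; negative = earlier)
#' on the mean warming it experienced (delta-T, degrees C).  The slope, in
#' days per degree C, is the temperature sensitivity; warming-advanced
#' budburst gives a negative slope.  The regression is unweighted through
#' the treatment means.
#'
#' @param observations observation data frame (columns species, treatment,
#'   bb_index or budburst_doy).
#' @param delta_T_by_treatment named numeric vector of mean warming per
#'   treatment (see \code{\link{observed_warming_deltas}}); needs >= 2
#'   distinct values.
#' @param control_label label of the control treatment (delta-T 0,
#'   advancement 0 by construction).
#' @return An object of class \code{sensitivity_result}: list with
#'   \code{slopes} (data frame species, slope) and \code{treatments}
#'   (data frame species, treatment, delta_T, advancement, mean_bb_doy).
#' @examples
#' obs <- data.frame(species = "birch",
#'                   treatment = rep(c("W0S0", "W6S6"), each = 3),
#'                   bb_index = c(220, 221, 219, 199, 200, 198))
#' sensitivity_slope(obs, c(W0S0 = 0, W6S6 = 6))$slopes$slope  # -3.5
#' @export
sensitivity_slope <- function(observations, delta_T_by_treatment,
                              control_label = "W0S0") {
  obs <- as_observation_frame(observations)
  if (!("species" %in% names(obs))) obs$species <- "all"
  if (!(control_label %in% obs$treatment)) {
    bb_stop(sprintf("control treatment '%s' absent from observations",
                    control_label), "bb_validation_error")
  }
  trts <- unique(obs$treatment)
  missing <- setdiff(trts, names(delta_T_by_treatment))
  if (length(missing)) {
    bb_stop(sprintf("no delta_T for treatment(s): %s",
                    paste(missing, collapse = ", ")), "bb_lookup_error")
  }
  if (length(unique(delta_T_by_treatment[trts])) < 2L) {
    bb_stop("sensitivity regression is singular: all delta_T equal",
            "bb_validation_error")
  }
  rows <- list(); slopes <- list()
  for (sp in unique(obs$species)) {
    sub <- obs[obs$species == sp, ]
    means <- tapply(sub$bb_index, sub$treatment, mean)
    adv <- means - means[[control_label]]
    dt <- delta_T_by_treatment[names(means)]
    fit <- stats::lm(adv ~ dt)
    slopes[[sp]] <- data.frame(species = sp,
                               slope = unname(stats::coef(fit)[2]),
                               stringsAsFactors = FALSE)
    rows[[sp]] <- data.frame(species = sp, treatment = names(means),
                             delta_T = unname(dt),
                             advancement = unname(adv),
                             mean_bb_doy = unname(index_to_doy(round(means))),
                             stringsAsFactors = FALSE)
  }
  structure(list(slopes = do.call(rbind, c(slopes, make.row.names = FALSE)),
                 treatments = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> slopes (days per degC):\n")
  print(x$slopes, row.names = FALSE)
  invisible(x)
}
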