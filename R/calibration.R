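#' MCMC configuration for Metropolis--Hastings calibration
#'
#' @param n_iterations total chain length.
#' @param burn_in iterations discarded (and, if \code{adapt}, used to tune
#'   proposal scales); must be < \code{n_iterations}.
#' @param proposal_scales optional named per-parameter proposal standard
#'   deviations; default 5\% of each flat-prior range.
#' @param seed integer seed; chains are exactly reproducible given seed and
#'   config.
#' @param adapt tune proposal scales during burn-in towards the target
#'   acceptance rate (the post-burn-in kernel is fixed, so the retained
#'   chain is valid MH).
#' @param thin keep every \code{thin}-th post-burn-in sample.
#' @param sigma fixed residual standard deviation (days); if \code{NULL}
#'   (default) sigma is calibrated as a nuisance parameter with a flat
#'   prior on \code{sigma_bounds}.
#' @param sigma_bounds flat-prior interval for the calibrated sigma, days.
#' @param adapt_interval iterations between scale updates during burn-in.
#' @param target_acceptance acceptance rate targeted by adaptation.
#' @param init optional named vector of starting values.
#' @param n_starts when \code{init} is NULL, number of uniform draws scored
#'   (in addition to the box midpoint) to pick the chain's starting point.
#' @return An object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_iterations = 50000L, burn_in = 10000L,
                        proposal_scales = NULL, seed = 1L, adapt = TRUE,
                        thin = 1L, sigma = NULL, sigma_bounds = c(0.1, 20),
                        adapt_interval = 100L, target_acceptance = 0.3,
                        init = NULL, n_starts = 200L) {
  if (burn_in >= n_iterations) {
    bb_stop("burn_in must be < n_iterations", "bb_validation_error")
  }
  if (!is.null(proposal_scales) && any(proposal_scales <= 0)) {
    bb_stop("proposal_scales must be > 0", "bb_validation_error")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 proposal_scales = proposal_scales, seed = as.integer(seed),
                 adapt = isTRUE(adapt), thin = as.integer(thin),
                 sigma = sigma, sigma_bounds = sigma_bounds,
                 adapt_interval = as.integer(adapt_interval),
                 target_acceptance = target_acceptance, init = init,
                 n_starts = as.integer(n_starts)),
            class = "mcmc_config")
}

#' Gaussian log-likelihood of budburst observations
#'
#' Sum over observations of the Gaussian log-density of
#' (observed - predicted) budburst day with standard deviation
#' \code{sigma}.  Any \code{NONE} prediction yields \code{-Inf}, so such a
#' proposal is rejected by the sampler.
#'
#' @param spec a \code{\link{model_spec}} or model id.
#' @param params named parameter vector.
#' @param sigma residual standard deviation, days (> 0).
#' @param observations an observation set (data frame with columns
#'   \code{treatment} and \code{bb_index} or \code{budburst_doy}).
#' @param series_by_treatment named list of \code{temperature_series}, one
#'   per treatment label appearing in \code{observations}.
#' @param horizon prediction horizon day index.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(spec, params, sigma, observations,
                           series_by_treatment, horizon = 303L) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (!is.finite(sigma) || sigma <= 0) {
    bb_stop("sigma must be > 0", "bb_validation_error")
  }
  obs <- as_observation_frame(observations)
  trts <- unique(obs$treatment)
  missing <- setdiff(trts, names(series_by_treatment))
  if (length(missing)) {
    bb_stop(sprintf("no temperature series for treatment(s): %s",
                    paste(missing, collapse = ", ")), "bb_lookup_error")
  }
  p <- parameter_vector(spec, params)
  ll <- 0
  for (trt in trts) {
    pred <- .predict_bb_day(spec$model_id, p,
                            series_by_treatment[[trt]]$temps, horizon)
    if (is.na(pred)) return(-Inf)
    resid <- obs$bb_index[obs$treatment == trt] - pred
    ll <- ll + sum(stats::dnorm(resid, 0, sigma, log = TRUE))
  }
  ll
}

# Normalise an observation container to a data frame with treatment and
# bb_index columns.
as_observation_frame <- function(observations) {
  obs <- as.data.frame(observations)
  if (!("bb_index" %in% names(obs))) {
    if (!("budburst_doy" %in% names(obs))) {
      bb_stop("observations need a bb_index or budburst_doy column",
              "bb_validation_error")
    }
    obs$bb_index <- doy_to_index(obs$budburst_doy)
  }
  if (!("treatment" %in% names(obs))) {
    bb_stop("observations need a treatment column", "bb_validation_error")
  }
  obs
}

#' Random-walk Metropolis sampler on a box support
#'
#' General-purpose Metropolis--Hastings random walk with independent
#' Gaussian proposals per coordinate and a flat prior on a finite box:
#' proposals outside the box (or for which \code{support} returns FALSE)
#' are rejected outright, otherwise acceptance probability is
#' \code{min(1, exp(l' - l))}.
#'
#' @param log_post function taking a named parameter vector, returning the
#'   log target density (up to a constant); \code{-Inf} allowed.
#' @param bounds matrix (parameters x \code{lower}, \code{upper}) with
#'   finite entries; rownames are the parameter names.
#' @param config an \code{\link{mcmc_config}}.
#' @param support optional extra indicator function of the parameter vector
#'   (e.g. ordering constraints); part of the flat prior.
#' @return List with \code{samples} (matrix, post burn-in), \code{log_lik},
#'   \code{acceptance_rate} (post burn-in), \code{scales} (final proposal
#'   scales), \code{best_index}.
#' @export
mh_sample <- function(log_post, bounds, config = mcmc_config(),
                      support = NULL) {
  k <- nrow(bounds)
  nm <- rownames(bounds)
  rng <- bounds[, "upper"] - bounds[, "lower"]
  scales <- config$proposal_scales
  if (is.null(scales)) scales <- 0.05 * rng
  scales <- rep_len(scales, k)
  names(scales) <- nm
  in_box <- function(x) {
    all(x >= bounds[, "lower"]) && all(x <= bounds[, "upper"]) &&
      (is.null(support) || isTRUE(support(x)))
  }
  with_seed(config$seed, {
    x <- config$init
    if (is.null(x)) {
      # Best-of-N start: score the box midpoint plus uniform draws and walk
      # from the best, which keeps the chain out of flat -Inf regions and
      # multimodal traps.
      x <- (bounds[, "lower"] + bounds[, "upper"]) / 2
      names(x) <- nm
      ll <- if (in_box(x)) log_post(x) else -Inf
      for (i in seq_len(config$n_starts)) {
        cand <- bounds[, "lower"] + stats::runif(k) * rng
        names(cand) <- nm
        if (in_box(cand)) {
          llc <- log_post(cand)
          if (llc > ll || !is.finite(ll)) {
            x <- cand
            ll <- llc
          }
        }
      }
    } else {
      ll <- if (in_box(x)) log_post(x) else -Inf
    }
    tries <- 0L
    while (!is.finite(ll) && tries < 100L) {
      x <- bounds[, "lower"] + stats::runif(k) * rng
      names(x) <- nm
      if (in_box(x)) ll <- log_post(x)
      tries <- tries + 1L
    }
    if (!is.finite(ll)) {
      bb_stop("could not find a starting point with finite posterior in 100 draws",
              "bb_state_error")
    }
    n_keep <- (config$n_iterations - config$burn_in) %/% config$thin
    samples <- matrix(NA_real_, n_keep, k, dimnames = list(NULL, nm))
    log_lik <- numeric(n_keep)
    kept <- 0L
    acc_post <- 0L; n_post <- 0L
    acc_win <- 0L
    for (it in seq_len(config$n_iterations)) {
      prop <- x + stats::rnorm(k, 0, scales)
      accept <- FALSE
      if (in_box(prop)) {
        llp <- log_post(prop)
        if (is.finite(llp) && log(stats::runif(1)) < llp - ll) {
          x <- prop; ll <- llp; accept <- TRUE
        }
      }
      if (it <= config$burn_in) {
        acc_win <- acc_win + accept
        if (config$adapt && it %% config$adapt_interval == 0L) {
          rate <- acc_win / config$adapt_interval
          scales <- pmin(pmax(scales * exp(rate - config$target_acceptance),
                              1e-6 * rng), rng)
          acc_win <- 0L
        }
      } else {
        n_post <- n_post + 1L
        acc_post <- acc_post + accept
        if ((it - config$burn_in) %% config$thin == 0L) {
          kept <- kept + 1L
          samples[kept, ] <- x
          log_lik[kept] <- ll
        }
      }
    }
    samples <- samples[seq_len(kept), , drop = FALSE]
    log_lik <- log_lik[seq_len(kept)]
    list(samples = samples, log_lik = log_lik,
         acceptance_rate = if (n_post > 0L) acc_post / n_post else NA_real_,
         scales = scales, best_index = which.max(log_lik))
  })
}

#' Calibrate a budburst model by Metropolis--Hastings
#'
#' Bayesian calibration of a model against budburst observations: flat
#' priors on the parameter box (\code{\link{default_parameter_bounds}} by
#' default), Gaussian residual likelihood (\code{\link{log_likelihood}}),
#' random-walk proposals.  The residual standard deviation \code{sigma} is
#' calibrated alongside the model parameters unless fixed in the config.
#' Day-valued parameters (t1f, t2c) are proposed continuously and rounded
#' at evaluation time, keeping the walk on a connected support.
#'
#' @inheritParams log_likelihood
#' @param bounds optional bounds matrix for the calibrated parameters
#'   (rows named); defaults to the spec's shipped bounds.
#' @param config an \code{\link{mcmc_config}}.
#' @return An object of class \code{calibration_chain}: list with
#'   \code{model_id}, \code{samples} (post burn-in, within prior bounds),
#'   \code{log_lik}, \code{acceptance_rate}, \code{best_index},
#'   \code{fixed} (non-calibrated parameters), \code{bounds},
#'   \code{config}, \code{n_obs}.
#' @export
metropolis_hastings <- function(spec, observations, series_by_treatment,
                                bounds = NULL, config = mcmc_config(),
                                horizon = 303L) {
  if (is.character(spec)) spec <- model_spec(spec)
  obs <- as_observation_frame(observations)
  trts <- unique(obs$treatment)
  missing <- setdiff(trts, names(series_by_treatment))
  if (length(missing)) {
    bb_stop(sprintf("no temperature series for treatment(s): %s",
                    paste(missing, collapse = ", ")), "bb_lookup_error")
  }
  cal_names <- spec$parameter_names[spec$calibrated]
  if (is.null(bounds)) {
    bounds <- spec$bounds[cal_names, , drop = FALSE]
  }
  if (!all(is.finite(bounds))) {
    bb_stop("calibration bounds must be finite", "bb_validation_error")
  }
  calibrate_sigma <- is.null(config$sigma)
  if (calibrate_sigma) {
    bounds <- rbind(bounds, sigma = config$sigma_bounds)
  }
  fixed <- spec$defaults[!spec$calibrated]

  # Pre-split observations by treatment for a fast likelihood.
  temps_by_trt <- lapply(series_by_treatment[trts], function(s) {
    if (s$start_index != 1L || length(s$temps) < horizon) {
      bb_stop("treatment series must start at index 1 and cover the horizon",
              "bb_range_error")
    }
    s$temps
  })
  obs_by_trt <- split(obs$bb_index, factor(obs$treatment, levels = trts))
  model_id <- spec$model_id
  full <- spec$defaults

  log_post <- function(x) {
    sigma <- if (calibrate_sigma) x[["sigma"]] else config$sigma
    full[cal_names] <- x[cal_names]
    ll <- 0
    for (trt in trts) {
      pred <- .predict_bb_day(model_id, full, temps_by_trt[[trt]], horizon)
      if (is.na(pred)) return(-Inf)
      r <- obs_by_trt[[trt]] - pred
      ll <- ll - length(r) * (log(sigma) + 0.5 * log(2 * pi)) -
        sum(r * r) / (2 * sigma^2)
    }
    ll
  }
  support <- function(x) {
    full[cal_names] <- x[cal_names]
    parameters_valid(spec, full)
  }
  res <- mh_sample(log_post, bounds, config, support = support)
  structure(list(model_id = model_id, samples = res$samples,
                 log_lik = res$log_lik,
                 acceptance_rate = res$acceptance_rate,
                 best_index = res$best_index, fixed = fixed,
                 bounds = bounds, config = config, n_obs = nrow(obs),
                 scales = res$scales),
            class = "calibration_chain")
}

#' @export
print.calibration_chain <- function(x, ...) {
  cat(sprintf(
    "<calibration_chain> %s: %d retained samples, acceptance %.2f, max logL %.2f\n",
    x$model_id, nrow(x$samples), x$acceptance_rate,
    max(x$log_lik)))
  invisible(x)
}

#' Maximum-likelihood sample of a calibration chain
#'
#' Returns the stored sample with the highest log-likelihood (ties broken
#' by earliest iteration), merged with the model's fixed parameters.  The
#' calibrated residual sd, if any, is attached as attribute \code{sigma},
#' and the sample's log-likelihood as attribute \code{log_lik}.
#'
#' @param chain a \code{calibration_chain}.
#' @return Named numeric vector of model parameters.
#' @export
best_fit <- function(chain) {
  if (!inherits(chain, "calibration_chain") || nrow(chain$samples) == 0L) {
    bb_stop("best_fit needs a non-empty calibration chain", "bb_state_error")
  }
  i <- which.max(chain$log_lik)  # which.max returns the first maximum
  x <- chain$samples[i, ]
  sigma <- if ("sigma" %in% names(x)) unname(x[["sigma"]]) else chain$config$sigma
  params <- c(x[setdiff(names(x), "sigma")], chain$fixed)
  attr(params, "sigma") <- sigma
  attr(params, "log_lik") <- chain$log_lik[i]
  params
}

#' Export a calibration chain
#'
#' \code{write_chain_csv} writes one row per retained sample (iteration,
#' parameters, log-likelihood).  \code{write_chain_summary_json} writes the
#' best-fit parameters, acceptance rate and configuration.
#'
#' @param chain a \code{calibration_chain}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_chain_csv <- function(chain, path) {
  df <- data.frame(iteration = seq_len(nrow(chain$samples)),
                   chain$samples, log_likelihood = chain$log_lik,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain_csv
#' @export
write_chain_summary_json <- function(chain, path) {
  bf <- best_fit(chain)
  out <- list(model_id = chain$model_id,
              best_fit = as.list(bf),
              sigma = attr(bf, "sigma"),
              log_lik = attr(bf, "log_lik"),
              acceptance_rate = chain$acceptance_rate,
              n_samples = nrow(chain$samples),
              n_obs = chain$n_obs,
              seed = chain$config$seed,
              n_iterations = chain$config$n_iterations,
              burn_in = chain$config$burn_in)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
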