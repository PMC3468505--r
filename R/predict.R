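#' Predict the budburst day for one model and temperature series
#'
#' Runs the model's day loop over the series and returns the first day on
#' which the state of forcing reaches the (possibly chilling-dependent)
#' forcing requirement.  Per model:
#'
#' \describe{
#'   \item{TTM}{linear forcing \code{max(0, T - Tb)} accumulated from day
#'     \code{round(t1f)}; budburst when \code{Sf >= Fstar}.}
#'   \item{SM}{triangular chilling accumulated from 1 September; sigmoid
#'     forcing begins on the first day with \code{Sc >= Cstar} (that day
#'     inclusive); budburst when \code{Sf >= Fstar}.}
#'   \item{PM}{chilling and forcing in parallel from 1 September, the
#'     sigmoid forcing rate scaled by the competence
#'     \code{Km + (1 - Km) min(Sc / Cstar, 1)}.}
#'   \item{AM}{chill days counted from 1 November, linear forcing from
#'     1 January; budburst on the first day with
#'     \code{Sf >= a + b exp(c Sc)}, the requirement re-evaluated daily
#'     against the running \code{Sc}.}
#'   \item{UM}{unified sigmoid chilling from 1 September; unified forcing
#'     begins when \code{Sc >= Cstar}; the requirement is
#'     \code{w exp(k Sc(t2c))} with \code{Sc(t2c)} the chilling accumulated
#'     by day \code{round(t2c)}.}
#' }
#'
#' The first forcing day contributes its full rate, so with constant
#' \code{T = Tb + 1} and \code{Fstar = 10} the TTM predicts budburst on the
#' 10th forcing day.  If the requirement is never met before the horizon the
#' prediction is \code{NONE} (\code{bb_index = NA}), a first-class outcome.
#'
#' Two engines are provided: \code{"fast"} (vectorized, used everywhere) and
#' \code{"reference"} (a plain day-by-day loop).  Both perform additions in
#' the same order, so they agree exactly, not merely to tolerance.
#'
#' @param spec a \code{\link{model_spec}} or model id string.
#' @param params named parameter vector/list (see
#'   \code{\link{parameter_vector}}); missing entries take model defaults.
#' @param series a \code{\link{temperature_series}} starting at day index 1
#'   (1 September) and covering at least \code{horizon} days.
#' @param horizon last day index considered (default 303 = 30 June).
#' @param engine \code{"fast"} or \code{"reference"}.
#' @param trace if TRUE, attach per-day trajectories of Rc, Rf, Sc, Sf.
#' @return An object of class \code{budburst_prediction}: list with
#'   \code{model_id}, \code{bb_index} (NA if NONE), \code{bb_doy},
#'   \code{none}, \code{forcing_start}, \code{sc_final}, \code{sf_final}
#'   and \code{fstar} (the requirement in force on the budburst day, or at
#'   the horizon for NONE).
#' @examples
#' s <- temperature_series(rep(6, 303))
#' predict_budburst("TTM", c(t1f = 100, Tb = 5, Fstar = 10), s)$bb_index  # 109
#' @export
predict_budburst <- function(spec, params, series, horizon = 303L,
                             engine = c("fast", "reference"), trace = FALSE) {
  if (is.character(spec)) spec <- model_spec(spec)
  engine <- match.arg(engine)
  p <- parameter_vector(spec, params)
  if (!inherits(series, "temperature_series")) {
    bb_stop("series must be a temperature_series", "bb_validation_error")
  }
  if (series$start_index != 1L) {
    bb_stop("series must start at day index 1 (1 September)", "bb_range_error")
  }
  horizon <- as.integer(horizon)
  if (length(series$temps) < horizon) {
    bb_stop(sprintf("series too short: %d days, horizon %d",
                    length(series$temps), horizon), "bb_range_error")
  }
  core <- if (engine == "fast") .bb_fast else .bb_reference
  res <- core(spec$model_id, p, series$temps, horizon, trace = trace)
  structure(c(list(model_id = spec$model_id,
                   bb_index = res$bb,
                   bb_doy = if (is.na(res$bb)) NA_integer_ else index_to_doy(res$bb),
                   none = is.na(res$bb),
                   forcing_start = res$t0,
                   sc_final = res$sc_final, sf_final = res$sf_final,
                   fstar = res$fstar),
              if (trace) list(trajectory = res$trajectory)),
            class = "budburst_prediction")
}

#' @export
print.budburst_prediction <- function(x, ...) {
  if (x$none) {
    cat(sprintf("<budburst_prediction> %s: NONE before horizon (Sc %.2f, Sf %.2f, F* %.2f)\n",
                x$model_id, x$sc_final, x$sf_final, x$fstar))
  } else {
    cat(sprintf("<budburst_prediction> %s: day index %d (DOY %d), F* %.2f\n",
                x$model_id, x$bb_index, x$bb_doy, x$fstar))
  }
  invisible(x)
}

# ---- fast (vectorized) engine ----------------------------------------------

# Left-to-right cumulative sum in plain double precision.  base::cumsum
# accumulates in extended (long double) precision, which would make the
# vectorized engine differ from the reference day loop in the last bits;
# this accumulator performs exactly the additions the day loop performs.
cumsum_dbl <- function(x) {
  s <- 0
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- s + x[i]
    out[i] <- s
  }
  out
}


.bb_fast <- function(model_id, p, temps, horizon, trace = FALSE) {
  T <- temps[seq_len(horizon)]
  switch(model_id,
    TTM = {
      t1 <- as.integer(round(p[["t1f"]]))
      rf <- rate_forcing_linear(T[t1:horizon], p[["Tb"]])
      sf <- cumsum_dbl(rf)
      hit <- which(sf >= p[["Fstar"]])
      bb <- if (length(hit)) t1 - 1L + hit[1] else NA_integer_
      .bb_result(bb, t1, 0, sf, t1, p[["Fstar"]], horizon,
                 rc = NULL, rf = rf, trace = trace)
    },
    SM = {
      rc <- rate_chilling_triangular(T, p[["Tmin"]], p[["Topt"]], p[["Tmax"]])
      sc <- cumsum_dbl(rc)
      t0 <- which(sc >= p[["Cstar"]])[1]
      if (is.na(t0)) return(.bb_none(sc[horizon], 0, p[["Fstar"]],
                                     rc = rc, trace = trace, horizon = horizon))
      rf <- rate_forcing_sigmoid(T[t0:horizon], p[["a"]], p[["b"]], p[["c"]])
      sf <- cumsum_dbl(rf)
      hit <- which(sf >= p[["Fstar"]])
      bb <- if (length(hit)) t0 - 1L + hit[1] else NA_integer_
      .bb_result(bb, t0, sc, sf, t0, p[["Fstar"]], horizon,
                 rc = rc, rf = rf, trace = trace)
    },
    PM = {
      rc <- rate_chilling_triangular(T, p[["Tmin"]], p[["Topt"]], p[["Tmax"]])
      sc <- cumsum_dbl(rc)
      kf <- p[["Km"]] + (1 - p[["Km"]]) * pmin(sc / p[["Cstar"]], 1)
      rf <- rate_forcing_sigmoid(T, p[["a"]], p[["b"]], p[["c"]]) * kf
      sf <- cumsum_dbl(rf)
      hit <- which(sf >= p[["Fstar"]])
      bb <- if (length(hit)) hit[1] else NA_integer_
      .bb_result(bb, 1L, sc, sf, 1L, p[["Fstar"]], horizon,
                 rc = rc, rf = rf, trace = trace)
    },
    AM = {
      t1c <- as.integer(round(p[["t1c"]]))
      t1f <- as.integer(round(p[["t1f"]]))
      rc <- numeric(horizon)
      rc[t1c:horizon] <- rate_chilling_chill_day(T[t1c:horizon], p[["Tc"]])
      sc <- cumsum_dbl(rc)
      rf <- numeric(horizon)
      rf[t1f:horizon] <- rate_forcing_linear(T[t1f:horizon], p[["Tb"]])
      sf_tail <- cumsum_dbl(rf[t1f:horizon])
      req <- forcing_requirement_am(sc[t1f:horizon], p[["a"]], p[["b"]], p[["c"]])
      hit <- which(sf_tail >= req)
      bb <- if (length(hit)) t1f - 1L + hit[1] else NA_integer_
      fstar_at <- if (is.na(bb)) req[length(req)] else req[bb - t1f + 1L]
      .bb_result(bb, t1f, sc, sf_tail, t1f, fstar_at, horizon,
                 rc = rc, rf = rf[t1f:horizon], trace = trace)
    },
    UM = {
      rc <- rate_chilling_unified(T, p[["Ca"]], p[["Cb"]], p[["Cc"]])
      sc <- cumsum_dbl(rc)
      t2c <- min(as.integer(round(p[["t2c"]])), horizon)
      fstar <- forcing_requirement_um(sc[t2c], p[["w"]], p[["k"]])
      t0 <- which(sc >= p[["Cstar"]])[1]
      if (is.na(t0)) return(.bb_none(sc[horizon], 0, fstar,
                                     rc = rc, trace = trace, horizon = horizon))
      rf <- rate_forcing_unified(T[t0:horizon], p[["Fb"]], p[["Fc"]])
      sf <- cumsum_dbl(rf)
      hit <- which(sf >= fstar)
      bb <- if (length(hit)) t0 - 1L + hit[1] else NA_integer_
      .bb_result(bb, t0, sc, sf, t0, fstar, horizon,
                 rc = rc, rf = rf, trace = trace)
    })
}

# Package the engine output.  sc may be a trajectory (indexed by day) or a
# scalar 0 for chilling-free models; sf is the trajectory from forcing start.
.bb_result <- function(bb, t0, sc, sf, sf_from, fstar, horizon,
                       rc = NULL, rf = NULL, trace = FALSE) {
  end <- if (is.na(bb)) horizon else bb
  sc_final <- if (length(sc) > 1L) sc[end] else sc
  sf_final <- if (is.na(bb)) sf[length(sf)] else sf[bb - sf_from + 1L]
  out <- list(bb = bb, t0 = t0, sc_final = sc_final, sf_final = sf_final,
              fstar = fstar)
  if (trace) {
    out$trajectory <- list(Rc = rc, Rf = rf,
                           Sc = if (length(sc) > 1L) sc else NULL, Sf = sf)
  }
  out
}

.bb_none <- function(sc_final, sf_final, fstar, rc = NULL, trace = FALSE,
                     horizon = NA_integer_) {
  out <- list(bb = NA_integer_, t0 = NA_integer_, sc_final = sc_final,
              sf_final = sf_final, fstar = fstar)
  if (trace) out$trajectory <- list(Rc = rc, Rf = numeric(0), Sc = NULL,
                                    Sf = numeric(0))
  out
}

# ---- reference (day-by-day) engine -----------------------------------------
# A deliberately plain scalar loop mirroring the written model definitions;
# serves as the oracle for the vectorized engine.

.bb_reference <- function(model_id, p, temps, horizon, trace = FALSE) {
  T <- temps[seq_len(horizon)]
  switch(model_id,
    TTM = {
      t1 <- as.integer(round(p[["t1f"]]))
      sf <- 0
      sf_traj <- numeric(0)
      for (d in t1:horizon) {
        sf <- sf + rate_forcing_linear(T[d], p[["Tb"]])
        sf_traj <- c(sf_traj, sf)
        if (sf >= p[["Fstar"]]) {
          return(.bb_result(d, t1, 0, sf_traj, t1, p[["Fstar"]], horizon,
                            trace = trace))
        }
      }
      .bb_result(NA_integer_, t1, 0, sf_traj, t1, p[["Fstar"]], horizon,
                 trace = trace)
    },
    SM = {
      sc <- 0; sf <- 0; t0 <- NA_integer_
      sc_traj <- numeric(horizon)
      for (d in 1:horizon) {
        sc <- sc + rate_chilling_triangular(T[d], p[["Tmin"]], p[["Topt"]],
                                            p[["Tmax"]])
        sc_traj[d] <- sc
        if (is.na(t0) && sc >= p[["Cstar"]]) t0 <- d
        if (!is.na(t0)) {
          sf <- sf + rate_forcing_sigmoid(T[d], p[["a"]], p[["b"]], p[["c"]])
          if (sf >= p[["Fstar"]]) {
            return(.bb_result(d, t0, sc_traj[seq_len(d)], sf, d,
                              p[["Fstar"]], horizon, trace = trace))
          }
        }
      }
      if (is.na(t0)) {
        .bb_none(sc, 0, p[["Fstar"]], trace = trace, horizon = horizon)
      } else {
        .bb_result(NA_integer_, t0, sc_traj, sf, horizon, p[["Fstar"]],
                   horizon, trace = trace)
      }
    },
    PM = {
      sc <- 0; sf <- 0
      sc_traj <- numeric(horizon)
      for (d in 1:horizon) {
        sc <- sc + rate_chilling_triangular(T[d], p[["Tmin"]], p[["Topt"]],
                                            p[["Tmax"]])
        sc_traj[d] <- sc
        kf <- p[["Km"]] + (1 - p[["Km"]]) * min(sc / p[["Cstar"]], 1)
        sf <- sf + rate_forcing_sigmoid(T[d], p[["a"]], p[["b"]], p[["c"]]) * kf
        if (sf >= p[["Fstar"]]) {
          return(.bb_result(d, 1L, sc_traj[seq_len(d)], sf, d, p[["Fstar"]],
                            horizon, trace = trace))
        }
      }
      .bb_result(NA_integer_, 1L, sc_traj, sf, horizon, p[["Fstar"]],
                 horizon, trace = trace)
    },
    AM = {
      t1c <- as.integer(round(p[["t1c"]]))
      t1f <- as.integer(round(p[["t1f"]]))
      sc <- 0; sf <- 0
      sc_traj <- numeric(horizon)
      req <- NA_real_
      for (d in 1:horizon) {
        if (d >= t1c) sc <- sc + rate_chilling_chill_day(T[d], p[["Tc"]])
        sc_traj[d] <- sc
        if (d >= t1f) {
          sf <- sf + rate_forcing_linear(T[d], p[["Tb"]])
          req <- forcing_requirement_am(sc, p[["a"]], p[["b"]], p[["c"]])
          if (sf >= req) {
            return(.bb_result(d, t1f, sc_traj[seq_len(d)], sf, d, req,
                              horizon, trace = trace))
          }
        }
      }
      .bb_result(NA_integer_, t1f, sc_traj, sf, horizon, req, horizon,
                 trace = trace)
    },
    UM = {
      t2c <- min(as.integer(round(p[["t2c"]])), horizon)
      # Chilling pass (still a day loop); the requirement needs Sc at t2c.
      sc_traj <- numeric(horizon)
      sc <- 0
      for (d in 1:horizon) {
        sc <- sc + rate_chilling_unified(T[d], p[["Ca"]], p[["Cb"]], p[["Cc"]])
        sc_traj[d] <- sc
      }
      fstar <- forcing_requirement_um(sc_traj[t2c], p[["w"]], p[["k"]])
      t0 <- NA_integer_
      for (d in 1:horizon) {
        if (sc_traj[d] >= p[["Cstar"]]) { t0 <- d; break }
      }
      if (is.na(t0)) {
        return(.bb_none(sc_traj[horizon], 0, fstar, trace = trace,
                        horizon = horizon))
      }
      sf <- 0
      for (d in t0:horizon) {
        sf <- sf + rate_forcing_unified(T[d], p[["Fb"]], p[["Fc"]])
        if (sf >= fstar) {
          return(.bb_result(d, t0, sc_traj[seq_len(d)], sf, d, fstar,
                            horizon, trace = trace))
        }
      }
      .bb_result(NA_integer_, t0, sc_traj, sf, horizon, fstar, horizon,
                 trace = trace)
    })
}

# Minimal fast path for the sampler: model id + full parameter vector +
# temperature vector -> budburst day index (NA for NONE).  No validation.
.predict_bb_day <- function(model_id, p, temps, horizon = 303L) {
  .bb_fast(model_id, p, temps, horizon)$bb
}
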