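#' The five budburst models
#'
#' String identifiers of the implemented models: Thermal Time (TTM),
#' Sequential (SM), Parallel (PM), Alternating (AM) and Unified (UM).
#' @return Character vector of model ids.
#' @export
model_ids <- function() c("TTM", "SM", "PM", "AM", "UM")

# Per-model parameter tables: name, lower, upper, calibrated, default.
# Bounds are the shipped flat-prior boxes for calibration; the source
# literature gives none, so they are wide, sign-constrained boxes around
# physically plausible values (temperatures in degC, thresholds in CU/FU,
# days on the package day axis).
.param_table <- function(model_id) {
  tab <- switch(model_id,
    TTM = list(
      t1f   = c(62, 203, TRUE, 123),     # forcing start day (1 Nov..22 Mar)
      Tb    = c(-5, 15, TRUE, 5),
      Fstar = c(1e-3, 500, TRUE, 100)),
    SM = list(
      Tmin  = c(-30, 5, TRUE, -10),
      Topt  = c(-5, 15, TRUE, 4),
      Tmax  = c(5, 30, TRUE, 15),
      a     = c(0.01, 2, TRUE, 0.3),
      b     = c(-5, 20, TRUE, 10),
      c     = c(0.01, 2, TRUE, 1),
      Cstar = c(1e-3, 200, TRUE, 100),
      Fstar = c(1e-3, 500, TRUE, 20)),
    PM = list(
      Tmin  = c(-30, 5, TRUE, -10),
      Topt  = c(-5, 15, TRUE, 4),
      Tmax  = c(5, 30, TRUE, 15),
      a     = c(0.01, 2, TRUE, 0.3),
      b     = c(-5, 20, TRUE, 10),
      c     = c(0.01, 2, TRUE, 1),
      Cstar = c(1e-3, 200, TRUE, 100),
      Fstar = c(1e-3, 500, TRUE, 20),
      Km    = c(0, 1, TRUE, 0.2)),
    AM = list(
      # Day anchors are fixed by the model definition (forcing from 1 Jan,
      # chilling from 1 Nov); they are carried as non-calibrated parameters.
      t1f   = c(62, 203, FALSE, 123),
      t1c   = c(30, 92, FALSE, 62),
      t2c   = c(123, 250, FALSE, 175),   # listed by the model, unused by the day loop
      Tb    = c(-5, 15, TRUE, 5),
      Tc    = c(-5, 15, TRUE, 5),
      a     = c(1e-3, 300, TRUE, 20),
      b     = c(1e-3, 1000, TRUE, 200),
      c     = c(-1, -1e-4, TRUE, -0.05)),
    UM = list(
      Ca    = c(0, 2, TRUE, 0.1),
      Cb    = c(-5, 5, TRUE, 0),
      Cc    = c(-10, 15, TRUE, 3),
      Fb    = c(0.01, 3, TRUE, 0.4),
      Fc    = c(0, 20, TRUE, 8),
      Cstar = c(1e-3, 200, TRUE, 80),
      k     = c(-1, 0, TRUE, -0.01),
      w     = c(1e-3, 500, TRUE, 60),
      t2c   = c(123, 250, TRUE, 175)),
    bb_stop(sprintf("unknown model id '%s'", model_id), "bb_validation_error")
  )
  tab
}

#' Model specification
#'
#' Returns the registry entry for one of the five budburst models: its
#' ordered parameter names, flat-prior bounds, which parameters are
#' calibrated (the Alternating model's day anchors t1f / t1c / t2c are
#' fixed by the model definition), defaults, and the model's fixed calendar
#' anchors on the package day axis.
#'
#' Parameter counts are exact: TTM 3, SM 8, PM 9, AM 8, UM 9.
#'
#' @param model_id one of \code{"TTM"}, \code{"SM"}, \code{"PM"},
#'   \code{"AM"}, \code{"UM"}.
#' @return An object of class \code{model_spec}: list with
#'   \code{model_id}, \code{parameter_names}, \code{bounds} (matrix with
#'   columns \code{lower}, \code{upper}), \code{calibrated} (named logical),
#'   \code{defaults} (named numeric), \code{fixed_days} (named integer) and
#'   \code{n_parameters}.
#' @examples
#' model_spec("SM")$n_parameters  # 8
#' @export
model_spec <- function(model_id) {
  model_id <- match.arg(model_id, model_ids())
  tab <- .param_table(model_id)
  nm <- names(tab)
  bounds <- t(vapply(tab, function(x) x[1:2], numeric(2)))
  colnames(bounds) <- c("lower", "upper")
  calibrated <- vapply(tab, function(x) as.logical(x[3]), logical(1))
  defaults <- vapply(tab, function(x) x[4], numeric(1))
  fixed_days <- switch(model_id,
    TTM = integer(0),
    SM  = c(t1c = 1L),                 # chilling accumulates from 1 September
    PM  = c(t1c = 1L),
    AM  = c(t1f = 123L, t1c = 62L),    # forcing 1 Jan, chilling 1 Nov
    UM  = c(t1c = 1L))
  structure(list(model_id = model_id, parameter_names = nm, bounds = bounds,
                 calibrated = calibrated, defaults = defaults,
                 fixed_days = fixed_days, n_parameters = length(nm)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, %d parameters: %s\n", x$model_id,
              x$n_parameters, paste(x$parameter_names, collapse = ", ")))
  invisible(x)
}

#' Flat-prior bounds for a model's parameters
#'
#' The documented default calibration box for each model: every parameter
#' has a finite \code{[lower, upper]} interval used as a flat prior by
#' \code{\link{metropolis_hastings}}.
#'
#' @inheritParams model_spec
#' @return Numeric matrix (parameters x \code{lower}/\code{upper}).
#' @export
default_parameter_bounds <- function(model_id) {
  model_spec(model_id)$bounds
}

# Merge user values over spec defaults; returns full named numeric vector in
# spec order.
merge_parameters <- function(spec, values) {
  values <- unlist(values)
  out <- spec$defaults
  unknown <- setdiff(names(values), spec$parameter_names)
  if (length(unknown)) {
    bb_stop(sprintf("unknown parameter(s) for %s: %s", spec$model_id,
                    paste(unknown, collapse = ", ")), "bb_parameter_error")
  }
  out[names(values)] <- values
  out
}

# TRUE iff a full parameter vector lies in the prior support: inside the
# bounds box and satisfying the structural orderings (Tmin < Topt < Tmax for
# SM/PM, t1c < t2c for AM/UM).  Used as the flat-prior indicator by the
# sampler, so it never throws.
parameters_valid <- function(spec, params) {
  p <- merge_parameters(spec, params)
  if (anyNA(p) || !all(is.finite(p))) return(FALSE)
  if (any(p < spec$bounds[, "lower"] - 1e-12) ||
      any(p > spec$bounds[, "upper"] + 1e-12)) {
    return(FALSE)
  }
  if (spec$model_id %in% c("SM", "PM")) {
    if (!(p[["Tmin"]] < p[["Topt"]] && p[["Topt"]] < p[["Tmax"]])) return(FALSE)
  }
  if (spec$model_id %in% c("AM", "UM")) {
    t1c <- if (spec$model_id == "AM") p[["t1c"]] else spec$fixed_days[["t1c"]]
    if (!(t1c < p[["t2c"]])) return(FALSE)
  }
  TRUE
}

#' Build and validate a parameter vector for a model
#'
#' Merges the supplied values over the model defaults and checks bounds and
#' structural orderings, raising a parameter error on violation.
#'
#' @param spec a \code{\link{model_spec}} (or model id string).
#' @param values named numeric vector or list of parameter values.
#' @return Full named numeric parameter vector in specification order.
#' @export
parameter_vector <- function(spec, values = numeric(0)) {
  if (is.character(spec)) spec <- model_spec(spec)
  p <- merge_parameters(spec, values)
  if (!parameters_valid(spec, p)) {
    bb_stop(sprintf("invalid parameter vector for %s (bounds or ordering violated)",
                    spec$model_id), "bb_parameter_error")
  }
  p
}
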