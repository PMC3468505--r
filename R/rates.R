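#' Daily chilling and forcing rate functions
#'
#' The building blocks of the five budburst models.  All functions are
#' vectorized over the temperature argument and return daily rates in
#' chilling units (CU/day) or forcing units (FU/day).
#'
#' \describe{
#'   \item{\code{rate_forcing_linear}}{Growing-degree-day forcing:
#'     \code{max(0, T - Tb)} above a base temperature \code{Tb} (TTM, AM).}
#'   \item{\code{rate_chilling_triangular}}{Unit triangle: 0 outside
#'     \code{(Tmin, Tmax)}, rising linearly to 1 at \code{Topt} (SM, PM).}
#'   \item{\code{rate_forcing_sigmoid}}{\code{c / (1 + exp(-a (T - b)))}:
#'     monotone increasing, asymptote \code{c}, midpoint \code{b} (SM, PM).}
#'   \item{\code{rate_chilling_chill_day}}{Chill-day counter: 1 when
#'     \code{T < Tc} (strictly), else 0 (AM).}
#'   \item{\code{rate_chilling_unified}}{Chuine-style bell sigmoid
#'     \code{1 / (1 + exp(Ca (T - Cc)^2 + Cb (T - Cc)))}, bounded in (0, 1)
#'     (UM).}
#'   \item{\code{rate_forcing_unified}}{\code{1 / (1 + exp(-Fb (T - Fc)))}
#'     (UM); written with a leading minus and \code{Fb > 0} so the rate
#'     increases with temperature by construction.}
#' }
#'
#' @param T mean daily air temperature, degrees C (vectorized).
#' @param Tb critical (base) temperature for forcing, degrees C.
#' @param Tmin,Topt,Tmax triangle feet and peak; requires
#'   \code{Tmin < Topt < Tmax}.
#' @param a,b,c sigmoid slope, midpoint (degrees C) and asymptote (FU/day).
#' @param Tc chilling threshold temperature, degrees C.
#' @param Ca,Cb,Cc unified chilling rate parameters (quadratic and linear
#'   coefficients, and centre temperature).
#' @param Fb,Fc unified forcing slope (> 0) and midpoint.
#' @return Daily rate(s), CU/day or FU/day.
#' @name rate_functions
NULL

# Exponent clamp: exp() overflows past ~709, so sigmoid exponents are capped.
clamp_exp <- function(x) pmin(pmax(x, -700), 700)

#' @rdname rate_functions
#' @export
rate_forcing_linear <- function(T, Tb) {
  pmax(0, T - Tb)
}

#' @rdname rate_functions
#' @export
rate_chilling_triangular <- function(T, Tmin, Topt, Tmax) {
  if (!(Tmin < Topt && Topt < Tmax)) {
    bb_stop("triangular chilling requires Tmin < Topt < Tmax",
            "bb_parameter_error")
  }
  pmax(0, pmin((T - Tmin) / (Topt - Tmin), (Tmax - T) / (Tmax - Topt)))
}

#' @rdname rate_functions
#' @export
rate_forcing_sigmoid <- function(T, a, b, c) {
  c / (1 + exp(clamp_exp(-a * (T - b))))
}

#' @rdname rate_functions
#' @export
rate_chilling_chill_day <- function(T, Tc) {
  as.numeric(T < Tc)
}

#' @rdname rate_functions
#' @export
rate_chilling_unified <- function(T, Ca, Cb, Cc) {
  1 / (1 + exp(clamp_exp(Ca * (T - Cc)^2 + Cb * (T - Cc))))
}

#' @rdname rate_functions
#' @export
rate_forcing_unified <- function(T, Fb, Fc) {
  1 / (1 + exp(clamp_exp(-Fb * (T - Fc))))
}

#' Chilling-dependent forcing requirements
#'
#' In the Alternating and Unified models the forcing threshold \code{F*} is
#' not a constant but a decreasing function of accumulated chilling: the
#' more chilling a bud has received, the less forcing it needs.
#'
#' \code{forcing_requirement_am} (AM): \code{a + b exp(c Sc)} with
#' \code{b > 0, c < 0}, re-evaluated daily against the running state of
#' chilling.
#'
#' \code{forcing_requirement_um} (UM): \code{w exp(k Sc_total)} with
#' \code{w > 0, k <= 0}, where \code{Sc_total} is the chilling accumulated
#' from 1 September (t1c) to the parameter day \code{t2c}.
#'
#' @param Sc,Sc_total state of chilling, CU.
#' @param a asymptotic forcing requirement, FU.
#' @param b amplitude, FU (> 0).
#' @param c,k exponential decay rates per CU (<= 0).
#' @param w forcing requirement at zero chilling, FU (> 0).
#' @return Forcing requirement, FU.
#' @name forcing_requirements
NULL

#' @rdname forcing_requirements
#' @export
forcing_requirement_am <- function(Sc, a, b, c) {
  a + b * exp(c * Sc)
}

#' @rdname forcing_requirements
#' @export
forcing_requirement_um <- function(Sc_total, w, k) {
  w * exp(k * Sc_total)
}
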