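#' Fixed anchor days of the budburst day axis
#'
#' All series in this package live on an integer day axis with index 1 =
#' 1 September of the year preceding budburst and a 365-day year (leap days
#' are ignored; the reference season, September 2009 -- June 2010, contains
#' none).  Chilling accumulation in the Unified model starts on
#' 1 September, which is why the axis must begin before 1 January.
#'
#' @return Named integer vector of anchor day indices:
#'   \code{sep1} (1), \code{nov1} (62, Alternating-model chilling start),
#'   \code{dec1} (92, experiment/warming start), \code{jan1} (123,
#'   Alternating-model forcing start), \code{feb22} (175, chamber transfer
#'   day), \code{jun30} (303, default prediction horizon).
#' @examples
#' day_anchors()["feb22"]  # 22 February = index 175
#' @export
day_anchors <- function() {
  c(sep1 = 1L, nov1 = 62L, dec1 = 92L, jan1 = 123L, feb22 = 175L, jun30 = 303L)
}

#' Convert between day index and calendar day-of-year
#'
#' The mapping is a fixed bijection: DOY = index - 122 for indices >= 123
#' (1 January of the budburst year = index 123).  Indices 1--122 fall in the
#' preceding autumn and map to DOY 244--365 of the previous calendar year.
#'
#' @param index integer day index (1 = 1 September).
#' @param doy integer day of year of the budburst year.
#' @return Integer vector of the converted days.
#' @examples
#' index_to_doy(123)  # 1
#' doy_to_index(181)  # 303 (30 June)
#' @export
index_to_doy <- function(index) {
  index <- as.integer(index)
  ifelse(index >= 123L, index - 122L, index + 243L)
}

#' @rdname index_to_doy
#' @export
doy_to_index <- function(doy) {
  as.integer(doy) + 122L
}
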