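#' Accumulate thermal time from daily mean temperatures
#'
#' Thermal time (growing degree days, degC d) is the running sum of the
#' daily mean air temperature above the cultivar's base temperature; days
#' below the base contribute zero. Clipping is applied to the daily mean,
#' not to sub-daily records (see \code{\link{daily_mean_temp}}).
#'
#' @param daily_mean_temps Numeric vector of daily mean temperatures, degC.
#' @param base_temp Base temperature, degC (10 for japonica, 12 for indica).
#' @return A data.frame with columns \code{day} (1-based index) and
#'   \code{tt} (cumulative thermal time, nondecreasing).
#' @examples
#' accumulate_thermal_time(c(20, 25, 15), base_temp = 10)
#' @export
accumulate_thermal_time <- function(daily_mean_temps, base_temp) {
  if (length(daily_mean_temps) == 0L) {
    stop("empty temperature series", call. = FALSE)
  }
  if (!all(is.finite(daily_mean_temps))) {
    stop("temperatures must all be finite", call. = FALSE)
  }
  stopifnot(is.numeric(base_temp), length(base_temp) == 1L,
            is.finite(base_temp))
  tt <- cumsum(pmax(daily_mean_temps - base_temp, 0))
  data.frame(day = seq_along(tt), tt = tt)
}

#' Daily mean temperature from sub-daily records
#'
#' Arithmetic mean of the records within each day. Use before
#' \code{\link{accumulate_thermal_time}} when the logger stores 30-min
#' readings.
#'
#' @param temps Numeric vector of sub-daily temperature records.
#' @param day Grouping vector (same length) identifying the day of each
#'   record.
#' @return Numeric vector of daily means, in order of first appearance of
#'   each day.
#' @export
daily_mean_temp <- function(temps, day) {
  stopifnot(length(temps) == length(day), all(is.finite(temps)))
  as.numeric(tapply(temps, factor(day, levels = unique(day)), mean))
}
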