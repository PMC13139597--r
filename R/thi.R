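#' Hourly temperature-humidity index
#'
#' Computes the THI from dry-bulb temperature and relative humidity using
#' the standard livestock formula
#' \deqn{THI = (1.8T + 32) - (0.55 - 0.0055 RH)(1.8T - 26)}
#' where \eqn{T} is in degrees Celsius and \eqn{RH} in percent. The index is
#' strictly increasing in temperature; it increases with humidity above
#' \eqn{T = 130/9 \approx 14.44} degrees C and decreases with humidity below
#' that temperature.
#'
#' @param temp_c dry-bulb air temperature in degrees Celsius.
#' @param rh_pct relative humidity in percent, within \[0, 100\]. Values
#'   outside that range are an error, not clipped.
#' @return numeric vector of THI values.
#' @export
#' @examples
#' hourlyThi(25, 50)     # 71.775
#' hourlyThi(130 / 9, 7) # 58 regardless of humidity
hourlyThi <- function(temp_c, rh_pct) {
  stopifnot(is.numeric(temp_c), is.numeric(rh_pct))
  if (any(!is.finite(rh_pct)) || any(rh_pct < 0) || any(rh_pct > 100)) {
    stop("relative humidity must lie within [0, 100] percent; got values outside that range")
  }
  (1.8 * temp_c + 32) - (0.55 - 0.0055 * rh_pct) * (1.8 * temp_c - 26)
}

#' Daily mean THI from hourly weather
#'
#' Aggregates hourly weather records into one daily THI per station (farm)
#' and calendar date, as the arithmetic mean of the hourly THI values of the
#' day. In strict mode a day must have exactly 24 hourly values; in lenient
#' mode at least `min_hours` values are required and the deviation is
#' reported as an attribute.
#'
#' @param weather data.frame with columns `farm` (station identifier),
#'   `timestamp` (POSIXct, hour resolution) and either `thi` or both
#'   `temp_c` and `rh_pct`.
#' @param strict logical; require complete 24-hour days (default `TRUE`).
#' @param min_hours minimum hourly values per day accepted in lenient mode.
#' @return data.frame with columns `farm`, `date`, `n_hours`, `thi_daily`.
#' @export
computeDailyThi <- function(weather, strict = TRUE, min_hours = 20L) {
  stopifnot(is.data.frame(weather), all(c("farm", "timestamp") %in% names(weather)))
  thi <- if ("thi" %in% names(weather)) weather$thi else
    hourlyThi(weather$temp_c, weather$rh_pct)
  date <- as.Date(weather$timestamp, tz = "UTC")
  key <- paste(weather$farm, date, sep = "\r")
  n <- tapply(thi, key, length)
  if (strict && any(n != 24L)) {
    bad <- names(n)[n != 24L]
    bad <- vapply(strsplit(bad, "\r", fixed = TRUE), function(p)
      paste0("farm ", p[1], " ", p[2]), character(1))
    stop("incomplete days (!= 24 hourly values) in strict mode: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!strict && any(n < min_hours)) {
    bad <- names(n)[n < min_hours]
    stop("days with fewer than ", min_hours, " hourly values even in lenient mode: ",
         paste(utils::head(gsub("\r", " ", bad, fixed = TRUE), 10), collapse = ", "))
  }
  m <- tapply(thi, key, mean)
  parts <- strsplit(names(m), "\r", fixed = TRUE)
  out <- data.frame(
    farm = vapply(parts, `[`, character(1), 1L),
    date = as.Date(vapply(parts, `[`, character(1), 2L)),
    n_hours = as.integer(n[names(m)]),
    thi_daily = as.numeric(m)
  )
  out <- out[order(out$farm, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Windowed test-day THI
#'
#' For each requested date, averages the daily THI of that date and the
#' three preceding days and rounds the mean to the closest integer
#' (half away from zero). This windowed value captures the lag between the
#' onset of heat load and its effect on the cow.
#'
#' @param daily data.frame as returned by [computeDailyThi()] for a single
#'   farm, or with a `farm` column when `farm` is given.
#' @param dates Date vector of test days.
#' @param farm optional farm identifier used to subset `daily`.
#' @return integer vector of windowed THI values, one per date.
#' @export
thiWindow <- function(daily, dates, farm = NULL) {
  stopifnot(is.data.frame(daily), all(c("date", "thi_daily") %in% names(daily)))
  if (!is.null(farm)) daily <- daily[daily$farm == farm, , drop = FALSE]
  dates <- as.Date(dates)
  lookup <- stats::setNames(daily$thi_daily, as.character(daily$date))
  out <- vapply(dates, function(d) {
    need <- as.character(d - 3:0)
    vals <- lookup[need]
    if (anyNA(vals)) {
      stop("missing daily THI for date(s): ",
           paste(need[is.na(vals)], collapse = ", "))
    }
    mean(vals)
  }, numeric(1))
  as.integer(roundHalfAwayFromZero(out))
}
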