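#' Exclusion criteria for the seasonal-shift statistic
#'
#' Locations are excluded from the analysis when, during the season of
#' interest, they are ice covered in at least `ice_year_frac` of all years,
#' or their climatological seasonal rate of change is below `gradient_min`
#' in magnitude (tropical lakes with marginal seasonality), or the centre
#' month is missing in more than `max_missing_frac` of years.
#'
#' @param gradient_min Minimum absolute seasonal rate of change
#'   (degrees C per month) for a location to be retained. Default 0.5;
#'   gradients exactly at the threshold are retained.
#' @param ice_year_frac Fraction of years with ice cover during the season
#'   (any window month) at or above which the location is excluded.
#'   Default 0.9, so one anomalous icy year in a multidecadal record does
#'   not exclude a lake.
#' @param max_missing_frac Maximum tolerated fraction of missing
#'   centre-month values before a location is marked insufficient.
#'   Default 0.25.
#' @return A list of class `exclusion_criteria`.
#' @export
exclusion_criteria <- function(gradient_min = 0.5, ice_year_frac = 0.9,
                               max_missing_frac = 0.25) {
  stopifnot(is.numeric(gradient_min), length(gradient_min) == 1L,
            gradient_min > 0,
            is.numeric(ice_year_frac), length(ice_year_frac) == 1L,
            ice_year_frac > 0, ice_year_frac <= 1,
            is.numeric(max_missing_frac), length(max_missing_frac) == 1L,
            max_missing_frac >= 0, max_missing_frac < 1)
  structure(list(gradient_min = gradient_min,
                 ice_year_frac = ice_year_frac,
                 max_missing_frac = max_missing_frac),
            class = "exclusion_criteria")
}

# days decade^-1 per (month year^-1): x 10 years x 365.25 days / 12 months
days_decade_per_month_year <- function() 10 * 365.25 / 12

#' Exclusion reason codes
#'
#' Stable integer codes used when exclusion reasons are written to NetCDF:
#' none = 0, ice_covered = 1, low_seasonality = 2, insufficient_data = 3.
#' @format Named integer vector.
#' @export
EXCLUSION_CODES <- c(none = 0L, ice_covered = 1L,
                     low_seasonality = 2L, insufficient_data = 3L)

insufficient_data_error <- function(msg) {
  stop(structure(class = c("lakeshift_insufficient_data", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Long-term linear trend of one calendar month's temperature
#'
#' Ordinary-least-squares slope of the given month's mean temperature
#' against calendar year, in degrees C per year. Missing years are omitted
#' pairwise.
#'
#' @param series A [lake_series()].
#' @param month Month index 1-12.
#' @return Slope in degrees C per year.
#'   Signals an error of class `lakeshift_insufficient_data` when fewer
#'   than 3 non-missing values are available.
#' @export
fit_monthly_trend <- function(series, month) {
  stopifnot(is_lake_series(series))
  month <- as.integer(month)
  stopifnot(length(month) == 1L, month >= 1L, month <= 12L)
  y <- series$temps[, month]
  ok <- !is.na(y)
  if (sum(ok) < 3L) {
    insufficient_data_error(sprintf(
      "need at least 3 non-missing values for month %d, have %d",
      month, sum(ok)))
  }
  x <- series$years[ok]
  y <- y[ok]
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

#' Climatological seasonal rate of change
#'
#' Half the difference in temperature between the month following and the
#' month preceding the centre month, averaged over all years with both
#' neighbours present (degrees C per month). At the year boundary the
#' neighbours come from the adjacent calendar year: a December-centred
#' window uses November of year y and January of year y+1 (the final year
#' is dropped when its following January is absent), and a January-centred
#' window uses December of year y-1 and February of year y.
#'
#' @param series A [lake_series()].
#' @param centre_month Month index 1-12 at the centre of the 3-month window.
#' @return Mean of (T\[m+1\] - T\[m-1\]) / 2 in degrees C per month.
#'   Signals `lakeshift_insufficient_data` with fewer than 3 usable year
#'   pairs.
#' @export
seasonal_rate_of_change <- function(series, centre_month) {
  stopifnot(is_lake_series(series))
  centre_month <- as.integer(centre_month)
  stopifnot(length(centre_month) == 1L,
            centre_month >= 1L, centre_month <= 12L)
  d <- neighbour_half_differences(series$temps, centre_month)
  ok <- !is.na(d)
  if (sum(ok) < 3L) {
    insufficient_data_error(sprintf(
      "need at least 3 year pairs around month %d, have %d",
      centre_month, sum(ok)))
  }
  mean(d[ok])
}

# Per-year half differences (T[next] - T[prev]) / 2 around a centre month,
# with December/January neighbours taken from the adjacent calendar year.
neighbour_half_differences <- function(temps, centre_month) {
  n <- nrow(temps)
  prev_m <- wrap_month(centre_month - 1L)
  next_m <- wrap_month(centre_month + 1L)
  prev_off <- if (centre_month == 1L) -1L else 0L
  next_off <- if (centre_month == 12L) 1L else 0L
  idx <- seq_len(n)
  pick <- function(m, off) {
    src <- idx + off
    v <- rep(NA_real_, n)
    in_range <- src >= 1L & src <= n
    v[in_range] <- temps[src[in_range], m]
    v
  }
  (pick(next_m, next_off) - pick(prev_m, prev_off)) / 2
}

#' Convert a monthly trend and seasonal gradient to a seasonal shift
#'
#' The pace-of-shifting-seasons statistic: the monthly temperature trend
#' (degrees C per year) divided by the climatological seasonal rate of
#' change (degrees C per month) gives a shift in months per year, converted
#' to days per decade by multiplying by 10 years and 365.25 days per year
#' and dividing by 12 months. Positive values mean the season's
#' temperatures arrive earlier (advance), negative that they are delayed.
#'
#' @param trend Monthly temperature trend, degrees C per year.
#' @param gradient Climatological seasonal rate of change, degrees C per
#'   month. Must be nonzero (the low-seasonality criterion is applied
#'   upstream and guarantees this in the pipeline).
#' @return Seasonal shift in days per decade. Vectorised over inputs.
#' @examples
#' compute_shift(0.1, 1.0)    # 30.4375
#' compute_shift(0.05, -1.25) # -12.175, a delayed season
#' @export
compute_shift <- function(trend, gradient) {
  stopifnot(is.numeric(trend), is.numeric(gradient))
  if (any(!is.na(gradient) & gradient == 0)) {
    stop(structure(class = c("lakeshift_zero_gradient", "error",
                             "condition"),
                   list(message = "seasonal rate of change is zero; shift undefined",
                        call = NULL)))
  }
  (trend / gradient) * days_decade_per_month_year()
}

#' Seasonal shift for one location and season
#'
#' Applies the full per-location procedure: the ice-cover exclusion, the
#' centre-month trend, the climatological seasonal rate of change across
#' the window, the low-seasonality criterion, and the unit conversion.
#' Exclusion reasons are evaluated in the order ice cover, insufficient
#' data, low seasonality.
#'
#' @param series A [lake_series()].
#' @param season A `season_def` from [season_for()], [season_custom()] or
#'   [moving_windows()].
#' @param criteria An [exclusion_criteria()].
#' @return A `shift_result`: list with `trend` (degrees C per year),
#'   `gradient` (degrees C per month), `shift` (days per decade, `NA` when
#'   invalid), `valid` (logical), and `exclusion_reason` (one of `"none"`,
#'   `"ice_covered"`, `"low_seasonality"`, `"insufficient_data"`).
#' @export
shift_for_season <- function(series, season, criteria = exclusion_criteria()) {
  stopifnot(is_lake_series(series), inherits(season, "season_def"),
            inherits(criteria, "exclusion_criteria"))
  trend <- tryCatch(fit_monthly_trend(series, season$centre_month),
                    lakeshift_insufficient_data = function(e) NA_real_)
  gradient <- tryCatch(seasonal_rate_of_change(series, season$centre_month),
                       lakeshift_insufficient_data = function(e) NA_real_)

  reason <- "none"
  if (!is.null(series$ice)) {
    icy_year <- rowSums(series$ice[, season$window, drop = FALSE]) > 0
    if (mean(icy_year) >= criteria$ice_year_frac) reason <- "ice_covered"
  }
  if (reason == "none") {
    centre_missing <- mean(is.na(series$temps[, season$centre_month]))
    if (is.na(trend) || is.na(gradient) ||
        centre_missing > criteria$max_missing_frac) {
      reason <- "insufficient_data"
    }
  }
  if (reason == "none" &&
      (gradient == 0 || abs(gradient) < criteria$gradient_min)) {
    reason <- "low_seasonality"
  }

  valid <- reason == "none"
  shift <- if (valid) compute_shift(trend, gradient) else NA_real_
  structure(list(trend = trend, gradient = gradient, shift = shift,
                 valid = valid, exclusion_reason = reason),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf(
      "<shift_result> %.3f days decade^-1 (trend %.4f degC yr^-1, gradient %.3f degC month^-1)\n",
      x$shift, x$trend, x$gradient))
  } else {
    cat(sprintf("<shift_result> excluded: %s\n", x$exclusion_reason))
  }
  invisible(x)
}
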