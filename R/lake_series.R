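#' Monthly lake surface temperature series for one location
#'
#' Bundles an ordered run of calendar years with a year-by-month matrix of
#' monthly mean surface water temperatures (degrees C) and, optionally, a
#' matching logical matrix of monthly ice-cover flags. This is the atomic
#' input to all trend and seasonal-shift computations.
#'
#' Temperatures supplied in Kelvin are detected (median of non-missing values
#' above 150) and converted to degrees C at construction, with a message.
#'
#' @param years Integer vector of calendar years, strictly increasing and
#'   contiguous (no gaps). At least 3 years are required for any trend.
#' @param temps Numeric matrix with one row per year and exactly 12 columns
#'   (January = column 1). `NA` marks a missing month; all non-missing values
#'   must be finite.
#' @param ice Optional logical matrix of the same shape; `TRUE` means ice
#'   cover was present in that month. `NA` entries are treated as no ice.
#' @return An object of class `lake_series`.
#' @examples
#' temps <- matrix(10 + 10 * sin(2 * pi * (1:12 - 0.5) / 12),
#'                 nrow = 5, ncol = 12, byrow = TRUE)
#' s <- lake_series(2001:2005, temps)
#' fit_monthly_trend(s, 4)
#' @export
lake_series <- function(years, temps, ice = NULL) {
  years <- as.integer(years)
  if (anyNA(years) || length(years) < 1) {
    stop("`years` must be a non-empty integer vector", call. = FALSE)
  }
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("`years` must be strictly increasing and contiguous", call. = FALSE)
  }
  temps <- as.matrix(temps)
  storage.mode(temps) <- "double"
  if (ncol(temps) != 12L) {
    stop("`temps` must have exactly 12 columns (one per month)", call. = FALSE)
  }
  if (nrow(temps) != length(years)) {
    stop("`temps` must have one row per year", call. = FALSE)
  }
  if (any(is.infinite(temps))) {
    stop("non-missing temperatures must be finite", call. = FALSE)
  }
  temps <- maybe_kelvin_to_celsius(temps)
  if (!is.null(ice)) {
    ice <- as.matrix(ice)
    if (!identical(dim(ice), dim(temps))) {
      stop("`ice` must have the same dimensions as `temps`", call. = FALSE)
    }
    if (!is.logical(ice)) {
      stop("`ice` must be a logical matrix", call. = FALSE)
    }
    ice[is.na(ice)] <- FALSE
  }
  structure(list(years = years, temps = temps, ice = ice),
            class = "lake_series")
}

#' @export
print.lake_series <- function(x, ...) {
  cat(sprintf("<lake_series> %d-%d (%d years), %d missing months%s\n",
              min(x$years), max(x$years), length(x$years),
              sum(is.na(x$temps)),
              if (is.null(x$ice)) "" else ", with ice flags"))
  invisible(x)
}

# Kelvin inputs are detected by magnitude: no lake surface on Earth reaches
# 150 degrees C, and 150 K is far below any ambient temperature.
maybe_kelvin_to_celsius <- function(temps, declared = NULL) {
  looks_kelvin <- if (!is.null(declared)) {
    tolower(declared) %in% c("k", "kelvin")
  } else {
    any(!is.na(temps)) && stats::median(temps, na.rm = TRUE) > 150
  }
  if (looks_kelvin) {
    message("temperatures appear to be in Kelvin; converting to degrees C")
    temps <- temps - 273.15
  }
  temps
}

is_lake_series <- function(x) inherits(x, "lake_series")
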