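#' Specification of a synthetic lake-temperature grid
#'
#' Parameters of a stochastic emulator of monthly lake surface temperature
#' fields: a smooth sinusoidal annual cycle, an optional linear warming
#' trend, an optional phenological phase drift (the annual cycle arriving
#' earlier each year), independent Gaussian observational noise, and ice
#' flags wherever the noiseless signal falls below a freezing threshold.
#' Because the warming rate and phase drift are injected, the expected
#' seasonal shift is known in closed form ([expected_shift()]), which makes
#' every stage of the pipeline testable without external data.
#'
#' Defaults mirror a 42-year (1980-2021) record of a temperate lake: a
#' 10 degrees C seasonal amplitude around a 15 degrees C mean, a warming
#' trend of 0.03 degrees C per year (about 0.3 degrees C per decade), no
#' phase drift, 0.5 degrees C monthly noise, and ice wherever the noiseless
#' monthly mean falls below 0 degrees C.
#'
#' @param n_years Number of years (>= 3).
#' @param start_year First calendar year.
#' @param mean_temp Annual mean temperature, degrees C.
#' @param amplitude Amplitude of the annual cycle, degrees C (>= 0).
#' @param warming_trend Linear trend, degrees C per year.
#' @param phase_drift Days per year by which the annual cycle arrives
#'   earlier (positive = earlier).
#' @param noise_sd Standard deviation of monthly noise, degrees C (>= 0).
#' @param ice_threshold Degrees C; months whose noiseless signal is below
#'   this get `ice = TRUE`. Use `-Inf` for no ice.
#' @param seed Integer seed; generation is fully reproducible.
#' @param grid_shape Integer pair (n_lat, n_lon).
#' @param lat_range,lon_range Numeric pairs giving the coordinate extent.
#' @param ar1 Lag-1 autocorrelation of the noise across consecutive months
#'   within a location. Off (0) by default: the statistic assumes nothing
#'   about autocorrelation.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_years = 42L, start_year = 1980L,
                           mean_temp = 15, amplitude = 10,
                           warming_trend = 0.03, phase_drift = 0,
                           noise_sd = 0.5, ice_threshold = 0,
                           seed = 42L, grid_shape = c(4L, 4L),
                           lat_range = c(-60, 60),
                           lon_range = c(-20, 20), ar1 = 0) {
  n_years <- as.integer(n_years)
  stopifnot(n_years >= 3L, amplitude >= 0, noise_sd >= 0,
            length(grid_shape) == 2L, all(grid_shape >= 1L),
            length(lat_range) == 2L, length(lon_range) == 2L,
            abs(ar1) < 1)
  structure(list(n_years = n_years, start_year = as.integer(start_year),
                 mean_temp = mean_temp, amplitude = amplitude,
                 warming_trend = warming_trend, phase_drift = phase_drift,
                 noise_sd = noise_sd, ice_threshold = ice_threshold,
                 seed = as.integer(seed),
                 grid_shape = as.integer(grid_shape),
                 lat_range = as.numeric(lat_range),
                 lon_range = as.numeric(lon_range), ar1 = ar1),
            class = "synthetic_spec")
}

# Mid-month day-of-year on a fixed 365.25-day calendar; monthly means are
# point evaluations at mid-month, adequate for a monthly-resolution
# statistic.
mid_month_day <- function(m) (m - 0.5) * 365.25 / 12

# Noiseless signal for one location; southern hemisphere = half-period
# phase offset so its climatological maximum sits 6 months from the north.
synthetic_signal <- function(spec, lat, year, month) {
  dy <- year - spec$start_year
  phase0 <- if (lat >= 0) 0 else pi
  d <- mid_month_day(month) + spec$phase_drift * dy
  spec$mean_temp +
    spec$amplitude * sin(2 * pi * d / 365.25 + phase0) +
    spec$warming_trend * dy
}

#' Generate a synthetic lake-temperature grid
#'
#' Evaluates the noiseless signal of [synthetic_spec()] on a regular
#' latitude-longitude grid, adds seeded Gaussian noise, and flags ice from
#' the noiseless signal. Output is bitwise-reproducible for a fixed spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A [lake_grid()] with ice flags.
#' @export
generate_grid <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_lat <- spec$grid_shape[1L]
  n_lon <- spec$grid_shape[2L]
  lats <- if (n_lat == 1L) mean(spec$lat_range) else
    seq(spec$lat_range[1L], spec$lat_range[2L], length.out = n_lat)
  lons <- if (n_lon == 1L) mean(spec$lon_range) else
    seq(spec$lon_range[1L], spec$lon_range[2L], length.out = n_lon)
  # location order: latitude outer, longitude inner
  coords <- expand.grid(lon = lons, lat = lats,
                        KEEP.OUT.ATTRS = FALSE)[, c("lat", "lon")]
  n_loc <- nrow(coords)
  years <- spec$start_year + seq_len(spec$n_years) - 1L

  phase0 <- ifelse(coords$lat >= 0, 0, pi)
  temps <- array(NA_real_, dim = c(n_loc, spec$n_years, 12L))
  for (m in 1:12) {
    d <- outer(rep(mid_month_day(m), n_loc),
               spec$phase_drift * (years - spec$start_year), "+")
    sig <- spec$mean_temp +
      spec$amplitude * sin(2 * pi * d / 365.25 + phase0) +
      outer(rep(1, n_loc), spec$warming_trend * (years - spec$start_year))
    temps[, , m] <- sig
  }
  ice <- temps < spec$ice_threshold

  if (spec$noise_sd > 0) {
    eps <- with_seed(spec$seed, {
      e <- array(stats::rnorm(n_loc * spec$n_years * 12L, sd = spec$noise_sd),
                 dim = c(n_loc, spec$n_years, 12L))
      if (spec$ar1 != 0) e <- ar1_filter(e, spec$ar1)
      e
    })
    temps <- temps + eps
  }
  lake_grid(coords$lat, coords$lon, years, temps, ice = ice)
}

# Evaluate expr with a local RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# AR(1) along the month axis within each location, variance-normalised so
# the marginal sd stays at noise_sd.
ar1_filter <- function(e, rho) {
  d <- dim(e)
  flat <- matrix(aperm(e, c(2L, 3L, 1L)), nrow = d[2L] * d[3L])
  for (j in seq_len(ncol(flat))) {
    flat[, j] <- as.numeric(stats::filter(flat[, j] * sqrt(1 - rho^2),
                                          rho, method = "recursive"))
  }
  aperm(array(flat, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
}

#' Closed-form expected seasonal shift for a synthetic spec
#'
#' Ground truth for parameter-recovery tests. A pure phase drift of
#' delta days per year translates the whole annual cycle, so the seasonal
#' shift is 10 x delta days per decade at every centre month whose
#' gradient passes the seasonality criterion. A pure warming trend b
#' shifts timing by b divided by the climatological gradient; the gradient
#' of the sinusoidal climatology under the central difference used by the
#' estimator is 0.5 x amplitude x cos(phase at the centre month). Mixed
#' cases add to first order.
#'
#' @param spec A [synthetic_spec()].
#' @param centre_month Month index 1-12.
#' @param hemisphere `"north"` (default) or `"south"`.
#' @return Expected shift in days per decade. Signals an error of class
#'   `lakeshift_zero_gradient` when the expected gradient is numerically
#'   zero.
#' @export
expected_shift <- function(spec, centre_month, hemisphere = "north") {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- expected_gradient(spec, centre_month, hemisphere)
  if (abs(g) < 1e-9) {
    stop(structure(class = c("lakeshift_zero_gradient", "error", "condition"),
                   list(message = "expected gradient is (near) zero; shift undefined",
                        call = NULL)))
  }
  drift_part <- 10 * spec$phase_drift
  warming_part <- (spec$warming_trend / g) * days_decade_per_month_year()
  drift_part + warming_part
}

#' Expected climatological gradient of the synthetic annual cycle
#'
#' The central-difference gradient of the noiseless sinusoid at a centre
#' month, (S(m+1) - S(m-1)) / 2 evaluated at mid-month days (in the first
#' year, before any phase drift accumulates).
#'
#' @inheritParams expected_shift
#' @return Gradient in degrees C per month.
#' @export
expected_gradient <- function(spec, centre_month, hemisphere = "north") {
  stopifnot(inherits(spec, "synthetic_spec"))
  phase0 <- if (hemisphere == "north") 0 else pi
  s <- function(m) {
    spec$amplitude * sin(2 * pi * mid_month_day(m) / 365.25 + phase0)
  }
  (s(centre_month + 1) - s(centre_month - 1)) / 2
}
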