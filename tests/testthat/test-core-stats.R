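test_that("monthly trend recovers exact linear and constant series", {
  years <- 1980:2021
  lin <- make_series(years, function(y, m) {
    if (m == 4) 10 + 0.05 * (y - 1980) else 12
  })
  expect_equal(fit_monthly_trend(lin, 4), 0.05)
  expect_equal(fit_monthly_trend(lin, 7), 0)

  const <- make_series(years, function(y, m) 12)
  expect_equal(fit_monthly_trend(const, 4), 0)
})

test_that("monthly trend matches a normal-equations oracle on noisy data", {
  years <- 1980:2021
  for (seed in 1:5) {
    set.seed(seed)
    noise <- rnorm(length(years), sd = 0.5)
    s <- make_series(years, function(y, m) {
      if (m == 4) 10 + 0.03 * (y - 1980) + noise[y - 1979] else 12
    })
    expect_equal(fit_monthly_trend(s, 4),
                 ols_slope_oracle(years, s$temps[, 4]),
                 tolerance = 1e-10)
  }
})

test_that("trend requires at least 3 non-missing values", {
  temps <- matrix(10, 5, 12)
  temps[1:3, 4] <- NA
  s <- lake_series(2001:2005, temps)
  expect_error(fit_monthly_trend(s, 4),
               class = "lakeshift_insufficient_data")
  expect_equal(fit_monthly_trend(s, 5), 0)  # other months unaffected
})

test_that("seasonal rate of change is the mean half-difference", {
  years <- 2000:2009
  s <- make_series(years, function(y, m) {
    c(1, 2, 5, 8, 11, 13, 14, 13, 11, 8, 5, 2)[m]
  })
  expect_equal(seasonal_rate_of_change(s, 4), (11 - 5) / 2)  # Mar 5, May 11
  sym <- make_series(years, function(y, m) ifelse(m %in% c(3, 5), 7, 10))
  expect_equal(seasonal_rate_of_change(sym, 4), 0)  # March = May
})

test_that("central difference of a sinusoid matches the closed form", {
  # climatology S(m) = A sin(2 pi m / 12): half-difference at centre m is
  # A sin(2 pi / 12) cos(2 pi m / 12) = 0.5 A cos(2 pi m / 12)
  A <- 10
  years <- 1990:1999
  s <- make_series(years, function(y, m) A * sin(2 * pi * m / 12))
  for (m in 1:12) {
    expect_equal(seasonal_rate_of_change(s, m),
                 0.5 * A * cos(2 * pi * m / 12),
                 tolerance = 1e-12)
  }
})

test_that("December and January windows wrap to adjacent calendar years", {
  years <- 2000:2004
  # November constant 6; January of year y equals y - 2000 (distinguishes
  # calendar years); December constant 5
  s <- make_series(years, function(y, m) {
    if (m == 11) rep(6, length(y)) else if (m == 1) y - 2000 else 5
  })
  # December-centred: (Jan[y+1] - Nov[y]) / 2 over y = 2000..2003 (final
  # year dropped: no following January). Jan values 1..4, Nov 6.
  expect_equal(seasonal_rate_of_change(s, 12),
               mean(((1:4) - 6) / 2))
  # January-centred: (Feb[y] - Dec[y-1]) / 2; first year dropped.
  expect_equal(seasonal_rate_of_change(s, 1), (5 - 5) / 2)
})

test_that("unit conversion is exact and signed", {
  expect_equal(compute_shift(0.1, 1.0), 30.4375)
  expect_equal(compute_shift(0.0, 2.0), 0.0)
  expect_equal(compute_shift(0.05, -1.25), -12.175)
  expect_equal(compute_shift(1, 1), 304.375)  # 1 month/yr in days/decade
  expect_error(compute_shift(0.1, 0), class = "lakeshift_zero_gradient")
})

test_that("shift is antisymmetric in trend and scale-invariant", {
  set.seed(7)
  for (i in 1:20) {
    t <- rnorm(1)
    g <- rnorm(1)
    if (g == 0) next
    k <- abs(rnorm(1)) + 0.1
    expect_equal(compute_shift(-t, g), -compute_shift(t, g))
    expect_equal(compute_shift(k * t, k * g), compute_shift(t, g),
                 tolerance = 1e-12)
  }
})

test_that("constant temperature offsets change nothing", {
  s <- random_series(11)
  s_off <- lake_series(s$years, s$temps + 7.5)
  season <- season_for("autumn", "north")
  r1 <- shift_for_season(s, season)
  r2 <- shift_for_season(s_off, season)
  expect_equal(r1$trend, r2$trend, tolerance = 1e-10)
  expect_equal(r1$gradient, r2$gradient, tolerance = 1e-10)
  expect_equal(r1$shift, r2$shift, tolerance = 1e-10)
})

test_that("a valid shift equals trend/gradient times the conversion", {
  s <- make_series(1980:2021, temperate_cycle(trend = 0.03))
  r <- shift_for_season(s, season_for("spring", "north"))
  expect_true(r$valid)
  expect_identical(r$exclusion_reason, "none")
  expect_equal(r$shift, r$trend / r$gradient * 10 * 365.25 / 12)
})

test_that("zero trend with strong seasonality gives a valid zero shift", {
  s <- make_series(1980:2021, temperate_cycle(trend = 0))
  r <- shift_for_season(s, season_for("spring", "north"))
  expect_true(r$valid)
  expect_equal(r$shift, 0)
})

test_that("ice exclusion follows the 90%-of-years rule", {
  years <- 1980:2021  # 42 years
  f <- temperate_cycle(trend = 0.03)
  # 41 of 42 icy years: 97.6% >= 90% -> excluded
  s_icy <- make_series(years, f, ice = ice_years(42, 41, months = 3:5))
  r <- shift_for_season(s_icy, season_for("spring", "north"))
  expect_false(r$valid)
  expect_identical(r$exclusion_reason, "ice_covered")
  # ice in non-window months is irrelevant
  s_winter_ice <- make_series(years, f, ice = ice_years(42, 42, months = 1:2))
  expect_true(shift_for_season(s_winter_ice,
                               season_for("spring", "north"))$valid)
})

test_that("low seasonality excludes on |gradient| with threshold retained", {
  years <- 1980:2021
  mk <- function(gap) {
    # March and May differ by 2*gap -> gradient exactly `gap`
    make_series(years, function(y, m) {
      base <- ifelse(m == 5, gap, ifelse(m == 3, -gap, 0))
      10 + base + 0.01 * (y - 1980)
    })
  }
  r_low <- shift_for_season(mk(0.4), season_for("spring", "north"))
  expect_false(r_low$valid)
  expect_identical(r_low$exclusion_reason, "low_seasonality")
  # boundary |g| = 0.5 retained
  expect_true(shift_for_season(mk(0.5), season_for("spring", "north"))$valid)
  expect_true(shift_for_season(mk(0.6), season_for("spring", "north"))$valid)
  # negative gradients are judged by magnitude (autumn-like cooling)
  r_neg <- shift_for_season(mk(-1.2), season_for("spring", "north"))
  expect_true(r_neg$valid)
  expect_true(r_neg$gradient < 0)
})

test_that("missing centre months beyond the completeness floor invalidate", {
  years <- 1980:2021
  s <- make_series(years, temperate_cycle(trend = 0.03))
  temps <- s$temps
  temps[1:12, 4] <- NA  # 12/42 = 28.6% > 25%
  r <- shift_for_season(lake_series(years, temps),
                        season_for("spring", "north"))
  expect_false(r$valid)
  expect_identical(r$exclusion_reason, "insufficient_data")
  temps2 <- s$temps
  temps2[1:10, 4] <- NA  # 23.8% <= 25%
  expect_true(shift_for_season(lake_series(years, temps2),
                               season_for("spring", "north"))$valid)
})

test_that("exclusion reasons are evaluated ice first, then data, then gradient", {
  years <- 1980:2021
  flat <- make_series(years, function(y, m) 10,
                      ice = ice_years(42, 42, months = 3:5))
  r <- shift_for_season(flat, season_for("spring", "north"))
  expect_identical(r$exclusion_reason, "ice_covered")  # not low_seasonality
  temps <- flat$temps
  temps[, 4] <- NA
  r2 <- shift_for_season(lake_series(years, temps),
                         season_for("spring", "north"))
  expect_identical(r2$exclusion_reason, "insufficient_data")
})

test_that("warming advances spring and delays autumn (sign convention)", {
  s <- make_series(1980:2021, temperate_cycle(trend = 0.03))
  spring <- shift_for_season(s, season_for("spring", "north"))
  autumn <- shift_for_season(s, season_for("autumn", "north"))
  expect_true(spring$gradient > 0)
  expect_true(spring$shift > 0)   # spring temperatures arrive earlier
  expect_true(autumn$gradient < 0)
  expect_true(autumn$shift < 0)   # autumn temperatures are delayed
})

test_that("scalar path matches a naive brute-force oracle on random series", {
  season <- season_for("summer", "north")
  for (seed in 1:5) {
    s <- random_series(seed, missing_frac = 0.05)
    r <- shift_for_season(s, season)
    # naive loops: closed-form OLS + explicit half-difference mean
    y <- s$temps[, 7]
    ok <- !is.na(y)
    slope <- ols_slope_oracle(s$years, y)
    d <- (s$temps[, 8] - s$temps[, 6]) / 2
    grad <- mean(d, na.rm = TRUE)
    expect_equal(r$trend, slope, tolerance = 1e-10)
    expect_equal(r$gradient, grad, tolerance = 1e-10)
    if (r$valid) {
      expect_equal(r$shift, slope / grad * 304.375, tolerance = 1e-10)
    }
  }
})
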