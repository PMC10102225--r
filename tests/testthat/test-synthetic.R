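test_that("spec validation rejects impossible parameters", {
  expect_error(synthetic_spec(n_years = 2))
  expect_error(synthetic_spec(amplitude = -1))
  expect_error(synthetic_spec(noise_sd = -0.5))
  expect_s3_class(synthetic_spec(), "synthetic_spec")
})

test_that("noise-free stationary climate repeats identically every year", {
  spec <- synthetic_spec(n_years = 5, warming_trend = 0, phase_drift = 0,
                         noise_sd = 0, grid_shape = c(1, 2))
  g <- generate_grid(spec)
  for (i in seq_along(g$lat)) {
    temps <- matrix(g$temps[i, , ], ncol = 12)
    for (y in 2:5) expect_equal(temps[y, ], temps[1, ])
  }
})

test_that("generation is bitwise reproducible for a fixed seed", {
  spec <- synthetic_spec(grid_shape = c(2, 2), noise_sd = 0.7, seed = 31)
  g1 <- generate_grid(spec)
  g2 <- generate_grid(spec)
  expect_identical(g1$temps, g2$temps)
  expect_identical(g1$ice, g2$ice)
  spec2 <- spec
  spec2$seed <- 32L
  expect_false(identical(generate_grid(spec2)$temps, g1$temps))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1)
  a <- rnorm(1)
  set.seed(1)
  invisible(generate_grid(synthetic_spec(grid_shape = c(1, 1))))
  expect_identical(rnorm(1), a)
})

test_that("ice flags come from the noiseless signal vs the threshold", {
  # minimum noiseless temperature is mean - amplitude = 5 > 0: no ice
  spec <- synthetic_spec(mean_temp = 15, amplitude = 10, ice_threshold = 0,
                         noise_sd = 2, grid_shape = c(2, 2))
  expect_false(any(generate_grid(spec)$ice))
  # mean 2, amplitude 10: months below 0 are flagged even with noise
  spec2 <- synthetic_spec(mean_temp = 2, amplitude = 10, ice_threshold = 0,
                          warming_trend = 0, noise_sd = 0,
                          grid_shape = c(1, 1), lat_range = c(60, 60))
  g2 <- generate_grid(spec2)
  expect_true(any(g2$ice))
  expect_equal(g2$ice[1, 1, ], g2$temps[1, 1, ] < 0)
})

test_that("southern cells peak six months away from northern cells", {
  spec <- synthetic_spec(warming_trend = 0, phase_drift = 0, noise_sd = 0,
                         grid_shape = c(2, 1), lat_range = c(-45, 45))
  g <- generate_grid(spec)
  clim <- function(i) colMeans(matrix(g$temps[i, , ], ncol = 12))
  clim_n <- clim(which(g$lat >= 0)[1])
  clim_s <- clim(which(g$lat < 0)[1])
  # the southern climatology is the northern one rolled by six months
  expect_equal(clim_s, clim_n[((0:11 + 6) %% 12) + 1], tolerance = 1e-12)
})

test_that("expected shift is definitional for drift and zero for stasis", {
  drift <- synthetic_spec(warming_trend = 0, phase_drift = 1, noise_sd = 0)
  for (m in c(1, 6, 7, 12)) expect_equal(expected_shift(drift, m), 10)
  still <- synthetic_spec(warming_trend = 0, phase_drift = 0, noise_sd = 0)
  expect_equal(expected_shift(still, 7), 0)
  # near-zero expected gradient is an error, not infinity
  flat <- synthetic_spec(amplitude = 0, warming_trend = 0.03, noise_sd = 0)
  expect_error(expected_shift(flat, 7), class = "lakeshift_zero_gradient")
})

test_that("closed-form gradient matches the estimator on noiseless data", {
  spec <- synthetic_spec(warming_trend = 0, phase_drift = 0, noise_sd = 0,
                         amplitude = 10, grid_shape = c(1, 1),
                         lat_range = c(45, 45))
  s <- grid_series(generate_grid(spec), 1)
  for (m in 2:11) {
    expect_equal(seasonal_rate_of_change(s, m), expected_gradient(spec, m),
                 tolerance = 1e-10)
  }
  # the steepest climatological rise of a 10-degree-amplitude cycle has
  # gradient 0.5 * A = 5.0; a 0.03 degC/yr warming there shifts timing by
  # 0.006 month/yr = 1.82625 days/decade
  expect_equal(compute_shift(0.03, 0.5 * 10), 1.82625)
})

test_that("warming recovery is exact against the closed form", {
  spec <- synthetic_spec(n_years = 42, warming_trend = 0.03, phase_drift = 0,
                         noise_sd = 0, ice_threshold = -Inf,
                         grid_shape = c(1, 1), lat_range = c(45, 45))
  s <- grid_series(generate_grid(spec), 1)
  for (m in 2:11) {  # interior months: no calendar-wrap trend leakage
    r <- shift_for_season(s, season_custom(m))
    if (!r$valid) next
    expect_equal(r$shift, expected_shift(spec, m), tolerance = 1e-10)
  }
})

test_that("drift recovery converges to the discretisation-corrected truth", {
  # The 2-month central difference underestimates the instantaneous
  # seasonal rate of a sinusoid by sin(pi/6)/(pi/6), so a pure translation
  # of delta days/yr is estimated as 10 * delta * (pi/6)/sin(pi/6) in the
  # small-drift limit. Check convergence there and boundedness at larger
  # drifts.
  factor <- (pi / 6) / sin(pi / 6)
  for (delta in c(0.1, 0.5)) {
    spec <- synthetic_spec(n_years = 42, warming_trend = 0,
                           phase_drift = delta, noise_sd = 0,
                           ice_threshold = -Inf, grid_shape = c(1, 1),
                           lat_range = c(45, 45))
    s <- grid_series(generate_grid(spec), 1)
    for (m in 1:12) {
      r <- shift_for_season(s, season_custom(m))
      if (!r$valid) next
      expect_equal(r$shift, 10 * delta * factor,
                   tolerance = 0.02 * (1 + delta))
    }
  }
})

test_that("mixed warming and drift adds to first order", {
  spec <- synthetic_spec(n_years = 42, warming_trend = 0.02,
                         phase_drift = 0.05, noise_sd = 0,
                         ice_threshold = -Inf, grid_shape = c(1, 1),
                         lat_range = c(45, 45))
  s <- grid_series(generate_grid(spec), 1)
  m <- 7
  r <- shift_for_season(s, season_custom(m))
  expect_true(r$valid)
  expect_equal(r$shift, expected_shift(spec, m), tolerance = 0.05)
})
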