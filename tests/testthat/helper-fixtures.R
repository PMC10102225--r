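# Fixture builders shared across test files. All data are generated in code.

# Series whose monthly means follow f(year, month); f must be vectorised in
# its first argument.
make_series <- function(years, f, ice = NULL) {
  temps <- vapply(1:12, function(m) rep_len(f(years, m), length(years)),
                  numeric(length(years)))
  lake_series(years, matrix(temps, nrow = length(years), ncol = 12),
              ice = ice)
}

# A realistic northern-temperate annual cycle: warmest in August, coldest
# in February (lakes lag the sun), plus an optional linear warming trend
# (degC / yr). Gradients at the fixed season centres are 4.33 (spring),
# 2.5 (summer) and -4.33 (autumn) times amplitude/10.
temperate_cycle <- function(mean_temp = 15, amplitude = 10, trend = 0,
                            start_year = 1980) {
  function(years, m) {
    mean_temp + amplitude * cos(2 * pi * (m - 8) / 12) +
      trend * (years - start_year)
  }
}

# Ice matrix with `n_icy` icy years (ice in all window months of the year).
ice_years <- function(n_years, n_icy, months = 1:12) {
  ice <- matrix(FALSE, n_years, 12)
  if (n_icy > 0) ice[seq_len(n_icy), months] <- TRUE
  ice
}

# Random but reproducible series for oracle-equivalence checks.
random_series <- function(seed, n_years = 42, start_year = 1980,
                          missing_frac = 0) {
  set.seed(seed)
  temps <- matrix(rnorm(n_years * 12, mean = 10, sd = 5), n_years, 12)
  if (missing_frac > 0) {
    holes <- sample(length(temps), round(missing_frac * length(temps)))
    temps[holes] <- NA
  }
  lake_series(seq(start_year, length.out = n_years), temps)
}

# Closed-form OLS slope through the normal equations, independent of the
# package's centred-sums implementation.
ols_slope_oracle <- function(x, y) {
  ok <- !is.na(y)
  X <- cbind(1, x[ok])
  beta <- solve(t(X) %*% X, t(X) %*% y[ok])
  beta[2, 1]
}
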