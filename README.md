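# lakeshift

Estimates the **pace of shifting seasons** in lake surface water
temperatures: how many days per decade the arrival of spring, summer or
autumn temperatures has advanced or been delayed, and how fast the summer
season is lengthening, from gridded or per-lake monthly temperature
records.

Seasonal thermal cues govern stratification onset, fish spawning and
plankton succession, so the *timing* of lake temperatures matters as much
as their level. For a season with centre month $m$, the shift at one
location is

```
shift = (b_m / g_m) × 10 × 365.25 / 12     [days decade⁻¹]
```

where `b_m` is the OLS trend of the centre month's temperature against
calendar year (°C yr⁻¹) and `g_m` is the climatological seasonal rate of
change — half the difference between the following and preceding months'
temperatures, averaged over all years (°C month⁻¹). Positive values mean
the season's temperatures arrive earlier. The summer-lengthening rate is
the summer shift minus the autumn shift.

Locations are excluded when the season is ice covered in ≥ 90 % of years,
when the absolute gradient is below 0.5 °C month⁻¹ (marginal seasonality,
e.g. tropical lakes), or when more than 25 % of centre-month values are
missing. Hemispheric summaries are medians with interquartile ranges over
valid locations, and ensembles (lake model × climate model members) are
computed per member and then averaged.

The package provides:

* `lake_series()` / `lake_grid()` — containers for monthly series with
  optional ice flags, Kelvin detection at ingest;
* `fit_monthly_trend()`, `seasonal_rate_of_change()`, `compute_shift()`,
  `shift_for_season()` — the statistic itself;
* `season_for()`, `moving_windows()` — fixed hemispheric seasons and the
  moving 3-month window variant;
* `compute_grid_shifts()`, `summer_length_change()`, `ensemble_average()`,
  `summarize_shifts()` — the gridded pipeline;
* `read_monthly_grid()`, `write_shift_map()`, `write_shift_table()` — CF
  style NetCDF and delimited-table I/O;
* `synthetic_spec()`, `generate_grid()`, `expected_shift()` — a synthetic
  lake-climate generator with closed-form ground truth;
* `run_shift()` / `run_synth()` — end-to-end workflow (also wrapped for
  the shell in `inst/cli/lakeshift.R`).

## Worked example

Generate a synthetic 6×6 global grid whose annual cycle arrives one day
earlier each year (a pure phase drift, true shift 10 days decade⁻¹, plus
0.5 °C observational noise), then run the full workflow:

```r
library(lakeshift)
dir <- tempfile(); dir.create(dir)
fixture <- file.path(dir, "synthetic.nc")
run_synth(synthetic_spec(phase_drift = 1, warming_trend = 0, noise_sd = 0.5,
                         grid_shape = c(6, 6), seed = 42), fixture)
res <- run_shift(list(inputs = fixture,
                      seasons = c("spring", "summer", "autumn"),
                      out_dir = file.path(dir, "out")))
print(res$summary, digits = 3)
#>     member        season hemisphere  median    q25      q75  n n_ice
#> 1 observed        spring      north 10.6556 10.389 11.06777 18     0
#> 2 observed        spring      south 10.3438  9.652 11.02636 18     0
#> 3 observed        summer      north 10.5840 10.140 10.89687 18     0
#> 4 observed        summer      south 10.3343 10.036 10.65684 18     0
#> 5 observed        autumn      north 10.8711 10.309 11.19060 18     0
#> 6 observed        autumn      south 10.7917 10.359 11.13218 18     0
#> 7 observed summer_length      north -0.0428 -0.684  0.35024 18     0
#> 8 observed summer_length      south -0.4941 -0.932  0.00898 18     0
```

Every season advances by about 10.5 days decade⁻¹ — a pure translation of
the annual cycle moves all seasons equally, so the summer length stays
unchanged (medians near 0). The small systematic excess over 10 is the
intrinsic finite-difference bias of the statistic on a sinusoidal cycle,
quantified in the methods vignette. A single location and season:

```r
s <- grid_series(read_monthly_grid(fixture), 1)
shift_for_season(s, season_for("summer", "south"))
#> <shift_result> 10.094 days decade^-1 (trend -0.1373 degC yr^-1, gradient -4.139 degC month^-1)
```

The output directory holds per-season NetCDF and CSV maps (shift, trend,
gradient, validity and exclusion-reason layers), a `summary.csv`, and a
`config.json` echo from which the run can be reproduced identically.

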