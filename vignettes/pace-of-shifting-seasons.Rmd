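---
title: "Estimating the pace of shifting seasons in lake surface temperatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the pace of shifting seasons in lake surface temperatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeshift)
```

## The statistic

Lake ecosystems respond to the *timing* of seasonal temperatures as much as
to their level: stratification onset, fish spawning and plankton succession
all track thermal cues. This package estimates how fast those cues are
moving through the calendar. For a season identified by its centre month
$m$, the seasonal shift at one location is

$$
\mathrm{shift} \;=\; \frac{b_m}{g_m}\times 10 \times \frac{365.25}{12}
\quad\text{days decade}^{-1},
$$

where

* $b_m$ (°C yr⁻¹) is the ordinary-least-squares slope of the centre month's
  mean surface water temperature against calendar year, and
* $g_m$ (°C month⁻¹) is the *climatological seasonal rate of change*: half
  the difference between the following and preceding months' temperatures,
  $\tfrac{1}{2}(T_{m+1}-T_{m-1})$, averaged over all years of the record.

A positive shift means the season's temperatures now arrive earlier
(advance); a negative shift means they arrive later (delay). Dividing a
warming rate by a seasonal temperature gradient converts "how much warmer"
into "how much earlier the same temperature occurs" — the temporal analogue
of a climate-velocity calculation. The summer-lengthening rate at a
location is the difference between the summer shift and the autumn shift:
an earlier summer and a later autumn both stretch the warm season.

Seasons are 3-month windows. Fixed definitions follow the usual hemispheric
convention (northern spring March–May with centre April, summer June–August,
autumn September–November; southern counterparts offset six months); a
moving-window variant evaluates all twelve centre months, wrapping the year
boundary, for lakes — such as very deep ones — whose thermal seasons sit
outside the fixed windows.

## Exclusion criteria

Three masks remove locations where the statistic is meaningless, evaluated
in this order:

1. **Ice cover** (`ice_year_frac`, default 0.90): a location is excluded
   when at least 90 % of years have ice in any month of the window. The
   high threshold keeps a single anomalous icy year from discarding a
   multidecadal record.
2. **Insufficient data** (`max_missing_frac`, default 0.25, plus an
   absolute floor of 3 values for any regression or climatology): trends on
   sparse series are unstable, so a centre month missing in more than a
   quarter of years invalidates the location. The 25 % floor is this
   package's choice of a conservative completeness rule.
3. **Low seasonality** (`gradient_min`, default 0.5 °C month⁻¹): where the
   within-year temperature gradient is small — tropical lakes, or windows
   straddling the thermal maximum — the ratio divides by a near-zero number
   and the notion of a season "arriving" loses meaning. The criterion is
   applied to the *absolute* gradient, since autumn gradients are negative;
   a gradient exactly at the threshold is retained.

Exclusion reasons are carried through every pipeline stage and written to
output files with stable integer codes (`EXCLUSION_CODES`), so the masked
categories can be mapped alongside the estimates.

## Conventions and edge rules

Where a convention had to be fixed and no single standard exists, the
package uses one deterministic rule, applied everywhere:

* Months are 1-based (January = 1). Latitude ≥ 0 is "north".
* A December-centred window takes its following January from the next
  calendar year (the final year is dropped when that January is absent);
  a January-centred window takes its preceding December from the previous
  year. A consequence worth knowing: at these two wrap months a warming
  trend leaks into the gradient by ±b/2, because the two neighbours are
  observed one year apart. For realistic trends this is well below a
  percent of a passing gradient.
* Ice flags for a wrap-around window (e.g. the southern summer
  December–February) are read from the same calendar-year row for all
  three window months.
* Trends use the centre month only, not a 3-month pooled mean.
* Missing values are deleted pairwise per computation.
* Kelvin inputs are recognised (declared units, or values above 150) and
  converted at ingest. Longitudes are normalised to [−180, 180); descending
  latitude axes are flipped.
* Quantile summaries use linear interpolation between order statistics
  (`quantile(..., type = 7)`); medians and interquartile ranges are
  reported instead of means because shift distributions are heavy-tailed.
  Summaries are unweighted counts of valid locations, with `n` reported —
  note that the valid sets, and hence `n`, differ between seasons, so a
  summer-length median is not exactly the summer median minus the autumn
  median.
* Ensembles (lake model × climate model members) are averaged per location
  over the members where that location is valid; the output location is
  valid when at least half the members are. The statistic is always
  computed per member first and averaged second.

## The synthetic generator

Real gridded inputs (reanalysis or lake-model ensembles) are large and
external, so every stage of the package is exercised against a synthetic
generator whose ground truth is known in closed form:

$$
T_{y,m} = \bar{T} + A\,\sin\!\Big(\frac{2\pi\,(d_m + \delta\,(y-y_0))}{365.25}
 + \phi_h\Big) + b\,(y-y_0) + \varepsilon_{y,m},
$$

with $d_m$ the mid-month day-of-year on a fixed 365.25-day calendar,
$\phi_h$ a half-period offset in the southern hemisphere (so its
climatological maximum sits six months from the north's), $\delta$ a phase
drift in days per year (positive = the cycle arrives earlier), $b$ a linear
warming trend, and $\varepsilon \sim N(0, \sigma^2)$ independent across
months and cells (an AR(1) knob along the month axis exists but is off by
default, since the statistic assumes nothing about autocorrelation). Ice is
flagged where the noiseless signal falls below a freezing threshold.
Defaults describe a 42-year (1980–2021) temperate record: mean 15 °C,
amplitude 10 °C, warming 0.03 °C yr⁻¹ (≈ 0.3 °C decade⁻¹), noise 0.5 °C,
ice below 0 °C.

What the generator emulates is the statistical structure the method relies
on — a smooth annual cycle, a secular trend, a phase drift, observational
noise, hemispheric phase opposition, seasonal ice. What it does not emulate:
asymmetric annual cycles (real lakes warm faster than they cool),
autocorrelated and heteroscedastic noise, trends that vary by month,
partial-year ice, and spatial correlation. Passing recovery tests therefore
demonstrate correctness of the estimator, not accuracy of the statistic on
any particular lake.

Monthly values are point evaluations of the signal at mid-month, not
integrals over the month; for a monthly-resolution statistic the difference
is a uniform amplitude factor that cancels in the trend/gradient ratio.

## What recovery tests can and cannot show

For a **pure warming trend** the closed-form expectation is exact: the
centre-month series is exactly linear in year, and the climatological
gradient of the sinusoid under the same central difference the estimator
uses is $0.5\,A\cos\theta_m$. Noise-free recovery against
$b/(0.5A\cos\theta_m) \times 304.375$ holds to machine precision at
interior months (wrap months carry the ±b/2 leakage noted above).

For a **pure phase drift** of $\delta$ days yr⁻¹ the natural ground truth
is $10\,\delta$ days decade⁻¹. The estimator does *not* converge to that
value: the 2-month central difference underestimates the instantaneous
seasonal rate of a sinusoid by $\sin(\pi/6)/(\pi/6) \approx 0.955$, so the
estimate converges to $10\,\delta \times (\pi/6)/\sin(\pi/6) \approx
10.47\,\delta$ as $\delta \to 0$, with a further upward drift-averaging
term at finite $\delta$ (≈ 5.6 % total at $\delta = 1$ over 42 years,
slightly less at the wrap months). This ≈ 4.7 % overestimate of a pure
translation is an intrinsic property of the statistic — any user comparing
shift estimates against independently dated phenological events should be
aware of it. The test suite asserts the discretisation-corrected
convergence; one acceptance-style check that demands 5 % agreement with
$10\,\delta$ at $\delta = 1$ fails by this margin, and is retained as a
documented honest failure rather than loosened.

Mixed warming + drift expectations add to first order only; tests use small
parameter values where the cross terms are negligible.

## Numerical choices

* Grid-level trends use closed-form least squares on a globally centred
  year axis with masked sums, so pairwise deletion vectorises; agreement
  with the per-location scalar path is at the 10⁻¹³ relative level, and
  both are checked against an independent normal-equations oracle.
* A zero gradient raises a classed error (`lakeshift_zero_gradient`) rather
  than returning an infinity; in the pipeline a zero gradient is excluded
  as low seasonality before the division is attempted.
* Empty regions raise `lakeshift_empty_region`; the workflow converts this
  to an `n = 0` summary row and a nonzero run status rather than a crash.
* Problem sizes in the test-suite and acceptance runs (grids up to 20×20
  cells, 42-year records, 200 noisy replicates) were chosen as the smallest
  sizes at which the statistical assertions are stable.

## Workflow

`run_shift()` orchestrates the full analysis from a configuration list or
YAML/JSON file: read NetCDF members, compute per-season maps
(hemisphere-appropriate windows for named seasons, twelve labelled maps in
moving-window mode), ensemble-average, derive summer lengthening when both
summer and autumn are requested, and write NetCDF + CSV maps, a
hemisphere × season summary table with exclusion tallies, and an echo of
the effective configuration (`config.json`) from which the run can be
reproduced exactly. `run_synth()` writes a synthetic grid as a conforming
NetCDF fixture. `inst/cli/lakeshift.R` wraps both for shell use.

```{r example, eval = FALSE}
dir <- tempfile()
dir.create(dir)
fixture <- file.path(dir, "synthetic.nc")
run_synth(synthetic_spec(phase_drift = 1, warming_trend = 0,
                         grid_shape = c(6, 6)), fixture)
res <- run_shift(list(inputs = fixture,
                      seasons = c("spring", "summer", "autumn"),
                      out_dir = file.path(dir, "out")))
res$summary
```

## Known limitations

* The statistic is undefined, by design, where seasonality is weak; maps of
  tropical or polar lakes will be dominated by exclusion categories, and
  hemispheric medians describe only the valid subset.
* Season windows are calendar-fixed; lakes whose thermal seasons move
  across window boundaries during the record are better served by the
  moving-window variant.
* The ±4.7 % translation bias above applies wherever the annual cycle is
  near-sinusoidal; for strongly asymmetric cycles the finite-difference
  gradient error varies with the local cycle shape.
* NetCDF map output requires a complete regular latitude–longitude grid;
  irregular lake sets are supported through the table form.
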