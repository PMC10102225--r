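Package: lakeshift
Title: Pace of Shifting Seasons in Lake Surface Water Temperatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates how many days per decade seasonal lake surface water
    temperatures advance or are delayed, by dividing the long-term trend in
    monthly surface water temperature (degrees C per year) by the
    climatological seasonal rate of change (degrees C per month) and
    converting to days per decade. Provides fixed hemispheric seasons and a
    moving 3-month window variant, ice-cover and low-seasonality exclusion
    masks, gridded and per-lake pipelines, ensemble averaging across lake and
    climate models, hemispheric median and interquartile-range summaries,
    summer-lengthening maps, NetCDF and delimited-table input/output, and a
    synthetic lake-climate generator with closed-form expected shifts for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ncdf4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
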