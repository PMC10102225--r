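#' Read a gridded monthly temperature file
#'
#' Loads a NetCDF file with CF-style `(lon, lat, time)` coordinates into a
#' [lake_grid()]. The time axis is resolved to calendar (year, month) from
#' its `units` attribute (`"<days|hours|minutes|seconds> since <origin>"`);
#' sub-monthly time steps are averaged to calendar months with a notice.
#' Kelvin input is converted to degrees C when declared by the variable's
#' `units` attribute or detected by magnitude (values above 150).
#' Longitudes are normalised to \[-180, 180) and latitudes flipped to
#' ascending order if needed (with a notice), so grids written with either
#' convention load identically.
#'
#' @param path Path to a NetCDF file.
#' @param var Name of the temperature variable; `NULL` picks the first
#'   3-dimensional non-ice variable.
#' @param ice_var Optional name of a monthly ice-cover variable (nonzero =
#'   ice); `NULL` loads `"ice"` if present.
#' @param year_range Optional `c(first, last)` calendar years to keep.
#' @return A [lake_grid()]. Locations are ordered latitude-outer,
#'   longitude-inner, both ascending.
#' @export
read_monthly_grid <- function(path, var = NULL, ice_var = NULL,
                              year_range = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))

  vars3d <- names(nc$var)[vapply(nc$var, function(v) v$ndims == 3L,
                                 logical(1))]
  if (is.null(ice_var) && "ice" %in% vars3d) ice_var <- "ice"
  if (is.null(var)) {
    cand <- setdiff(vars3d, ice_var)
    if (length(cand) == 0L) {
      io_error("lakeshift_missing_variable",
               "no 3-dimensional temperature variable found")
    }
    var <- cand[1L]
  }
  if (!var %in% names(nc$var)) {
    io_error("lakeshift_missing_variable",
             sprintf("variable '%s' not found in %s", var, path))
  }

  lon <- as.numeric(nc$dim[[nc$var[[var]]$dim[[1L]]$name]]$vals)
  lat <- as.numeric(nc$dim[[nc$var[[var]]$dim[[2L]]$name]]$vals)
  tdim <- nc$var[[var]]$dim[[3L]]
  ym <- resolve_time_axis(tdim$vals, tdim$units)

  temps <- ncdf4::ncvar_get(nc, var, collapse_degen = FALSE)
  units_att <- ncdf4::ncatt_get(nc, var, "units")
  declared <- if (isTRUE(units_att$hasatt)) units_att$value else NULL
  ice_raw <- if (!is.null(ice_var) && ice_var %in% names(nc$var)) {
    ncdf4::ncvar_get(nc, ice_var, collapse_degen = FALSE)
  } else NULL

  # normalise coordinates: lon to [-180, 180), both axes ascending
  lon_norm <- ((lon + 180) %% 360) - 180
  olon <- order(lon_norm)
  if (!identical(olon, seq_along(lon_norm))) {
    temps <- temps[olon, , , drop = FALSE]
    if (!is.null(ice_raw)) ice_raw <- ice_raw[olon, , , drop = FALSE]
    lon_norm <- lon_norm[olon]
  }
  if (length(lat) > 1 && is.unsorted(lat)) {
    message("flipping descending latitude axis to ascending")
    olat <- order(lat)
    temps <- temps[, olat, , drop = FALSE]
    if (!is.null(ice_raw)) ice_raw <- ice_raw[, olat, , drop = FALSE]
    lat <- lat[olat]
  }

  # collapse the time axis to calendar (year, month) means
  key <- ym$year * 100L + ym$month
  ukey <- sort(unique(key))
  if (length(ukey) < length(key)) {
    message("averaging sub-monthly time axis to calendar months")
  }
  n_lon <- length(lon_norm)
  n_lat <- length(lat)
  monthly <- array(NA_real_, dim = c(n_lon, n_lat, length(ukey)))
  ice_m <- if (!is.null(ice_raw)) array(FALSE, dim = dim(monthly)) else NULL
  for (i in seq_along(ukey)) {
    sel <- which(key == ukey[i])
    slab <- temps[, , sel, drop = FALSE]
    monthly[, , i] <- if (length(sel) == 1L) slab[, , 1L] else
      apply(slab, c(1L, 2L), mean)
    if (!is.null(ice_raw)) {
      islab <- ice_raw[, , sel, drop = FALSE]
      ice_m[, , i] <- apply(islab, c(1L, 2L), function(v)
        any(!is.na(v) & v > 0.5))
    }
  }
  uyear <- ukey %/% 100L
  umonth <- ukey %% 100L

  if (!is.null(year_range)) {
    keep <- uyear >= year_range[1L] & uyear <= year_range[2L]
    if (!any(keep)) {
      io_error("lakeshift_empty_years",
               sprintf("requested years %d-%d do not intersect file years %d-%d",
                       year_range[1L], year_range[2L],
                       min(uyear), max(uyear)))
    }
    monthly <- monthly[, , keep, drop = FALSE]
    if (!is.null(ice_m)) ice_m <- ice_m[, , keep, drop = FALSE]
    uyear <- uyear[keep]
    umonth <- umonth[keep]
  }

  years <- seq(min(uyear), max(uyear))
  n_loc <- n_lon * n_lat
  arr <- array(NA_real_, dim = c(n_loc, length(years), 12L))
  ice_arr <- if (!is.null(ice_m)) array(FALSE, dim = dim(arr)) else NULL
  # location order: latitude outer, longitude inner
  for (i in seq_along(uyear)) {
    slab <- monthly[, , i]
    arr[, uyear[i] - years[1L] + 1L, umonth[i]] <- as.numeric(slab)
    if (!is.null(ice_m)) {
      ice_arr[, uyear[i] - years[1L] + 1L, umonth[i]] <-
        as.numeric(ice_m[, , i]) > 0
    }
  }
  arr_flat <- maybe_kelvin_to_celsius(arr, declared = declared)
  coords <- expand.grid(lon = lon_norm, lat = lat,
                        KEEP.OUT.ATTRS = FALSE)[, c("lat", "lon")]
  lake_grid(coords$lat, coords$lon, years, arr_flat, ice = ice_arr)
}

io_error <- function(class, msg) {
  stop(structure(class = c(class, "lakeshift_io_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# "X since <date>[ <time>]" time axes, proleptic/standard calendars
resolve_time_axis <- function(vals, units) {
  m <- regmatches(units, regexec(
    "^\\s*(days?|hours?|minutes?|seconds?)\\s+since\\s+(\\S+)( .*)?$",
    units, ignore.case = TRUE))[[1L]]
  if (length(m) == 0L) {
    io_error("lakeshift_bad_time_axis",
             sprintf("cannot parse time units '%s'", units))
  }
  scale <- switch(tolower(sub("s$", "", m[2L])),
                  day = 86400, hour = 3600, minute = 60, second = 1)
  origin <- as.POSIXct(m[3L], tz = "UTC", tryFormats = c("%Y-%m-%d"))
  if (is.na(origin)) {
    io_error("lakeshift_bad_time_axis",
             sprintf("cannot parse time origin in '%s'", units))
  }
  stamp <- origin + vals * scale
  list(year = as.integer(format(stamp, "%Y")),
       month = as.integer(format(stamp, "%m")))
}

#' Write a lake grid as a CF-style NetCDF file
#'
#' Inverse of [read_monthly_grid()]: locations must form a complete regular
#' latitude-longitude grid. Time is written at mid-month (the 15th) in
#' days since 1970-01-01. Ice flags, when present, are written as a 0/1
#' variable named `"ice"`.
#'
#' @param grid A [lake_grid()] on a regular grid.
#' @param path Output path.
#' @param var Temperature variable name.
#' @param units `"degC"` (default) or `"K"` for Kelvin output.
#' @return `path`, invisibly.
#' @export
write_monthly_grid <- function(grid, path, var = "watertemp",
                               units = c("degC", "K")) {
  stopifnot(inherits(grid, "lake_grid"))
  units <- match.arg(units)
  g <- regular_grid_layout(grid$lat, grid$lon)

  years <- grid$years
  n_t <- length(years) * 12L
  dates <- as.Date(sprintf("%04d-%02d-15", rep(years, each = 12L),
                           rep(1:12, length(years))))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lats)
  dim_t <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                            as.numeric(dates), unlim = TRUE)
  fill <- 9.9692099683868690e36
  v_temp <- ncdf4::ncvar_def(var, units, list(dim_lon, dim_lat, dim_t),
                             missval = fill, prec = "double")
  vars <- list(v_temp)
  if (!is.null(grid$ice)) {
    vars$ice <- ncdf4::ncvar_def("ice", "1", list(dim_lon, dim_lat, dim_t),
                                 missval = -1L, prec = "integer")
  }
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))

  offset <- if (units == "K") 273.15 else 0
  arr <- array(NA_real_, dim = c(g$n_lon, g$n_lat, n_t))
  for (yi in seq_along(years)) {
    for (m in 1:12) {
      t_i <- (yi - 1L) * 12L + m
      arr[, , t_i] <- grid$temps[g$loc_index, yi, m] + offset
    }
  }
  ncdf4::ncvar_put(nc, v_temp, arr)
  if (!is.null(grid$ice)) {
    iarr <- array(0L, dim = c(g$n_lon, g$n_lat, n_t))
    for (yi in seq_along(years)) {
      for (m in 1:12) {
        iarr[, , (yi - 1L) * 12L + m] <-
          as.integer(grid$ice[g$loc_index, yi, m])
      }
    }
    ncdf4::ncvar_put(nc, vars$ice, iarr)
  }
  ncdf4::ncatt_put(nc, 0, "source", "lakeshift synthetic/processed grid")
  invisible(path)
}

# Check that (lat, lon) pairs form a complete regular grid and return the
# axes plus, for each (lon-inner, lat-outer) cell, the location index.
regular_grid_layout <- function(lat, lon) {
  lats <- sort(unique(lat))
  lons <- sort(unique(lon))
  n_lat <- length(lats)
  n_lon <- length(lons)
  if (n_lat * n_lon != length(lat)) {
    stop("locations do not form a complete regular grid; use the table export",
         call. = FALSE)
  }
  key <- paste(lat, lon)
  want <- paste(rep(lats, each = n_lon), rep(lons, n_lat))
  loc_index <- match(want, key)
  if (anyNA(loc_index)) {
    stop("locations do not form a complete regular grid; use the table export",
         call. = FALSE)
  }
  list(lats = lats, lons = lons, n_lat = n_lat, n_lon = n_lon,
       loc_index = loc_index)
}

#' Write a shift map to NetCDF
#'
#' Stores `shift`, `trend` and `gradient` as double layers plus integer
#' `valid` (0/1) and `reason` layers; exclusion reasons use the stable
#' codes of [EXCLUSION_CODES]. Season and ensemble-member metadata are
#' recorded as global attributes. Locations must form a complete regular
#' grid; for per-lake sets use [write_shift_table()].
#'
#' @param map A `shift_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shift_map <- function(map, path) {
  stopifnot(inherits(map, "shift_map"))
  g <- regular_grid_layout(map$lat, map$lon)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lats)
  fill <- 9.9692099683868690e36
  dd <- function(name, units) {
    ncdf4::ncvar_def(name, units, list(dim_lon, dim_lat),
                     missval = fill, prec = "double")
  }
  di <- function(name) {
    ncdf4::ncvar_def(name, "1", list(dim_lon, dim_lat),
                     missval = -1L, prec = "integer")
  }
  vars <- list(shift = dd("shift", "days decade-1"),
               trend = dd("trend", "degC year-1"),
               gradient = dd("gradient", "degC month-1"),
               valid = di("valid"), reason = di("reason"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  as_grid <- function(v) array(v[g$loc_index], dim = c(g$n_lon, g$n_lat))
  ncdf4::ncvar_put(nc, vars$shift, as_grid(map$shift))
  ncdf4::ncvar_put(nc, vars$trend, as_grid(map$trend))
  ncdf4::ncvar_put(nc, vars$gradient, as_grid(map$gradient))
  ncdf4::ncvar_put(nc, vars$valid, as_grid(as.integer(map$valid)))
  ncdf4::ncvar_put(nc, vars$reason,
                   as_grid(EXCLUSION_CODES[map$exclusion_reason]))
  season <- attr(map, "season")
  ncdf4::ncatt_put(nc, 0, "season_name", as.character(season$name))
  ncdf4::ncatt_put(nc, 0, "season_centre_month",
                   if (is.na(season$centre_month)) -1L else
                     as.integer(season$centre_month))
  ncdf4::ncatt_put(nc, 0, "season_hemisphere",
                   as.character(season$hemisphere))
  ncdf4::ncatt_put(nc, 0, "member", as.character(attr(map, "member")))
  yrs <- attr(map, "years")
  if (!is.null(yrs)) {
    ncdf4::ncatt_put(nc, 0, "year_start", as.integer(yrs[1L]))
    ncdf4::ncatt_put(nc, 0, "year_end", as.integer(yrs[2L]))
  }
  invisible(path)
}

#' Read a shift map written by [write_shift_map()]
#'
#' @param path Path to the NetCDF file.
#' @return A `shift_map` with locations ordered latitude-outer,
#'   longitude-inner.
#' @export
read_shift_map <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- as.numeric(nc$dim$lon$vals)
  lat <- as.numeric(nc$dim$lat$vals)
  flat <- function(name) {
    v <- ncdf4::ncvar_get(nc, name, collapse_degen = FALSE)
    # [lon, lat] -> location order lat-outer, lon-inner
    as.numeric(v)
  }
  n_lon <- length(lon)
  n_lat <- length(lat)
  reason_code <- as.integer(flat("reason"))
  reason <- names(EXCLUSION_CODES)[match(reason_code, EXCLUSION_CODES)]
  att <- function(name) ncdf4::ncatt_get(nc, 0, name)$value
  centre <- att("season_centre_month")
  season <- list(name = att("season_name"),
                 centre_month = if (centre < 0) NA_integer_ else
                   as.integer(centre),
                 window = NA_integer_,
                 hemisphere = att("season_hemisphere"))
  if (!is.na(season$centre_month)) {
    season$window <- wrap_month(season$centre_month + c(-1L, 0L, 1L))
    class(season) <- "season_def"
  }
  ys <- ncdf4::ncatt_get(nc, 0, "year_start")
  years <- if (isTRUE(ys$hasatt)) {
    c(ys$value, ncdf4::ncatt_get(nc, 0, "year_end")$value)
  } else NULL
  coords <- expand.grid(lon = lon, lat = lat,
                        KEEP.OUT.ATTRS = FALSE)[, c("lat", "lon")]
  new_shift_map(coords$lat, coords$lon, NULL,
                flat("trend"), flat("gradient"), flat("shift"),
                as.integer(flat("valid")) == 1L, reason,
                season = season, member = att("member"), years = years)
}

#' Export a shift map as a delimited table
#'
#' One row per location with `lat`, `lon`, (`id`,) `trend`, `gradient`,
#' `shift`, `valid` and `exclusion_reason` columns; season and member
#' metadata are written as `#`-prefixed header comments. Numeric values
#' are written with 17 significant digits so the round trip through
#' [read_shift_table()] is exact.
#'
#' @param map A `shift_map`.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(map, path) {
  stopifnot(inherits(map, "shift_map"))
  season <- attr(map, "season")
  df <- as.data.frame(map)
  num_cols <- c("lat", "lon", "trend", "gradient", "shift")
  for (cl in num_cols) df[[cl]] <- sprintf("%.17g", df[[cl]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# season_name=%s", season$name),
               sprintf("# season_centre_month=%s", season$centre_month),
               sprintf("# season_hemisphere=%s", season$hemisphere),
               sprintf("# member=%s", attr(map, "member"))), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a shift table written by [write_shift_table()]
#'
#' @param path Path to the CSV file.
#' @return A `shift_map`.
#' @export
read_shift_table <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- list()
  for (line in hdr) {
    kv <- strsplit(sub("^# ", "", line), "=", fixed = TRUE)[[1L]]
    meta[[kv[1L]]] <- kv[2L]
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  centre <- suppressWarnings(as.integer(meta$season_centre_month))
  season <- list(name = meta$season_name, centre_month = centre,
                 window = NA_integer_, hemisphere = meta$season_hemisphere)
  if (!is.na(centre)) {
    season$window <- wrap_month(centre + c(-1L, 0L, 1L))
    class(season) <- "season_def"
  }
  for (cl in c("lat", "lon", "trend", "gradient", "shift")) {
    df[[cl]] <- as.numeric(df[[cl]])
  }
  new_shift_map(df$lat, df$lon, df$id, df$trend, df$gradient, df$shift,
                as.logical(df$valid), df$exclusion_reason,
                season = season, member = meta$member)
}
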