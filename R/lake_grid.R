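#' Collection of monthly temperature series with coordinates
#'
#' Container for many co-registered locations sharing one year range:
#' grid cells of a gridded product or a set of individual lakes. The
#' temperature field is a 3-dimensional array (location, year, month) so
#' that grid-level statistics can be computed with vectorised matrix
#' operations.
#'
#' @param lat,lon Numeric vectors, one entry per location. For per-lake
#'   collections these are the lake coordinates; `id` can carry lake names.
#' @param years Integer vector of contiguous calendar years shared by all
#'   locations.
#' @param temps Numeric array of dimension (n_locations, n_years, 12),
#'   degrees C, `NA` for missing months.
#' @param ice Optional logical array of the same dimension.
#' @param id Optional character vector of location identifiers.
#' @return An object of class `lake_grid`.
#' @seealso [as_lake_grid()] to build one from a list of [lake_series()].
#' @export
lake_grid <- function(lat, lon, years, temps, ice = NULL, id = NULL) {
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  years <- as.integer(years)
  n_loc <- length(lat)
  if (length(lon) != n_loc) stop("`lat` and `lon` lengths differ", call. = FALSE)
  if (n_loc < 1L) stop("grid must contain at least one location", call. = FALSE)
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("`years` must be strictly increasing and contiguous", call. = FALSE)
  }
  if (!is.array(temps) || length(dim(temps)) != 3L ||
      !all(dim(temps) == c(n_loc, length(years), 12L))) {
    stop("`temps` must be an array of dim (n_locations, n_years, 12)",
         call. = FALSE)
  }
  storage.mode(temps) <- "double"
  if (any(is.infinite(temps))) {
    stop("non-missing temperatures must be finite", call. = FALSE)
  }
  if (!is.null(ice)) {
    if (!is.array(ice) || !all(dim(ice) == dim(temps)) || !is.logical(ice)) {
      stop("`ice` must be a logical array matching `temps`", call. = FALSE)
    }
    ice[is.na(ice)] <- FALSE
  }
  if (!is.null(id) && length(id) != n_loc) {
    stop("`id` must have one entry per location", call. = FALSE)
  }
  structure(list(lat = lat, lon = lon, years = years,
                 temps = temps, ice = ice, id = id),
            class = "lake_grid")
}

#' Assemble a grid from individual series
#'
#' @param series_list List of [lake_series()] sharing one year range.
#' @param lat,lon Coordinates, one per series.
#' @param id Optional identifiers, one per series.
#' @return A [lake_grid()].
#' @export
as_lake_grid <- function(series_list, lat, lon, id = NULL) {
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, is_lake_series, logical(1))))
  years <- series_list[[1L]]$years
  same <- vapply(series_list, function(s) identical(s$years, years),
                 logical(1))
  if (!all(same)) stop("all series must share the same year range", call. = FALSE)
  n_loc <- length(series_list)
  temps <- array(NA_real_, dim = c(n_loc, length(years), 12L))
  has_ice <- any(!vapply(series_list, function(s) is.null(s$ice), logical(1)))
  ice <- if (has_ice) array(FALSE, dim = dim(temps)) else NULL
  for (i in seq_len(n_loc)) {
    temps[i, , ] <- series_list[[i]]$temps
    if (has_ice && !is.null(series_list[[i]]$ice)) {
      ice[i, , ] <- series_list[[i]]$ice
    }
  }
  lake_grid(lat, lon, years, temps, ice = ice, id = id)
}

#' Extract one location as a lake_series
#'
#' @param grid A [lake_grid()].
#' @param i Location index.
#' @return A [lake_series()].
#' @export
grid_series <- function(grid, i) {
  stopifnot(inherits(grid, "lake_grid"))
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= length(grid$lat))
  temps <- matrix(grid$temps[i, , ], ncol = 12L)
  ice <- if (is.null(grid$ice)) NULL else matrix(grid$ice[i, , ], ncol = 12L)
  lake_series(grid$years, temps, ice = ice)
}

#' @export
print.lake_grid <- function(x, ...) {
  cat(sprintf("<lake_grid> %d locations, years %d-%d%s\n",
              length(x$lat), min(x$years), max(x$years),
              if (is.null(x$ice)) "" else ", with ice flags"))
  invisible(x)
}
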