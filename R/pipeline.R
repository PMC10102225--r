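#' Per-location seasonal shifts over a grid or lake set
#'
#' Applies the seasonal-shift statistic to every location of a
#' [lake_grid()] for one season definition, using vectorised matrix
#' operations (a closed-form least-squares slope per location with
#' pairwise deletion of missing years, and a mean central difference for
#' the climatological gradient). Exclusion reasons are evaluated per
#' location in the order ice cover, insufficient data, low seasonality,
#' exactly as in [shift_for_season()].
#'
#' @param grid A [lake_grid()].
#' @param season A `season_def`.
#' @param criteria An [exclusion_criteria()].
#' @param member Ensemble-member label recorded on the result (e.g.
#'   `"observed"` or a lake-model x climate-model combination).
#' @return A `shift_map`: data frame with one row per location and columns
#'   `lat`, `lon`, (`id`,) `trend`, `gradient`, `shift`, `valid`,
#'   `exclusion_reason`, carrying the season and member as attributes.
#' @export
compute_grid_shifts <- function(grid, season, criteria = exclusion_criteria(),
                                member = "observed") {
  stopifnot(inherits(grid, "lake_grid"), inherits(season, "season_def"),
            inherits(criteria, "exclusion_criteria"))
  n_loc <- length(grid$lat)
  n_yr <- length(grid$years)
  centre <- season$centre_month

  # centre-month OLS slope per location, pairwise deletion
  y <- matrix(grid$temps[, , centre], nrow = n_loc)
  m <- is.finite(y)
  y0 <- ifelse(m, y, 0)
  # centre the year axis globally for numerical conditioning; per-location
  # re-centring (pairwise deletion) happens through the masked sums
  x <- as.numeric(grid$years) - mean(as.numeric(grid$years))
  n <- rowSums(m)
  sx <- as.numeric(m %*% x)
  sxx <- as.numeric(m %*% (x * x))
  sy <- rowSums(y0)
  sxy <- as.numeric(y0 %*% x)
  denom <- n * sxx - sx * sx
  trend <- ifelse(n >= 3, (n * sxy - sx * sy) / denom, NA_real_)

  # climatological gradient: mean over years of (T[next] - T[prev]) / 2,
  # with December/January neighbours drawn from the adjacent calendar year
  prev_m <- wrap_month(centre - 1L)
  next_m <- wrap_month(centre + 1L)
  shift_cols <- function(mat, off) {
    if (off == 0L) return(mat)
    out <- matrix(NA_real_, nrow = nrow(mat), ncol = ncol(mat))
    if (off == 1L) out[, seq_len(n_yr - 1L)] <- mat[, 2L:n_yr]
    if (off == -1L) out[, 2L:n_yr] <- mat[, seq_len(n_yr - 1L)]
    out
  }
  pmat <- shift_cols(matrix(grid$temps[, , prev_m], nrow = n_loc),
                     if (centre == 1L) -1L else 0L)
  nmat <- shift_cols(matrix(grid$temps[, , next_m], nrow = n_loc),
                     if (centre == 12L) 1L else 0L)
  d <- (nmat - pmat) / 2
  dm <- is.finite(d)
  npairs <- rowSums(dm)
  gradient <- ifelse(npairs >= 3, rowSums(ifelse(dm, d, 0)) / npairs,
                     NA_real_)

  reason <- rep("none", n_loc)
  if (!is.null(grid$ice)) {
    icy <- grid$ice[, , season$window[1L]] |
      grid$ice[, , season$window[2L]] |
      grid$ice[, , season$window[3L]]
    icy <- matrix(icy, nrow = n_loc)
    reason[rowMeans(icy) >= criteria$ice_year_frac] <- "ice_covered"
  }
  centre_missing <- 1 - n / n_yr
  insufficient <- is.na(trend) | is.na(gradient) |
    centre_missing > criteria$max_missing_frac
  reason[reason == "none" & insufficient] <- "insufficient_data"
  low <- !is.na(gradient) &
    (gradient == 0 | abs(gradient) < criteria$gradient_min)
  reason[reason == "none" & low] <- "low_seasonality"

  valid <- reason == "none"
  shift <- rep(NA_real_, n_loc)
  shift[valid] <- compute_shift(trend[valid], gradient[valid])

  new_shift_map(grid$lat, grid$lon, grid$id, trend, gradient, shift,
                valid, reason, season = season, member = member,
                years = range(grid$years))
}

new_shift_map <- function(lat, lon, id, trend, gradient, shift, valid,
                          reason, season, member, years = NULL) {
  df <- data.frame(lat = lat, lon = lon, trend = trend,
                   gradient = gradient, shift = shift, valid = valid,
                   exclusion_reason = reason,
                   stringsAsFactors = FALSE)
  if (!is.null(id)) df$id <- id
  structure(df, season = season, member = member, years = years,
            class = c("shift_map", "data.frame"))
}

#' Seasonal shifts with hemisphere-appropriate season windows
#'
#' For a named season on a grid spanning both hemispheres, northern
#' locations use the northern window and southern locations the window
#' offset by six months. Results are returned as a single map in the
#' original location order.
#'
#' @inheritParams compute_grid_shifts
#' @param name `"spring"`, `"summer"` or `"autumn"`.
#' @return A `shift_map`.
#' @export
compute_season_shifts <- function(grid, name,
                                  criteria = exclusion_criteria(),
                                  member = "observed") {
  stopifnot(inherits(grid, "lake_grid"))
  hemis <- hemisphere_of(grid$lat)
  out <- NULL
  for (h in c("north", "south")) {
    idx <- which(hemis == h)
    if (length(idx) == 0L) next
    sub <- subset_grid(grid, idx)
    map <- compute_grid_shifts(sub, season_for(name, h), criteria, member)
    if (is.null(out)) {
      out <- map[rep(1L, length(grid$lat)), , drop = FALSE]
      out[] <- NA
    }
    out[idx, ] <- map
  }
  rownames(out) <- NULL
  structure(out,
            season = list(name = name, centre_month = NA_integer_,
                          window = NA_integer_, hemisphere = "both"),
            member = member, years = range(grid$years),
            class = c("shift_map", "data.frame"))
}

subset_grid <- function(grid, idx) {
  lake_grid(grid$lat[idx], grid$lon[idx], grid$years,
            grid$temps[idx, , , drop = FALSE],
            ice = if (is.null(grid$ice)) NULL else
              grid$ice[idx, , , drop = FALSE],
            id = if (is.null(grid$id)) NULL else grid$id[idx])
}

#' Change in the length of the summer-temperature season
#'
#' Per location, the lengthening of the period with summer temperatures is
#' the difference between the seasonal shift in the start of summer and
#' the shift in the start of autumn: an advance of summer and a delay of
#' autumn both lengthen the season. Positive values mean the summer season
#' has lengthened. A location is valid only where both input maps are
#' valid; otherwise it inherits the first invalid input's reason (summer
#' checked first).
#'
#' @param summer,autumn `shift_map`s for the summer and autumn seasons on
#'   identical locations and ensemble member.
#' @return A `shift_map` whose `shift` column is the summer-length trend in
#'   days per decade (`trend` and `gradient` are `NA`; they do not apply to
#'   a difference of shifts).
#' @export
summer_length_change <- function(summer, autumn) {
  stopifnot(inherits(summer, "shift_map"), inherits(autumn, "shift_map"))
  if (!isTRUE(all.equal(summer$lat, autumn$lat)) ||
      !isTRUE(all.equal(summer$lon, autumn$lon))) {
    stop("summer and autumn maps must cover identical locations",
         call. = FALSE)
  }
  if (!identical(attr(summer, "member"), attr(autumn, "member"))) {
    stop("summer and autumn maps must come from the same ensemble member",
         call. = FALSE)
  }
  valid <- summer$valid & autumn$valid
  shift <- ifelse(valid, summer$shift - autumn$shift, NA_real_)
  reason <- ifelse(valid, "none",
                   ifelse(!summer$valid, summer$exclusion_reason,
                          autumn$exclusion_reason))
  new_shift_map(summer$lat, summer$lon, summer$id,
                rep(NA_real_, nrow(summer)), rep(NA_real_, nrow(summer)),
                shift, valid, reason,
                season = list(name = "summer_length",
                              centre_month = NA_integer_,
                              window = NA_integer_, hemisphere = "both"),
                member = attr(summer, "member"),
                years = attr(summer, "years"))
}

#' Average seasonal shifts across an ensemble
#'
#' The statistic is computed independently for each ensemble member (each
#' lake-model x climate-model combination) and then averaged: per location,
#' the arithmetic mean of `shift` (and of `trend` and `gradient`) over the
#' members where that location is valid. A location is valid in the output
#' when it is valid in at least half of the members; otherwise it carries
#' the first invalid member's exclusion reason.
#'
#' @param members Non-empty list of `shift_map`s sharing locations and
#'   season.
#' @param member Label for the averaged map (default `"ensemble_mean"`).
#' @return A `shift_map`.
#' @export
ensemble_average <- function(members, member = "ensemble_mean") {
  if (!is.list(members) || length(members) == 0L ||
      !all(vapply(members, inherits, logical(1), "shift_map"))) {
    stop("`members` must be a non-empty list of shift maps", call. = FALSE)
  }
  ref <- members[[1L]]
  for (m in members[-1L]) {
    if (!isTRUE(all.equal(ref$lat, m$lat)) ||
        !isTRUE(all.equal(ref$lon, m$lon))) {
      stop("all members must cover identical locations", call. = FALSE)
    }
  }
  k <- length(members)
  validm <- vapply(members, function(m) m$valid, logical(nrow(ref)))
  validm <- matrix(validm, nrow = nrow(ref))
  n_valid <- rowSums(validm)
  out_valid <- n_valid >= k / 2

  mean_over_valid <- function(col) {
    vals <- vapply(members, function(m) m[[col]], numeric(nrow(ref)))
    vals <- matrix(vals, nrow = nrow(ref))
    vals[!validm] <- NA_real_
    ifelse(out_valid & n_valid > 0, rowMeans(vals, na.rm = TRUE), NA_real_)
  }
  shift <- mean_over_valid("shift")
  trend <- mean_over_valid("trend")
  gradient <- mean_over_valid("gradient")

  reasonm <- vapply(members, function(m) m$exclusion_reason,
                    character(nrow(ref)))
  reasonm <- matrix(reasonm, nrow = nrow(ref))
  reason <- rep("none", nrow(ref))
  for (i in which(!out_valid)) {
    reason[i] <- reasonm[i, which(!validm[i, ])[1L]]
  }
  new_shift_map(ref$lat, ref$lon, ref$id, trend, gradient, shift,
                out_valid, reason, season = attr(ref, "season"),
                member = member, years = attr(ref, "years"))
}

#' Regional summary of a shift map
#'
#' Median and interquartile range (25th and 75th percentiles, linear
#' interpolation between order statistics) of the shift over the valid
#' locations in a region, with the valid count. Medians and IQRs are used
#' instead of means and standard deviations because shift distributions
#' are skewed by lakes with particularly dramatic seasonal shifts.
#' Summaries are unweighted location counts (no area weighting).
#'
#' @param map A `shift_map`.
#' @param region Region selector: `NULL` or `"global"` for all locations,
#'   `"north"` / `"south"` for a hemisphere, a logical vector over
#'   locations, or a predicate `function(lat, lon)` returning one.
#' @return Data frame with one row: `median`, `q25`, `q75` (days per
#'   decade) and `n`. Signals an error of class `lakeshift_empty_region`
#'   when the region contains no valid location.
#' @export
summarize_shifts <- function(map, region = NULL) {
  stopifnot(inherits(map, "shift_map"))
  sel <- region_mask(map, region)
  vals <- map$shift[sel & map$valid]
  if (length(vals) == 0L) {
    stop(structure(class = c("lakeshift_empty_region", "error", "condition"),
                   list(message = "no valid locations in region",
                        call = NULL)))
  }
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(median = q[2L], q25 = q[1L], q75 = q[3L], n = length(vals))
}

region_mask <- function(map, region) {
  n <- nrow(map)
  if (is.null(region)) return(rep(TRUE, n))
  if (is.function(region)) {
    sel <- region(map$lat, map$lon)
    stopifnot(is.logical(sel), length(sel) == n)
    return(!is.na(sel) & sel)
  }
  if (is.logical(region)) {
    stopifnot(length(region) == n)
    return(!is.na(region) & region)
  }
  if (is.character(region) && length(region) == 1L) {
    return(switch(region,
                  global = rep(TRUE, n),
                  north = hemisphere_of(map$lat) == "north",
                  south = hemisphere_of(map$lat) == "south",
                  stop("unknown region: ", region, call. = FALSE)))
  }
  stop("`region` must be NULL, a name, a logical vector or a predicate",
       call. = FALSE)
}

#' Tally exclusion reasons in a shift map
#'
#' @param map A `shift_map`.
#' @param region Optional region selector, as in [summarize_shifts()].
#' @return Named integer vector over the four reason categories.
#' @export
exclusion_counts <- function(map, region = NULL) {
  stopifnot(inherits(map, "shift_map"))
  sel <- region_mask(map, region)
  reasons <- factor(map$exclusion_reason[sel], levels = names(EXCLUSION_CODES))
  tab <- table(reasons)
  out <- as.integer(tab)
  names(out) <- names(EXCLUSION_CODES)
  out
}

#' @export
print.shift_map <- function(x, ...) {
  season <- attr(x, "season")
  cat(sprintf("<shift_map> %s [%s], %d locations (%d valid)\n",
              if (is.list(season)) season$name else "?",
              attr(x, "member"), nrow(x), sum(x$valid)))
  NextMethod()
}
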