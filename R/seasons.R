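#' Season definitions
#'
#' A season is a 3-month window identified by its centre month. The fixed
#' limnological seasons follow the usual hemispheric convention: northern
#' spring is March-May (centre April), summer June-August (centre July),
#' autumn September-November (centre October); each southern-hemisphere
#' season is offset by six months. Months are 1-based (January = 1)
#' throughout the package.
#'
#' @param name One of `"spring"`, `"summer"`, `"autumn"`.
#' @param hemisphere `"north"` or `"south"`.
#' @return A `season_def`: list with `name`, `centre_month`, `window`
#'   (ordered triple of month indices, wrapping the year boundary), and
#'   `hemisphere`.
#' @examples
#' season_for("spring", "north")   # centre April, window 3-4-5
#' season_for("summer", "south")   # centre January, window 12-1-2
#' @export
season_for <- function(name = c("spring", "summer", "autumn"),
                       hemisphere = c("north", "south")) {
  name <- match.arg(name)
  hemisphere <- match.arg(hemisphere)
  centre <- switch(name, spring = 4L, summer = 7L, autumn = 10L)
  if (hemisphere == "south") centre <- wrap_month(centre + 6L)
  new_season(name, centre, hemisphere)
}

#' Moving 3-month season windows
#'
#' The moving-window variant of the seasonal-shift analysis: one 3-month
#' window centred on each calendar month, spanning the entire year. Windows
#' at the year boundary wrap (the December-centred window is Nov-Dec-Jan).
#'
#' @param hemisphere `"north"` or `"south"`; recorded on each definition,
#'   the windows themselves are hemisphere-independent.
#' @return A list of 12 `season_def` objects, centres January..December.
#' @examples
#' length(moving_windows())          # 12
#' moving_windows()[[12]]$window     # 11 12 1
#' @export
moving_windows <- function(hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  lapply(1:12, function(m) new_season("custom", m, hemisphere))
}

#' A custom 3-month season centred on an arbitrary month
#'
#' @param centre_month Month index 1-12 for the window centre.
#' @param hemisphere `"north"` or `"south"`.
#' @return A `season_def`.
#' @export
season_custom <- function(centre_month, hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  new_season("custom", centre_month, hemisphere)
}

new_season <- function(name, centre_month, hemisphere) {
  centre_month <- as.integer(centre_month)
  if (length(centre_month) != 1L || is.na(centre_month) ||
      centre_month < 1L || centre_month > 12L) {
    stop("`centre_month` must be a single month index in 1..12",
         call. = FALSE)
  }
  window <- wrap_month(centre_month + c(-1L, 0L, 1L))
  structure(list(name = name, centre_month = centre_month,
                 window = window, hemisphere = hemisphere),
            class = "season_def")
}

wrap_month <- function(m) ((as.integer(m) - 1L) %% 12L) + 1L

#' @export
print.season_def <- function(x, ...) {
  cat(sprintf("<season> %s (%s): window %s, centre %s\n",
              x$name, x$hemisphere,
              paste(month.abb[x$window], collapse = "-"),
              month.abb[x$centre_month]))
  invisible(x)
}

#' Hemisphere of a latitude
#'
#' Single deterministic rule used everywhere in the package: latitudes at or
#' north of the equator are `"north"`, strictly negative latitudes `"south"`.
#'
#' @param lat Numeric latitude(s) in degrees.
#' @return Character vector of `"north"` / `"south"`.
#' @export
hemisphere_of <- function(lat) ifelse(lat >= 0, "north", "south")
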