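# Daily sea-ice concentration around recording stations, 15%-edge crossing
# events, and song/ice timing lags.
#
# The sea-ice edge is defined as the 15% concentration contour: a retreat
# event is the first day the station-mean concentration drops below the
# threshold, an advance event the first day it exceeds it.

#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees; the second pair may be
#'   vectors.
#' @param radius Earth radius in km (default 6371).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius = 6371) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Read a long-format sea-ice grid CSV
#'
#' Columns: `date`, `lat`, `lon`, `sic_percent` (0-100). One record per
#' grid-cell day; cells are treated as points at their centres.
#'
#' @param path CSV path.
#' @return `data.frame` with parsed `date`.
#' @export
read_ice_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "lat", "lon", "sic_percent")
  if (!all(need %in% names(df)))
    stop("ice grid '", path, "' is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$sic_percent < 0 | df$sic_percent > 100, na.rm = TRUE))
    stop("sea-ice concentrations must be within [0, 100]")
  df$date <- as.Date(df$date)
  df
}

#' Daily station-level sea-ice series
#'
#' Per day, the unweighted mean concentration over grid cells within
#' `radius_km` great-circle distance of the station. Missing days inside
#' the covered range are linearly interpolated when the gap is at most
#' `max_gap` days, otherwise left `NA`.
#'
#' @param grid `data.frame` from [read_ice_csv()] (or equivalent).
#' @param station A [station()] or list with `id`, `latitude`, `longitude`.
#' @param radius_km Averaging radius in km (default 50).
#' @param max_gap Longest gap (days) to interpolate across (default 5).
#' @return `data.frame` of class `ice_series` with consecutive `date` and
#'   `sic` columns; station id kept as attribute `station`.
#' @export
station_series <- function(grid, station, radius_km = 50, max_gap = 5) {
  stopifnot(is.data.frame(grid),
            all(c("date", "lat", "lon", "sic_percent") %in% names(grid)))
  cells <- unique(grid[, c("lat", "lon")])
  d <- haversine_km(station$latitude, station$longitude, cells$lat, cells$lon)
  keep <- cells[d <= radius_km, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no sea-ice grid cell within ", radius_km, " km of station ",
         station$id)
  sel <- grid[paste(grid$lat, grid$lon) %in% paste(keep$lat, keep$lon), ]
  daily <- tapply(sel$sic_percent, sel$date, mean, na.rm = TRUE)
  obs_dates <- as.Date(names(daily))
  dates <- seq(min(obs_dates), max(obs_dates), by = "day")
  sic <- rep(NA_real_, length(dates))
  sic[match(obs_dates, dates)] <- as.numeric(daily)
  sic <- fill_gaps(sic, max_gap)
  structure(data.frame(date = dates, sic = sic),
            station = station$id, class = c("ice_series", "data.frame"))
}

# linear interpolation of interior NA runs of length <= max_gap
fill_gaps <- function(x, max_gap) {
  if (!anyNA(x) || all(is.na(x))) return(x)
  r <- rle(is.na(x))
  pos <- cumsum(c(1L, r$lengths))
  for (k in which(r$values)) {
    i0 <- pos[k]; i1 <- pos[k + 1L] - 1L
    if (i0 == 1L || i1 == length(x) || r$lengths[k] > max_gap) next
    x[i0:i1] <- stats::approx(c(i0 - 1L, i1 + 1L), c(x[i0 - 1L], x[i1 + 1L]),
                              xout = i0:i1)$y
  }
  x
}

#' Monthly mean sea-ice concentration
#'
#' @param series An `ice_series` (or data.frame with `date`, `sic`).
#' @return `data.frame` with `month` (`"YYYY-MM"`), `mean_sic`, `n_days`;
#'   months with no non-missing day are omitted (no-data, not zero).
#' @export
monthly_mean <- function(series) {
  stopifnot(all(c("date", "sic") %in% names(series)))
  ok <- is.finite(series$sic)
  if (!any(ok)) return(data.frame(month = character(0), mean_sic = numeric(0),
                                  n_days = integer(0)))
  m <- format(series$date[ok], "%Y-%m")
  agg <- tapply(series$sic[ok], m, mean)
  data.frame(month = names(agg), mean_sic = as.numeric(agg),
             n_days = as.integer(table(m)[names(agg)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sea-ice edge crossing events
#'
#' A retreat event is the first day with concentration strictly below the
#' threshold following a day at or above it ("dropped below"); an advance
#' event the first day strictly above following a day at or below
#' ("exceeded"). Missing spans are skipped: comparisons use the last
#' observed value.
#'
#' @param series An `ice_series`.
#' @param threshold Edge definition in % (default 15).
#' @return Object of class `crossing_events`: `data.frame` with `date` and
#'   `type` (`"retreat"`/`"advance"`), alternating in time; empty when the
#'   series never crosses.
#' @export
crossings <- function(series, threshold = 15) {
  stopifnot(all(c("date", "sic") %in% names(series)))
  ok <- is.finite(series$sic)
  x <- series$sic[ok]; dt <- series$date[ok]
  ev_date <- as.Date(character(0)); ev_type <- character(0)
  if (length(x) >= 2L) {
    for (i in seq(2L, length(x))) {
      if (x[i] < threshold && x[i - 1L] >= threshold) {
        ev_date <- c(ev_date, dt[i]); ev_type <- c(ev_type, "retreat")
      } else if (x[i] > threshold && x[i - 1L] <= threshold) {
        ev_date <- c(ev_date, dt[i]); ev_type <- c(ev_type, "advance")
      }
    }
  }
  structure(data.frame(date = ev_date, type = ev_type,
                       stringsAsFactors = FALSE),
            threshold = threshold,
            class = c("crossing_events", "data.frame"))
}

#' Lags between song timing and sea-ice edge crossings
#'
#' The retreat lag is the number of days from the most recent retreat event
#' at or before the first song of the season to that first song; the
#' advance lag likewise from the most recent prior advance event to the
#' last song. If no prior event exists but a later one does, the lag to the
#' next event is returned (negative) with flag `"song_before_event"`; with
#' no event at all the lag is `NA`, flagged `"undefined"`.
#'
#' @param first_song,last_song `Date`s of the season's first and last song.
#' @param events A [crossings()] result.
#' @return List with `retreat_lag`, `advance_lag` (days), `retreat_flag`,
#'   `advance_flag`.
#' @export
song_ice_lags <- function(first_song, last_song, events) {
  lag_to <- function(song, type) {
    song <- as.Date(song)
    ev <- events$date[events$type == type]
    if (!length(ev)) return(list(lag = NA_real_, flag = "undefined"))
    prior <- ev[ev <= song]
    if (length(prior))
      return(list(lag = as.numeric(song - max(prior)), flag = "ok"))
    list(lag = as.numeric(song - min(ev)), flag = "song_before_event")
  }
  r <- lag_to(first_song, "retreat")
  a <- lag_to(last_song, "advance")
  list(retreat_lag = r$lag, retreat_flag = r$flag,
       advance_lag = a$lag, advance_flag = a$flag)
}
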