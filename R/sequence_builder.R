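# Singer attribution, quality filtering and segmentation of song recordings
# into sessions and songs.
#
# Single-sensor autonomous recordings cannot identify individuals; singers
# are therefore delimited operationally: distinct stations (> 200 km apart,
# beyond plausible 24 h travel at 4 km/h) host distinct singers, and within
# a station a gap of more than 24 h between song recordings starts a new
# presumed singer (feeding-ground travel rates of 17-75 km/day).

#' Singer-attribution configuration
#'
#' @param singer_gap Hours of silence after which a new singer is assumed at
#'   the same station (default 24).
#' @param min_station_distance Minimum distance between stations in km
#'   (default 200), documented rationale for the station rule.
#' @param swim_speed Average swim speed in km/h (default 4).
#' @param travel_rate_range Plausible travel rates in km/day (default 17-75).
#' @return An object of class `attribution_config`.
#' @export
attribution_config <- function(singer_gap = 24, min_station_distance = 200,
                               swim_speed = 4, travel_rate_range = c(17, 75)) {
  vals <- c(singer_gap, min_station_distance, swim_speed, travel_rate_range)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all attribution parameters must be positive")
  structure(list(singer_gap = singer_gap,
                 min_station_distance = min_station_distance,
                 swim_speed = swim_speed,
                 travel_rate_range = travel_rate_range),
            class = "attribution_config")
}

#' Attribute song hours to presumed individual singers
#'
#' @param hours `data.frame` with columns `station` and `time` (`POSIXct` or
#'   ISO strings). Input is sorted internally; duplicate station-times
#'   collapse to one hour.
#' @param config An [attribution_config()].
#' @return The deduplicated, sorted table with an added `singer_id` column
#'   (`station` + date of the singer's first hour, spaced dd/MM/YY form).
#' @export
assign_singers <- function(hours, config = attribution_config()) {
  stopifnot(is.data.frame(hours), all(c("station", "time") %in% names(hours)))
  tm <- as.POSIXct(hours$time, tz = "UTC")
  df <- data.frame(station = as.character(hours$station), time = tm,
                   stringsAsFactors = FALSE)
  df <- unique(df[order(df$station, df$time), , drop = FALSE])
  gap_s <- config$singer_gap * 3600
  ids <- character(nrow(df))
  for (stn in unique(df$station)) {
    i <- which(df$station == stn)
    t <- as.numeric(df$time[i])
    new_singer <- c(TRUE, diff(t) > gap_s)
    first_time <- df$time[i][cummax(ifelse(new_singer, seq_along(i), 0L))]
    ids[i] <- format_singer_id(stn, as.Date(first_time, tz = "UTC"))
  }
  df$singer_id <- ids
  rownames(df) <- NULL
  df
}

#' Quality filter for analysed song sequences
#'
#' Keeps high-quality sequences of complex song: signal-to-noise ratio
#' >= 10 dB and at least two distinct themes discernible. Sequences with a
#' missing SNR are excluded with a warning.
#'
#' @param sequences List of [song_sequence()] objects.
#' @param min_snr SNR threshold in dB (default 10).
#' @param min_themes Minimum number of distinct theme types (default 2).
#' @return The filtered list.
#' @export
quality_filter <- function(sequences, min_snr = 10, min_themes = 2L) {
  stopifnot(is.list(sequences))
  keep <- vapply(sequences, function(s) {
    stopifnot(inherits(s, "song_sequence"))
    if (!is.finite(s$snr)) {
      warning("sequence for singer ", s$singer,
              " excluded: missing SNR", call. = FALSE)
      return(FALSE)
    }
    s$snr >= min_snr && length(unique(s$themes)) >= min_themes
  }, logical(1))
  sequences[keep]
}

#' Extend an analysed even hour to its odd neighbours
#'
#' The preceding and succeeding odd hours are included in the analysis
#' window when they also contain high-quality song.
#'
#' @param even_hour `POSIXct` start of the analysed even hour.
#' @param quality_hours `POSIXct` vector of hour starts known to contain
#'   high-quality song sequences.
#' @return Sorted `POSIXct` vector of 1-3 contiguous hour starts.
#' @export
extend_to_neighbours <- function(even_hour, quality_hours) {
  even_hour <- as.POSIXct(even_hour, tz = "UTC")
  if (as.integer(format(even_hour, "%H")) %% 2L != 0L)
    stop("analysed hour must be an even hour of day")
  quality_hours <- as.POSIXct(quality_hours, tz = "UTC")
  window <- even_hour
  for (off in c(-3600, 3600)) {
    nb <- even_hour + off
    if (any(abs(as.numeric(quality_hours) - as.numeric(nb)) < 1))
      window <- c(window, nb)
  }
  sort(window)
}

#' Split a singer's units into song sessions
#'
#' A song session comprises all song elements sung until a gap of silence of
#' more than one minute occurs. The gap is measured end-to-start and the
#' comparison is strict: a gap of exactly 60 s does not split.
#'
#' @param units Time-ordered [units_table()] for one singer.
#' @param max_gap Silence threshold in seconds (default 60).
#' @return The table with an added integer `session_id` column.
#' @export
split_sessions <- function(units, max_gap = 60) {
  stopifnot(is.data.frame(units), all(c("start", "duration") %in% names(units)))
  units <- units[order(units$start), , drop = FALSE]
  n <- nrow(units)
  if (n == 0L) {
    units$session_id <- integer(0)
    return(units)
  }
  ends <- units$start + units$duration
  if (n > 1L && any(units$start[-1] < ends[-n] - 1e-9))
    stop("overlapping units at row(s) ",
         paste(which(units$start[-1] < ends[-n] - 1e-9) + 1L, collapse = ", "))
  gaps <- c(0, units$start[-1] - ends[-n])
  units$session_id <- cumsum(gaps > max_gap) + 1L
  units
}

#' Delineate songs within a session
#'
#' A song is the complete rendition of all unique theme types of the
#' session: scanning the session's theme tokens left to right, a boundary is
#' emitted each time the set of theme types seen since the last boundary
#' equals the session's full unique theme-type set. A trailing incomplete
#' segment is kept and flagged partial. The reference set is the session's
#' own, not a global catalogue.
#'
#' @param themes Character vector of theme tokens for the session, in order.
#' @return List of segments, each a list with `themes` (tokens) and
#'   `partial` (logical). An empty input gives an empty list with a message.
#' @examples
#' delineate_songs(c("Aa", "Ba", "Aa", "Ba"))
#' @export
delineate_songs <- function(themes) {
  themes <- as.character(themes)
  if (!length(themes)) {
    message("session contains no themes; no songs delineated")
    return(list())
  }
  full <- unique(themes)
  segs <- list()
  seen <- character(0)
  seg_start <- 1L
  for (i in seq_along(themes)) {
    seen <- union(seen, themes[i])
    if (setequal(seen, full)) {
      segs[[length(segs) + 1L]] <- list(themes = themes[seg_start:i],
                                        partial = FALSE)
      seg_start <- i + 1L
      seen <- character(0)
    }
  }
  if (seg_start <= length(themes))
    segs[[length(segs) + 1L]] <- list(themes = themes[seg_start:length(themes)],
                                      partial = TRUE)
  segs
}

#' Split a structured session into song_sequence objects
#'
#' Applies [delineate_songs()] at the theme level and carries the underlying
#' phrases and units into each song, so that unit counts are conserved:
#' the concatenation of the returned songs reproduces the session.
#'
#' @param units [units_table()] of the session with `phrase_id` and
#'   `phrase_code` filled.
#' @param phrases `data.frame` with `phrase_id`, `code` (and optionally
#'   `reps`), in order of occurrence.
#' @param singer Singer id attached to each song.
#' @return List of [song_sequence()] objects (trailing one may be partial).
#' @export
build_songs <- function(units, phrases, singer = NA_character_) {
  stopifnot(is.data.frame(units), is.data.frame(phrases))
  runs <- rle(phrases$code)
  # theme index of each phrase row
  theme_of_phrase <- rep(seq_along(runs$values), runs$lengths)
  segs <- delineate_songs(runs$values)
  out <- list()
  next_theme <- 1L
  for (seg in segs) {
    idx_themes <- seq(next_theme, length.out = length(seg$themes))
    next_theme <- next_theme + length(seg$themes)
    ph <- phrases[theme_of_phrase %in% idx_themes, , drop = FALSE]
    un <- units[units$phrase_id %in% ph$phrase_id, , drop = FALSE]
    out[[length(out) + 1L]] <- song_sequence(un, ph, singer = singer,
                                             partial = seg$partial)
  }
  out
}
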