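# ---- domain constructors -----------------------------------------------
#
# Humpback whale song is hierarchical: units (single sounds) combine into
# stereotyped phrases; consecutive repetitions of one phrase type form a
# theme; songs are built from themes. Phrase types are coded by an uppercase
# letter (the first unit type) plus a lowercase letter (the combination of
# following unit types). These constructors validate that hierarchy; most of
# the package operates on the plain data structures they return.

PHRASE_CODE_RE <- "^[A-Z][a-z]$"

#' Recording station
#'
#' @param id Short station label, e.g. `"G1"` or `"W13"`.
#' @param latitude,longitude Position in decimal degrees.
#' @return An object of class `station`.
#' @export
station <- function(id, latitude, longitude) {
  stopifnot(is.character(id), nzchar(id))
  if (!is.finite(latitude) || latitude < -90 || latitude > 90)
    stop("station '", id, "': latitude must be in [-90, 90]")
  if (!is.finite(longitude) || longitude < -180 || longitude > 180)
    stop("station '", id, "': longitude must be in [-180, 180]")
  structure(list(id = id, latitude = latitude, longitude = longitude),
            class = "station")
}

#' Vocalization unit type
#'
#' Unit types ("call types", `CT` + number) are delimited by tonal versus
#' broadband character, duration, frequency range and time-frequency slope.
#'
#' @param id Label of the form `"CT"` followed by an integer.
#' @param tonal Logical; tonal (`TRUE`) or broadband (`FALSE`).
#' @param nominal_duration Typical duration in seconds, > 0.
#' @param freq_low,freq_high Frequency bounds in Hz, `freq_low < freq_high`.
#' @param slope_sign -1, 0 or +1 time-frequency slope direction.
#' @return An object of class `unit_type`.
#' @export
unit_type <- function(id, tonal = TRUE, nominal_duration = 1,
                      freq_low = 100, freq_high = 1000, slope_sign = 0L) {
  stopifnot(grepl("^CT[0-9]+$", id))
  if (!(nominal_duration > 0)) stop("unit type '", id, "': duration must be > 0")
  if (!(freq_low < freq_high)) stop("unit type '", id, "': freq_low must be < freq_high")
  stopifnot(slope_sign %in% c(-1L, 0L, 1L))
  structure(list(id = id, tonal = isTRUE(tonal),
                 nominal_duration = nominal_duration,
                 freq_low = freq_low, freq_high = freq_high,
                 slope_sign = as.integer(slope_sign)),
            class = "unit_type")
}

#' Phrase type
#'
#' @param code Two-letter code matching `[A-Z][a-z]`.
#' @param unit_template Ordered character vector of unit-type ids; the first
#'   element is the unit type denoted by the uppercase letter.
#' @return An object of class `phrase_type`.
#' @export
phrase_type <- function(code, unit_template) {
  if (!grepl(PHRASE_CODE_RE, code))
    stop("phrase code '", code, "' does not match [A-Z][a-z]")
  if (length(unit_template) < 1L) stop("phrase type '", code, "': empty unit template")
  structure(list(code = code, unit_template = as.character(unit_template)),
            class = "phrase_type")
}

#' Units table constructor/validator
#'
#' A units table is the package's basic annotation container: one row per
#' vocalization unit, time-ordered, with half-open extents
#' `[start, start + duration)` in seconds from recording start.
#'
#' @param start Numeric start times (s).
#' @param duration Numeric durations (s), all > 0.
#' @param unit_type Character unit-type ids.
#' @param snr Signal-to-noise ratio per unit (dB); may be `NA`.
#' @param phrase_code Phrase-type code of the phrase each unit belongs to
#'   (optional, `NA` for free social calls).
#' @param phrase_id Integer phrase index within the table (optional).
#' @return A `data.frame` with the validated columns, ordered by `start`.
#' @export
units_table <- function(start, duration, unit_type, snr = NA_real_,
                        phrase_code = NA_character_, phrase_id = NA_integer_) {
  df <- data.frame(start = as.numeric(start), duration = as.numeric(duration),
                   unit_type = as.character(unit_type), snr = as.numeric(snr),
                   phrase_code = as.character(phrase_code),
                   phrase_id = as.integer(phrase_id),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$start))) stop("unit start times must be finite")
  if (any(!(df$duration > 0))) stop("unit durations must be > 0")
  df[order(df$start), , drop = FALSE]
}

#' Collapse a phrase-code sequence to a theme sequence
#'
#' Transcribes a sequence of phrases to a sequence of themes by collapsing
#' adjacent repeats of the same phrase type (repetition of phrases is
#' ignored when comparing song structure).
#'
#' @param codes Character vector of phrase-type codes, in order.
#' @param validate Check codes against `[A-Z][a-z]`?
#' @return Character vector of theme tokens with no two consecutive equal.
#' @examples
#' theme_sequence(c("Aa", "Aa", "Ba", "Ba", "Aa"))  # "Aa" "Ba" "Aa"
#' @export
theme_sequence <- function(codes, validate = TRUE) {
  codes <- as.character(codes)
  if (length(codes) == 0L) return(character(0))
  if (validate && any(bad <- !grepl(PHRASE_CODE_RE, codes)))
    stop("invalid phrase code(s): ", paste(unique(codes[bad]), collapse = ", "))
  rle(codes)$values
}

#' Song sequence
#'
#' One singer's ordered rendition: units partitioned into phrases, with the
#' derived theme sequence and the minimum unit SNR.
#'
#' @param units A [units_table()] whose `phrase_id`/`phrase_code` columns are
#'   filled for every unit.
#' @param phrases `data.frame` with columns `phrase_id`, `code`, `reps`
#'   (comma-separated per-unit repetition counts, may be `NA`).
#' @param singer Singer id (optional).
#' @param partial Logical flag for trailing incomplete songs.
#' @return An object of class `song_sequence` with elements `units`,
#'   `phrases`, `themes`, `snr`, `singer`, `partial`.
#' @export
song_sequence <- function(units, phrases, singer = NA_character_, partial = FALSE) {
  stopifnot(is.data.frame(units), is.data.frame(phrases))
  if (!all(c("phrase_id", "code") %in% names(phrases)))
    stop("phrases needs columns phrase_id, code")
  if (anyNA(units$phrase_id)) stop("song units must all belong to a phrase")
  if (!setequal(unique(units$phrase_id), phrases$phrase_id))
    stop("phrases must partition the song's units")
  structure(list(units = units, phrases = phrases,
                 themes = theme_sequence(phrases$code),
                 snr = suppressWarnings(min(units$snr, na.rm = TRUE)),
                 singer = singer, partial = isTRUE(partial)),
            class = "song_sequence")
}

#' @export
print.song_sequence <- function(x, ...) {
  cat(sprintf("<song_sequence> singer=%s units=%d phrases=%d themes=%s%s\n",
              x$singer, nrow(x$units), nrow(x$phrases),
              paste(x$themes, collapse = " "),
              if (x$partial) " [partial]" else ""))
  invisible(x)
}

# ---- singer ids ---------------------------------------------------------

#' Parse a singer id into station and date
#'
#' Singer ids encode the recording position (first 2-3 symbols) followed by
#' the recording date as `dd/MM/YY` (last 8 symbols), with or without a
#' separating space: both `"G3 13/04/11"` and `"W1305/06/13"` are valid.
#'
#' @param id Singer id string.
#' @return List with elements `station` (character) and `date` (`Date`).
#' @examples
#' parse_singer_id("G3 13/04/11")
#' parse_singer_id("W1305/06/13")
#' @export
parse_singer_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  id <- trimws(id)
  if (nchar(id) < 10L)
    stop("malformed singer id '", id, "': too short for station + dd/MM/YY")
  date_part <- substr(id, nchar(id) - 7L, nchar(id))
  stn <- trimws(substr(id, 1L, nchar(id) - 8L))
  if (!grepl("^\\d{2}/\\d{2}/\\d{2}$", date_part))
    stop("malformed singer id '", id, "': trailing token '", date_part,
         "' is not a dd/MM/YY date")
  if (!grepl("^[A-Z][A-Z0-9]{1,2}$", stn))
    stop("malformed singer id '", id, "': station prefix '", stn,
         "' is not 2-3 characters")
  d <- as.Date(date_part, format = "%d/%m/%y")
  if (is.na(d))
    stop("malformed singer id '", id, "': '", date_part,
         "' is not a valid calendar date")
  # round-trip guard: formats like 09/13/11 silently wrap in some locales
  if (format(d, "%d/%m/%y") != date_part)
    stop("malformed singer id '", id, "': date '", date_part,
         "' does not round-trip")
  list(station = stn, date = d)
}

#' Format (station, date) as a canonical singer id
#'
#' Emits the spaced dialect, e.g. `"G3 13/04/11"`.
#'
#' @param station Station id.
#' @param date A `Date` (or string coercible to one).
#' @return Singer id string.
#' @export
format_singer_id <- function(station, date) {
  paste(station, format(as.Date(date), "%d/%m/%y"))
}

#' Parse a printed theme sequence
#'
#' Accepts whitespace-separated two-letter phrase-type codes, optionally
#' followed by a parenthesized count of analysed sequences, e.g.
#' `"Cb Cc (17)"`.
#'
#' @param text The printed sequence.
#' @return List with `tokens` (character vector) and `n` (integer count, `NA`
#'   if absent).
#' @export
parse_theme_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  n <- NA_integer_
  if (length(toks) && grepl("^\\(\\d+\\)$", toks[length(toks)])) {
    n <- as.integer(gsub("[()]", "", toks[length(toks)]))
    toks <- toks[-length(toks)]
  }
  if (!length(toks)) stop("empty theme sequence")
  bad <- !grepl(PHRASE_CODE_RE, toks)
  if (any(bad))
    stop("invalid theme token(s): ", paste(toks[bad], collapse = ", "))
  list(tokens = toks, n = n)
}

# ---- phrase expansion ---------------------------------------------------

#' Expand a phrase type template by repetition counts
#'
#' @param ptype A [phrase_type()].
#' @param repetitions Integer vector, one count >= 1 per template element.
#' @return Character vector of unit-type ids for the realized phrase.
#' @export
expand_phrase <- function(ptype, repetitions) {
  stopifnot(inherits(ptype, "phrase_type"))
  reps <- as.integer(repetitions)
  if (length(reps) != length(ptype$unit_template))
    stop("phrase '", ptype$code, "': need one repetition count per template unit")
  if (any(reps < 1L)) stop("phrase '", ptype$code, "': repetitions must be >= 1")
  rep(ptype$unit_template, times = reps)
}
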