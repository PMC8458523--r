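# Hour-level categorization of annotated passive acoustic data.
#
# Hours with confirmed humpback whale acoustic presence are separated into
# hours with social calls and hours with song; song hours split further into
# the preliminary category HWS2 (at least three repeated, similar phrases)
# and the complex category HWS1 (at least two different themes).

HOUR_CATEGORIES <- c("ABSENT", "SOCIAL", "HWS2", "HWS1")

#' Classify one annotated hour
#'
#' Precedence is fixed: HWS1 if at least two distinct themes occur; else HWS2
#' if at least three consecutive phrases of one phrase type occur; else
#' SOCIAL if any vocalization is present; else ABSENT. "Repeated phrases"
#' are read as contiguous repetition (a theme); non-adjacent repeats of a
#' phrase type do not qualify for HWS2.
#'
#' @param phrases Ordered character vector of phrase-type codes, one entry
#'   per phrase in the bout (may be empty).
#' @param n_calls Total number of vocalizations in the hour, including
#'   unstructured social calls. Defaults to `length(phrases)`.
#' @param catalogue Optional character vector of known phrase-type codes;
#'   unknown codes raise an error.
#' @return One of `"ABSENT"`, `"SOCIAL"`, `"HWS2"`, `"HWS1"`.
#' @examples
#' classify_hour(c("Aa", "Aa", "Ac"))          # two themes -> "HWS1"
#' classify_hour(c("Ba", "Ba", "Ba"))          # one repeated phrase -> "HWS2"
#' classify_hour(character(0), n_calls = 2)    # "SOCIAL"
#' @export
classify_hour <- function(phrases = character(0), n_calls = length(phrases),
                          catalogue = NULL) {
  phrases <- as.character(phrases)
  if (length(phrases)) {
    bad <- !grepl(PHRASE_CODE_RE, phrases)
    if (any(bad))
      stop("invalid phrase code(s): ", paste(unique(phrases[bad]), collapse = ", "))
    if (!is.null(catalogue) && any(unk <- !(phrases %in% catalogue)))
      stop("unknown phrase type(s): ", paste(unique(phrases[unk]), collapse = ", "))
  }
  runs <- rle(phrases)
  if (length(unique(runs$values)) >= 2L) return("HWS1")
  if (length(runs$lengths) && max(runs$lengths) >= 3L) return("HWS2")
  if (n_calls > 0L || length(phrases)) return("SOCIAL")
  "ABSENT"
}

#' Keep even hours of the day
#'
#' Emulates the study's subsampling scheme, in which even hours (0, 2, ...,
#' 22) flagged by the automatic detector were revised manually.
#'
#' @param hours `POSIXct` vector, or a `data.frame` with a `hour_start`
#'   (`POSIXct`) or `hour_start_iso` (character) column.
#' @return The even-hour subset, same type as the input.
#' @export
even_hour_schedule <- function(hours) {
  if (is.data.frame(hours)) {
    ts <- hour_starts(hours)
    return(hours[as.integer(format(ts, "%H")) %% 2L == 0L, , drop = FALSE])
  }
  hours[as.integer(format(as.POSIXct(hours, tz = "UTC"), "%H")) %% 2L == 0L]
}

hour_starts <- function(df) {
  if ("hour_start" %in% names(df)) return(as.POSIXct(df$hour_start, tz = "UTC"))
  if ("hour_start_iso" %in% names(df))
    return(as.POSIXct(df$hour_start_iso, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                     "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")))
  stop("hour table needs a 'hour_start' or 'hour_start_iso' column")
}

#' Monthly category proportions per station
#'
#' For each station-month, counts of SOCIAL / HWS2 / HWS1 hours divided by
#' the number of classified hours in that station-month. Hours classified
#' ABSENT contribute to the denominator but to no numerator, so the three
#' proportions sum to at most 1. Station-months with no classified hours do
#' not appear (no-data, not zero).
#'
#' @param hours `data.frame` with columns `station`, `hour_start` (or
#'   `hour_start_iso`) and `category`.
#' @return `data.frame` with columns `station`, `month` (`"YYYY-MM"`),
#'   `n_hours`, `p_social`, `p_hws2`, `p_hws1`.
#' @export
monthly_proportions <- function(hours) {
  stopifnot(is.data.frame(hours), all(c("station", "category") %in% names(hours)))
  if (!all(hours$category %in% HOUR_CATEGORIES))
    stop("unknown hour categories: ",
         paste(setdiff(unique(hours$category), HOUR_CATEGORIES), collapse = ", "))
  month <- format(hour_starts(hours), "%Y-%m")
  key <- interaction(hours$station, month, drop = TRUE, sep = "\r")
  agg <- function(f) as.vector(tapply(hours$category, key, f))
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- data.frame(station = parts[, 1], month = parts[, 2],
                    n_hours = agg(length),
                    p_social = agg(function(x) mean(x == "SOCIAL")),
                    p_hws2 = agg(function(x) mean(x == "HWS2")),
                    p_hws1 = agg(function(x) mean(x == "HWS1")),
                    stringsAsFactors = FALSE)
  out[order(out$station, out$month), , drop = FALSE]
}
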