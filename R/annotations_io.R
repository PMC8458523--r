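# Readers/writers for Raven-style selection tables and the packaged
# set-median theme-sequence fixture.

SELECTION_COLUMNS <- c("Selection", "Begin Time (s)", "End Time (s)",
                       "Low Freq (Hz)", "High Freq (Hz)",
                       "unit_type", "phrase_code", "phrase_reps", "snr_db")

#' Read a Raven-style selection table
#'
#' UTF-8, tab-separated, one header row. Required columns:
#' `Selection`, `Begin Time (s)`, `End Time (s)`, `Low Freq (Hz)`,
#' `High Freq (Hz)`, `unit_type`, `phrase_code`, `phrase_reps`, `snr_db`.
#'
#' @param path File path.
#' @return A `data.frame` of annotated units ordered by start time, with
#'   columns `selection`, `start`, `duration`, `freq_low`, `freq_high`,
#'   `unit_type`, `phrase_code`, `phrase_reps`, `snr`.
#' @export
read_selection_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(SELECTION_COLUMNS, names(raw))
  if (length(missing))
    stop("selection table '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  begin <- as.numeric(raw[["Begin Time (s)"]])
  end <- as.numeric(raw[["End Time (s)"]])
  bad <- which(!(end > begin))
  if (length(bad))
    stop("selection table '", path, "': End Time <= Begin Time on row(s) ",
         paste(bad, collapse = ", "))
  out <- data.frame(selection = as.integer(raw[["Selection"]]),
                    start = begin, duration = end - begin,
                    freq_low = as.numeric(raw[["Low Freq (Hz)"]]),
                    freq_high = as.numeric(raw[["High Freq (Hz)"]]),
                    unit_type = as.character(raw[["unit_type"]]),
                    phrase_code = as.character(raw[["phrase_code"]]),
                    phrase_reps = as.character(raw[["phrase_reps"]]),
                    snr = as.numeric(raw[["snr_db"]]),
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Write a Raven-style selection table
#'
#' Inverse of [read_selection_table()]: the reader round-trips the written
#' file bit-identically on the fields it owns.
#'
#' @param units `data.frame` in the layout returned by [read_selection_table()]
#'   (`selection` and `freq_*` optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(units, path) {
  stopifnot(is.data.frame(units), all(c("start", "duration") %in% names(units)))
  n <- nrow(units)
  get <- function(col, default) if (col %in% names(units)) units[[col]] else default
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    "Selection" = get("selection", seq_len(n)),
    "Begin Time (s)" = units$start,
    "End Time (s)" = units$start + units$duration,
    "Low Freq (Hz)" = get("freq_low", rep(NA_real_, n)),
    "High Freq (Hz)" = get("freq_high", rep(NA_real_, n)),
    "unit_type" = get("unit_type", rep(NA_character_, n)),
    "phrase_code" = get("phrase_code", rep(NA_character_, n)),
    "phrase_reps" = get("phrase_reps", rep(NA_character_, n)),
    "snr_db" = get("snr", rep(NA_real_, n)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# md5 of the packaged fixture file; guards against silent corruption.
TABLE1_MD5 <- "7d19194b5ad349b3316a8bb0f0a7210d"

#' Read the packaged set-median theme-sequence table
#'
#' A verbatim transcription of the study's printed table of set-median theme
#' sequences per singer (77 singers, 44 distinct phrase-type tokens,
#' 2011-2018). Columns: `singer_id`, `station`, `date`, `theme_sequence`,
#' `n_sequences`, plus derived `year` and `era` (`"2011-2013"` or
#' `"2017-2018"`).
#'
#' @param path Optional path override (defaults to the packaged file).
#' @param checksum Expected md5 of the file; `NULL` skips the check.
#' @return `data.frame`, one row per singer.
#' @export
read_table1_fixture <- function(path = NULL, checksum = TABLE1_MD5) {
  if (is.null(path))
    path <- system.file("extdata", "table1_set_medians.csv",
                        package = "whalesong", mustWork = TRUE)
  if (!is.null(checksum)) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, checksum))
      stop("set-median table fixture '", path, "' failed its checksum (md5 ",
           got, " != expected ", checksum, "); file corrupted?")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("singer_id", "station", "date", "theme_sequence", "n_sequences")
  if (!all(need %in% names(df)))
    stop("fixture is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$singer_id))
    stop("fixture has duplicated singer ids")
  df$date <- as.Date(df$date)
  df$year <- as.integer(format(df$date, "%Y"))
  df$era <- ifelse(df$year <= 2013, "2011-2013", "2017-2018")
  df
}

#' Phrase-type sets from printed set-median sequences
#'
#' Repertoire proxy used when only the printed table is available: the set of
#' distinct tokens of each singer's set-median theme sequence. The result
#' carries `attr(, "repertoire_source") == "set_median_proxy"` so downstream
#' outputs can flag that the full quality-filtered repertoires were not used.
#'
#' @param fixture `data.frame` from [read_table1_fixture()].
#' @return Named list of character vectors (one phrase-type set per singer).
#' @export
fixture_repertoires <- function(fixture) {
  reps <- lapply(fixture$theme_sequence,
                 function(s) unique(parse_theme_sequence(s)$tokens))
  names(reps) <- fixture$singer_id
  attr(reps, "repertoire_source") <- "set_median_proxy"
  reps
}

#' Read the packaged published hour-count summary
#'
#' The study's printed hour totals: hours with exclusively social calls,
#' complex-song (HWS1) hours, preliminary-song (HWS2) hours, and total
#' verified vocalization hours. Used for the category accounting identity
#' (the three category counts must sum to the total).
#'
#' @return Named numeric vector.
#' @export
read_reported_hour_counts <- function() {
  path <- system.file("extdata", "reported_hour_counts.csv",
                      package = "whalesong", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$hours, df$quantity)
}
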