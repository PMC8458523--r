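# Length and complexity ("elaborateness") measures of song, and their
# correlation with day of year and latitude.
#
# Two measures of length (session and song length in vocalization units) and
# three of complexity: unit complexity = unique unit types / total units per
# song; phrase complexity = unique phrase types / total phrases per song;
# song complexity = unit complexity x phrase complexity. Lengths and
# complexities are computed per song and averaged per individual singer.

#' Sequence length in vocalization units
#'
#' @param x A [song_sequence()], a units table (`data.frame`), or a list of
#'   either (e.g. a session as a list of songs), counted jointly.
#' @return Integer unit count.
#' @export
sequence_length <- function(x) {
  n <- if (inherits(x, "song_sequence")) nrow(x$units)
       else if (is.data.frame(x)) nrow(x)
       else if (is.list(x)) sum(vapply(x, sequence_length, numeric(1)))
       else stop("cannot measure length of a ", class(x)[1])
  if (n < 1L) stop("empty sequence has no length")
  as.integer(n)
}

#' Unit complexity of a song
#'
#' Number of unique unit types divided by the total number of units.
#'
#' @param song A [song_sequence()] or a character vector of unit-type ids.
#' @return Ratio in (0, 1]; 1 iff all units are distinct types.
#' @export
unit_complexity <- function(song) {
  u <- if (inherits(song, "song_sequence")) song$units$unit_type
       else as.character(song)
  if (!length(u)) stop("empty song: unit complexity undefined")
  length(unique(u)) / length(u)
}

#' Phrase complexity of a song
#'
#' Number of unique phrase types divided by the total number of phrases.
#'
#' @param song A [song_sequence()] or a character vector of phrase codes.
#' @return Ratio in (0, 1].
#' @export
phrase_complexity <- function(song) {
  p <- if (inherits(song, "song_sequence")) song$phrases$code
       else as.character(song)
  if (!length(p)) stop("empty song: phrase complexity undefined")
  length(unique(p)) / length(p)
}

#' Song complexity
#'
#' The product of unit and phrase complexity.
#'
#' @param song A [song_sequence()].
#' @return Ratio in (0, 1].
#' @export
song_complexity <- function(song) {
  unit_complexity(song) * phrase_complexity(song)
}

#' Per-singer elaborateness records
#'
#' @param singers List of singer objects as produced by
#'   [generate_song_groups()]: each has `id`, `station`, `date`, `latitude`
#'   and a list `songs` of [song_sequence()]s. Sessions, where present
#'   (`sessions` element as list of unit tables), feed session length;
#'   otherwise each singer's songs are treated as one session each.
#' @return `data.frame`, one row per singer, with day-of-year, latitude,
#'   mean/sd session and song lengths and mean complexities.
#' @export
elaborateness_table <- function(singers) {
  rows <- lapply(singers, function(sg) {
    songs <- sg$songs
    if (!length(songs)) return(NULL)
    song_len <- vapply(songs, sequence_length, numeric(1))
    sess_len <- if (!is.null(sg$sessions))
      vapply(sg$sessions, sequence_length, numeric(1)) else song_len
    data.frame(singer = sg$id,
               day_of_year = as.integer(format(as.Date(sg$date), "%j")),
               latitude = sg$latitude,
               mean_session_length = mean(sess_len),
               sd_session_length = stats::sd(sess_len),
               mean_song_length = mean(song_len),
               sd_song_length = stats::sd(song_len),
               unit_complexity = mean(vapply(songs, unit_complexity, numeric(1))),
               phrase_complexity = mean(vapply(songs, phrase_complexity, numeric(1))),
               song_complexity = mean(vapply(songs, song_complexity, numeric(1))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation of an elaborateness measure with a covariate
#'
#' Standard product-moment correlation; no significance testing.
#'
#' @param values Numeric measure values.
#' @param covariate Numeric covariate (day of year or latitude).
#' @return List with `r` (in `[-1, 1]`, or `NA`), `n`, and `flag`
#'   (`"ok"` or `"undefined"` when the covariate or values are constant).
#' @export
correlate <- function(values, covariate) {
  ok <- is.finite(values) & is.finite(covariate)
  x <- values[ok]; y <- covariate[ok]
  if (length(x) < 3L)
    stop("need at least 3 paired finite values, got ", length(x))
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    return(list(r = NA_real_, n = length(x), flag = "undefined"))
  list(r = stats::cor(x, y), n = length(x), flag = "ok")
}

#' Correlation report over all measures and covariates
#'
#' @param records `data.frame` from [elaborateness_table()].
#' @return `data.frame` with columns `measure`, `covariate`, `r`, `n`,
#'   `flag`.
#' @export
correlation_report <- function(records) {
  measures <- c("mean_session_length", "mean_song_length", "unit_complexity",
                "phrase_complexity", "song_complexity")
  out <- expand.grid(measure = measures,
                     covariate = c("day_of_year", "latitude"),
                     stringsAsFactors = FALSE)
  res <- Map(function(m, cv) correlate(records[[m]], records[[cv]]),
             out$measure, out$covariate)
  out$r <- vapply(res, `[[`, numeric(1), "r")
  out$n <- vapply(res, `[[`, numeric(1), "n")
  out$flag <- vapply(res, `[[`, character(1), "flag")
  out
}
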