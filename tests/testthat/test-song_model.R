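test_that("singer ids parse in both printed dialects and round-trip", {
  cases <- list(
    list(id = "G3 13/04/11", station = "G3", date = as.Date("2011-04-13")),
    list(id = "W1305/06/13", station = "W13", date = as.Date("2013-06-05")),
    list(id = "W1305/10/13", station = "W13", date = as.Date("2013-10-05")))
  for (cs in cases) {
    p <- parse_singer_id(cs$id)
    expect_equal(p$station, cs$station)
    expect_equal(p$date, cs$date)
  }
  # formatter emits the spaced form; parse(format(.)) is the identity
  dates <- as.Date(c("2011-01-01", "2013-06-05", "2018-12-31", "2012-02-29"))
  for (stn in c("G1", "G5", "W13", "W6", "W9"))
    for (k in seq_along(dates)) {
      p <- parse_singer_id(format_singer_id(stn, dates[k]))
      expect_identical(p$station, stn)
      expect_identical(p$date, dates[k])
    }
})

test_that("malformed singer ids fail with the offending token named", {
  expect_error(parse_singer_id("G3 31/02/11"), "31/02/11")
  expect_error(parse_singer_id("G3 13-04-11"), "13-04-11")
  expect_error(parse_singer_id("TOOLONG 13/04/11"), "TOOLONG")
  expect_error(parse_singer_id("G3"), "too short")
})

test_that("printed theme sequences parse with optional trailing count", {
  p <- parse_theme_sequence("Cb Cc (17)")
  expect_identical(p$tokens, c("Cb", "Cc"))
  expect_identical(p$n, 17L)
  p <- parse_theme_sequence("Ga Ha Ec Ed Gb (7)")
  expect_identical(p$tokens, c("Ga", "Ha", "Ec", "Ed", "Gb"))
  expect_identical(p$n, 7L)
  p <- parse_theme_sequence("Aa")
  expect_identical(p$tokens, "Aa")
  expect_true(is.na(p$n))
  expect_error(parse_theme_sequence("Aa xx Ba"), "xx")
  expect_error(parse_theme_sequence("(3)"), "empty")
})

test_that("phrase expansion and theme collapsing are consistent", {
  pt <- phrase_type("Ab", c("CT1", "CT4", "CT4"))
  expect_identical(expand_phrase(pt, c(2, 1, 3)),
                   c("CT1", "CT1", "CT4", "CT4", "CT4", "CT4"))
  expect_error(expand_phrase(pt, c(1, 0, 1)), ">= 1")
  expect_error(phrase_type("ab", "CT1"), "does not match")
  # collapsing is idempotent
  x <- c("Aa", "Aa", "Ba", "Cc", "Cc", "Aa")
  once <- theme_sequence(x)
  expect_identical(theme_sequence(once), once)
  expect_identical(once, c("Aa", "Ba", "Cc", "Aa"))
})

test_that("selection tables round-trip bit-identically on owned fields", {
  s <- make_structured(c("Aa", "Aa", "Ba"))
  s$units$freq_low <- c(100, 120, 90)
  s$units$freq_high <- c(800, 700, 950)
  s$units$phrase_reps <- "1"
  path <- withr::local_tempfile(fileext = ".txt")
  write_selection_table(s$units, path)
  back <- read_selection_table(path)
  expect_equal(nrow(back), 3L)
  for (col in c("start", "duration", "unit_type", "phrase_code", "snr"))
    expect_identical(back[[col]], s$units[[col]])
  # writing the parsed table again reproduces the file exactly
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_selection_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("selection table schema and interval violations are reported", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Selection\tBegin Time (s)\tEnd Time (s)", "1\t0\t1"), path)
  expect_error(read_selection_table(path), "unit_type")
  hdr <- paste(c("Selection", "Begin Time (s)", "End Time (s)",
                 "Low Freq (Hz)", "High Freq (Hz)", "unit_type",
                 "phrase_code", "phrase_reps", "snr_db"), collapse = "\t")
  writeLines(c(hdr,
               "1\t0\t1\t100\t800\tCT1\tAa\t1\t12",
               "2\t5\t4\t100\t800\tCT1\tAa\t1\t12"), path)
  expect_error(read_selection_table(path), "row\\(s\\) 2")
})

test_that("the set-median table fixture matches its printed source", {
  fx <- read_table1_fixture()
  # the printed table has 77 singer rows ("Of 77 individual singers")
  expect_identical(nrow(fx), 77L)
  expect_false(anyDuplicated(fx$singer_id) > 0)
  toks <- unlist(lapply(fx$theme_sequence,
                        function(s) parse_theme_sequence(s)$tokens))
  expect_identical(length(unique(toks)), 44L)
  expect_true(all(grepl("^[A-Z][a-z]$", toks)))
  row <- fx[fx$singer_id == "G1 05/04/13", ]
  expect_identical(row$n_sequences, 24L)
  expect_identical(parse_theme_sequence(row$theme_sequence)$tokens,
                   c("Ac", "Aq", "Aa", "Am", "Ai", "An", "Ak"))
  # singer ids re-parse onto the stored station/date columns
  for (i in seq_len(nrow(fx))) {
    p <- parse_singer_id(fx$singer_id[i])
    expect_identical(p$station, fx$station[i])
    expect_identical(p$date, fx$date[i])
  }
})

test_that("a corrupted fixture copy fails its checksum", {
  orig <- system.file("extdata", "table1_set_medians.csv",
                      package = "whalesong")
  tmp <- withr::local_tempfile(fileext = ".csv")
  lines <- readLines(orig)
  lines[2] <- sub("Cb", "Zz", lines[2])
  writeLines(lines, tmp)
  expect_error(read_table1_fixture(tmp), "checksum")
  # explicit opt-out still parses
  expect_silent(read_table1_fixture(orig, checksum = NULL))
})

test_that("station and unit-type invariants are enforced", {
  expect_error(station("G1", -95, 0), "latitude")
  expect_error(station("G1", -60, 200), "longitude")
  expect_error(unit_type("CT3", freq_low = 500, freq_high = 100), "freq_low")
  expect_error(unit_type("CT3", nominal_duration = 0), "duration")
  expect_error(units_table(0, -1, "CT1"), "> 0")
})
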