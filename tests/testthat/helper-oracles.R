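# Independent oracles and small fixture builders used across the suite.

# top-down recursive edit distance with per-pair memoization; independent of
# the package's bottom-up DP
ed_oracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > length(a)) return(length(b) - j + 1L)
    if (j > length(b)) return(length(a) - i + 1L)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- min(rec(i + 1L, j) + 1L,
               rec(i, j + 1L) + 1L,
               rec(i + 1L, j + 1L) + (a[i] != b[j]))
    memo[[key]] <- val
    val
  }
  rec(1L, 1L)
}

lsi_oracle <- function(a, b) 1 - ed_oracle(a, b) / max(length(a), length(b))

# exhaustive set-median search built on the oracle distance
set_median_oracle <- function(seqs) {
  if (length(seqs) == 1L) return(seqs[[1L]])
  score <- vapply(seq_along(seqs), function(i)
    sum(vapply(seq_along(seqs)[-i], function(j)
      lsi_oracle(seqs[[i]], seqs[[j]]), numeric(1))), numeric(1))
  seqs[[which.max(score)]]
}

# all token sequences of length 0..max_len over an alphabet
all_token_seqs <- function(alphabet, max_len) {
  out <- list(character(0))
  for (len in seq_len(max_len)) {
    grids <- do.call(expand.grid,
                     c(rep(list(alphabet), len),
                       list(stringsAsFactors = FALSE)))
    out <- c(out, lapply(seq_len(nrow(grids)),
                         function(i) as.character(unlist(grids[i, ]))))
  }
  out
}

# minimal structured bout: one phrase per theme repetition, one unit per
# phrase (unit type = phrase code), evenly spaced
make_structured <- function(codes, gap = 1, t0 = 0, snr = 15) {
  n <- length(codes)
  units <- data.frame(start = t0 + (seq_len(n) - 1) * (1 + gap),
                      duration = rep(1, n), unit_type = paste0("CT", codes),
                      snr = rep(snr, n), phrase_code = codes,
                      phrase_id = seq_len(n), stringsAsFactors = FALSE)
  phrases <- data.frame(phrase_id = seq_len(n), code = codes,
                        reps = "1", stringsAsFactors = FALSE)
  list(units = units, phrases = phrases)
}

make_song <- function(codes, singer = "G1 01/05/13", snr = 15) {
  s <- make_structured(codes, snr = snr)
  song_sequence(s$units, s$phrases, singer = singer)
}

# small t4-style synthetic config: two disjoint 8-type catalogues,
# 10 singers per group in one year
t4_config <- function(seed) {
  synth_config(seed = seed, catalog_sizes = c(8, 8), group_overlap = 0,
               years = 2013,
               group_years = list(2013, 2013),
               group_stations = list(c("G1", "G2", "G3", "G4"),
                                     c("W13", "W9", "W6")),
               singers_per_group_year = 10)
}

# do two integer partitions agree exactly (Rand index 1)?
same_partition <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  all(outer(a, a, "==") == outer(b, b, "=="))
}
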