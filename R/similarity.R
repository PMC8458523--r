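# Repertoire and sequence similarity.
#
# Two indices drive all comparisons between singers:
#   DCI(a, b) = 2A / (B + C), with A the number of shared phrase types and
#     B, C the repertoire sizes of the two singers;
#   LSI(a, b) = 1 - min(I + D + S) / max(L(a), L(b)), with the numerator the
#     token-level Levenshtein distance between two theme sequences.
# Both live in [0, 1] and equal 1 on identical inputs. Edit distance
# operates on theme tokens, never characters: "Cb" is one symbol.

#' Dice Coincidence Index between two phrase repertoires
#'
#' @param rep_a,rep_b Character vectors of phrase-type codes (treated as
#'   sets; duplicates are ignored).
#' @param label_a,label_b Optional singer labels used in error messages.
#' @return Similarity in `[0, 1]`: 1 iff the sets are equal, 0 iff disjoint.
#' @examples
#' dci(c("Cb", "Cc"), c("Cb", "Cc"))                   # 1
#' dci(c("Ga", "Ha", "Ec", "Ed", "Gb"), c("Ed", "Gb", "Ga"))  # 0.75
#' @export
dci <- function(rep_a, rep_b, label_a = "a", label_b = "b") {
  a <- unique(as.character(rep_a)); b <- unique(as.character(rep_b))
  if (!length(a)) stop("empty phrase repertoire for singer ", label_a)
  if (!length(b)) stop("empty phrase repertoire for singer ", label_b)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Token-level Levenshtein distance
#'
#' Minimum number of insertions, deletions and substitutions required to
#' change one token sequence into the other, by dynamic programming. Tokens
#' (phrase-type codes) are the atomic symbols.
#'
#' @param a,b Character vectors of tokens.
#' @return Non-negative integer distance.
#' @export
token_edit_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,           # deletion
                         cur[j] + 1L,                 # insertion
                         prev[j] + (a[i] != b[j]))    # substitution
    }
    prev <- cur
  }
  as.integer(prev[m + 1L])
}

#' Levenshtein Distance Similarity Index between two theme sequences
#'
#' `1 - d(a, b) / max(length(a), length(b))` on theme tokens.
#'
#' @param a,b Non-empty character vectors of theme tokens.
#' @return Similarity in `[0, 1]`; 1 iff the sequences are identical.
#' @examples
#' lsi(c("Aa", "Ai", "Ac"), c("Aa", "Ac"))  # 1 - 1/3
#' @export
lsi <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty theme sequence")
  1 - token_edit_distance(a, b) / max(length(a), length(b))
}

#' Set-median theme sequence
#'
#' The member of a set of theme sequences with the highest similarity to all
#' sequences of the set — here the maximal sum of pairwise LSI to the other
#' members (equivalently the maximal mean; self-similarity excluded). Ties
#' break to the earliest sequence in input order, so callers should present
#' songs in a deterministic order (e.g. sorted by start time).
#'
#' @param sequences Non-empty list of token vectors (e.g. all songs recorded
#'   within one 24-h window at one recording position).
#' @return The selected member sequence (always an element of the input).
#' @export
set_median <- function(sequences) {
  stopifnot(is.list(sequences))
  k <- length(sequences)
  if (k == 0L) stop("set_median of an empty set")
  if (k == 1L) return(sequences[[1L]])
  score <- numeric(k)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      s <- lsi(sequences[[i]], sequences[[j]])
      score[i] <- score[i] + s
      score[j] <- score[j] + s
    }
  }
  sequences[[which.max(score)]]  # which.max takes the first maximum
}

#' Pairwise similarity matrix over singers
#'
#' DCI compares phrase repertoires; LSI compares set-median theme sequences.
#'
#' @param x Named list: character sets (repertoires) for `method = "dci"`,
#'   token vectors (set medians) for `method = "lsi"`.
#' @param method `"dci"` or `"lsi"`.
#' @return Object of class `similarity_matrix`: list with `values` (square
#'   symmetric matrix, unit diagonal), `labels`, `method`, and
#'   `repertoire_source` when `x` carries that attribute.
#' @export
similarity_matrix <- function(x, method = c("dci", "lsi")) {
  method <- match.arg(method)
  stopifnot(is.list(x), length(x) >= 2L)
  labels <- names(x)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("similarity_matrix needs named elements (singer ids)")
  n <- length(x)
  v <- diag(1, n)
  fun <- if (method == "dci")
    function(i, j) dci(x[[i]], x[[j]], labels[i], labels[j])
  else
    function(i, j) {
      if (!length(x[[i]])) stop("empty theme sequence for singer ", labels[i])
      if (!length(x[[j]])) stop("empty theme sequence for singer ", labels[j])
      lsi(x[[i]], x[[j]])
    }
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n))
      v[i, j] <- v[j, i] <- fun(i, j)
  dimnames(v) <- list(labels, labels)
  structure(list(values = v, labels = labels, method = toupper(method),
                 repertoire_source = attr(x, "repertoire_source")),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> method=%s n=%d range=[%.3f, %.3f]\n",
              x$method, length(x$labels),
              min(x$values), max(x$values)))
  if (!is.null(x$repertoire_source))
    cat("  repertoire source:", x$repertoire_source, "\n")
  invisible(x)
}

#' Write a similarity matrix as CSV plus a JSON sidecar
#'
#' @param sm A `similarity_matrix`.
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "similarity_matrix"))
  utils::write.csv(data.frame(singer = sm$labels, sm$values,
                              check.names = FALSE), path, row.names = FALSE)
  meta <- list(method = sm$method, n = length(sm$labels))
  if (!is.null(sm$repertoire_source)) meta$repertoire_source <- sm$repertoire_source
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
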