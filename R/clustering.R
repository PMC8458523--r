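# Hierarchical clustering of similarity matrices with multiscale-bootstrap
# approximately-unbiased (AU) support.
#
# Similarities s are converted to distances d = 1 - s and clustered by
# single linkage ("nearest neighbour"). Support for each dendrogram
# division comes from a multiscale bootstrap: the observations beneath the
# similarity matrix are resampled with replacement at several scale factors
# r (resampled size round(r * m)); for each internal division the bootstrap
# proportion BP_r of replicates whose dendrogram contains the division is
# recorded, qnorm(1 - BP_r) is regressed on (sqrt(r), 1/sqrt(r)) to give a
# signed distance v and curvature c, and AU = 1 - pnorm(v - c). AU > 0.95
# flags divisions likely to occur.

#' Single-linkage clustering of a similarity matrix
#'
#' Agglomerative merge tree on d = 1 - s with minimum-distance linkage.
#' Merge ties break deterministically to the pair whose smallest leaf
#' labels sort lexicographically first.
#'
#' @param sm A [similarity_matrix()] or a square symmetric numeric matrix
#'   with unit diagonal and dimnames.
#' @return Object of class `song_dendrogram`: `merge` and `height` in
#'   `stats::hclust` coding, `labels`, `order`, `method`.
#' @export
single_linkage <- function(sm) {
  S <- if (inherits(sm, "similarity_matrix")) sm$values else as.matrix(sm)
  n <- nrow(S)
  if (n < 2L) stop("need at least 2 singers to cluster")
  if (ncol(S) != n || max(abs(S - t(S))) > 1e-8)
    stop("similarity matrix must be square and symmetric")
  labels <- rownames(S)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- 1 - S
  diag(D) <- Inf

  ids <- -seq_len(n)             # hclust coding: negative = leaf
  minlab <- labels               # smallest leaf label per active cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    dmin <- min(D)
    cand <- which(D - dmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lab1 <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
    lab2 <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
    pick <- order(lab1, lab2)[1L]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    # left child = subtree holding the lexicographically smaller leaf
    merge[step, ] <- if (minlab[i] <= minlab[j]) c(ids[i], ids[j])
                     else c(ids[j], ids[i])
    height[step] <- dmin
    # Lance-Williams single-linkage update onto slot i, drop slot j
    newd <- pmin(D[i, ], D[j, ])
    D[i, ] <- D[, i] <- newd
    D[i, i] <- Inf
    D <- D[-j, -j, drop = FALSE]
    ids[i] <- step
    minlab[i] <- min(minlab[i], minlab[j])
    ids <- ids[-j]; minlab <- minlab[-j]
  }
  structure(list(merge = merge, height = height, labels = labels,
                 order = dendrogram_order(merge), method = "single"),
            class = "song_dendrogram")
}

# leaf order for plotting/hclust compatibility
dendrogram_order <- function(merge) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' @export
as.hclust.song_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = "1 - similarity"),
            class = "hclust")
}

#' @export
print.song_dendrogram <- function(x, ...) {
  cat(sprintf("<song_dendrogram> %d leaves, single linkage, heights [%.3f, %.3f]\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Leaf-label sets of all internal dendrogram divisions
#'
#' @param dend A `song_dendrogram`.
#' @return List (one element per merge, root last) of sorted label vectors.
#' @export
cluster_members <- function(dend) {
  n <- length(dend$labels)
  idx <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    get1 <- function(node) if (node < 0L) -node else idx[[node]]
    idx[[k]] <- c(get1(dend$merge[k, 1]), get1(dend$merge[k, 2]))
  }
  lapply(idx, function(i) sort(dend$labels[i]))
}

# ---- internal fast paths used inside bootstrap replicates ----------------

# DCI matrix from a (possibly column-resampled) binary singer x type matrix.
# Duplicated columns count multiply; a singer with no sampled types gets
# similarity 0 to everyone (conservative).
dci_from_binary <- function(X) {
  A <- tcrossprod(X)
  sizes <- rowSums(X)
  S <- 2 * A / outer(sizes, sizes, "+")
  S[!is.finite(S)] <- 0
  S[sizes == 0, ] <- 0
  S[, sizes == 0] <- 0
  diag(S) <- 1
  S
}

#' Binary singer-by-phrase-type repertoire matrix
#'
#' @param repertoires Named list of character phrase-type sets.
#' @return Binary matrix, singers in rows, phrase types in columns.
#' @export
repertoire_matrix <- function(repertoires) {
  stopifnot(is.list(repertoires), !is.null(names(repertoires)))
  types <- sort(unique(unlist(repertoires)))
  X <- matrix(0L, length(repertoires), length(types),
              dimnames = list(names(repertoires), types))
  for (i in seq_along(repertoires))
    X[i, unique(repertoires[[i]])] <- 1L
  X
}

# single-linkage cluster keys (integer member lists, comma-joined); lean
# replicate-side counterpart of single_linkage() using the same
# lexicographic tie-break, so tie-created divisions are counted
# consistently between the observed tree and bootstrap trees
sl_keys <- function(D, labels) {
  n <- nrow(D)
  diag(D) <- Inf
  members <- as.list(seq_len(n))
  minlab <- labels
  keys <- character(n - 1L)
  for (step in seq_len(n - 1L)) {
    dmin <- min(D)
    cand <- which(D - dmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1L) {
      lab1 <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
      lab2 <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
      cand <- cand[order(lab1, lab2)[1L], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    keys[step] <- paste(members[[i]], collapse = ",")
    newd <- pmin(D[i, ], D[j, ])
    D[i, ] <- D[, i] <- newd
    D[i, i] <- Inf
    D <- D[-j, -j, drop = FALSE]
    members <- members[-j]
    minlab[i] <- min(minlab[i], minlab[j])
    minlab <- minlab[-j]
  }
  keys
}

# multiscale-bootstrap fit: AU from per-scale bootstrap proportions
au_from_bp <- function(bp, scales) {
  if (length(scales) < 2L)
    return(list(au = NA_real_, v = NA_real_, c = NA_real_,
                flag = "insufficient_scales"))
  if (all(bp >= 1)) return(list(au = 1, v = NA_real_, c = NA_real_,
                                flag = "degenerate_all_one"))
  if (all(bp <= 0)) return(list(au = 0, v = NA_real_, c = NA_real_,
                                flag = "degenerate_all_zero"))
  use <- bp > 0 & bp < 1
  if (sum(use) < 2L) {
    # only extreme BPs left (mix of 0s and 1s): no quantile scale to fit on
    return(list(au = as.numeric(mean(bp) >= 0.5), v = NA_real_, c = NA_real_,
                flag = "degenerate_extremes"))
  }
  r <- scales[use]
  z <- stats::qnorm(1 - bp[use])
  fit <- stats::lm.fit(cbind(sq = sqrt(r), isq = 1 / sqrt(r)), z)
  v <- unname(fit$coefficients["sq"])
  cc <- unname(fit$coefficients["isq"])
  list(au = 1 - stats::pnorm(v - cc), v = v, c = cc, flag = "ok")
}

#' Multiscale-bootstrap AU support for dendrogram divisions
#'
#' What is resampled depends on the index. For DCI, singers' repertoires
#' form a binary singer-by-phrase-type matrix and phrase-type columns are
#' resampled with replacement (round(r * m) columns at scale r); DCI and the
#' single-linkage tree are recomputed per replicate. For LSI, each singer's
#' set of songs is resampled with replacement (round(r * n_songs), at least
#' one) and the set median recomputed. Both resample the raw observations
#' beneath the similarity, not the matrix.
#'
#' @param x For `method = "dci"`: a named list of repertoires or a binary
#'   repertoire matrix. For `method = "lsi"`: a named list, one element per
#'   singer, each a list of token vectors (the singer's songs).
#' @param method `"dci"` or `"lsi"`.
#' @param n_boot Replicates per scale (default 1000; >= 100 enforced).
#' @param scales Scale factors r (default `seq(0.5, 1.4, by = 0.1)`).
#' @param seed Integer seed; mandatory.
#' @return `data.frame` with one row per internal division: `members`
#'   (semicolon-joined sorted labels), `bp` (proportion at the scale nearest
#'   1), `au`, `v`, `c`, `flag`. The observed dendrogram is attached as
#'   `attr(, "dendrogram")`, the full BP-by-scale matrix as
#'   `attr(, "bp_by_scale")`.
#' @export
au_support <- function(x, method = c("dci", "lsi"), n_boot = 1000,
                       scales = seq(0.5, 1.4, by = 0.1), seed) {
  method <- match.arg(method)
  if (missing(seed) || is.null(seed)) stop("au_support requires a seed")
  if (n_boot < 100) stop("n_boot must be >= 100")
  set.seed(as.integer(seed))

  if (method == "dci") {
    X <- if (is.matrix(x)) x else repertoire_matrix(x)
    labels <- rownames(X)
    S_obs <- dci_from_binary(X)
    dimnames(S_obs) <- list(labels, labels)
  } else {
    stopifnot(is.list(x), !is.null(names(x)))
    labels <- names(x)
    medians <- lapply(x, set_median)
    S_obs <- similarity_matrix(medians, "lsi")$values
  }
  dend <- single_linkage(S_obs)
  obs_idx <- lapply(cluster_members(dend),
                    function(mem) sort(match(mem, labels)))
  obs_keys <- vapply(obs_idx, paste, character(1), collapse = ",")

  counts <- matrix(0L, length(obs_keys), length(scales))
  for (si in seq_along(scales)) {
    r <- scales[si]
    for (b in seq_len(n_boot)) {
      if (method == "dci") {
        m <- ncol(X)
        idx <- sample.int(m, max(1L, round(r * m)), replace = TRUE)
        S <- dci_from_binary(X[, idx, drop = FALSE])
      } else {
        meds <- lapply(x, function(songs) {
          k <- max(1L, round(r * length(songs)))
          set_median(songs[sample.int(length(songs), k, replace = TRUE)])
        })
        nn <- length(meds)
        S <- diag(1, nn)
        for (i in seq_len(nn - 1L))
          for (j in seq(i + 1L, nn))
            S[i, j] <- S[j, i] <- lsi(meds[[i]], meds[[j]])
      }
      hit <- obs_keys %in% sl_keys(1 - S, labels)
      counts[hit, si] <- counts[hit, si] + 1L
    }
  }
  bp <- counts / n_boot
  fits <- apply(bp, 1L, au_from_bp, scales = scales)
  near1 <- which.min(abs(scales - 1))
  out <- data.frame(
    members = vapply(obs_idx, function(i) paste(labels[i], collapse = ";"),
                     character(1)),
    bp = bp[, near1],
    au = vapply(fits, `[[`, numeric(1), "au"),
    v = vapply(fits, `[[`, numeric(1), "v"),
    c = vapply(fits, `[[`, numeric(1), "c"),
    flag = vapply(fits, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE)
  dimnames(bp) <- list(NULL, paste0("r", scales))
  attr(out, "bp_by_scale") <- bp
  attr(out, "scales") <- scales
  attr(out, "n_boot") <- n_boot
  attr(out, "dendrogram") <- dend
  out
}

#' AU support of a specific division
#'
#' @param supports Result of [au_support()].
#' @param members Character vector of leaf labels forming one side of the
#'   division.
#' @return The AU value, or `NA` if the division is not in the observed
#'   dendrogram.
#' @export
division_support <- function(supports, members) {
  key <- paste(sort(members), collapse = ";")
  hit <- match(key, supports$members)
  if (is.na(hit)) return(NA_real_)
  supports$au[hit]
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are merge-height differences (leaves descend from their
#' parent's height to 0); internal node labels are AU x 100 when supports
#' are supplied. Labels containing characters outside `[A-Za-z0-9_.-]` are
#' single-quoted.
#'
#' @param dend A `song_dendrogram`.
#' @param supports Optional result of [au_support()] on the same tree.
#' @param digits Branch-length digits (default 6).
#' @return Newick string, terminated by `";"`.
#' @export
export_newick <- function(dend, supports = NULL, digits = 6) {
  labs <- dend$labels
  quote_lab <- function(s)
    ifelse(grepl("^[A-Za-z0-9_.-]+$", s), s, paste0("'", s, "'"))
  memb <- if (is.null(supports)) NULL else cluster_members(dend)
  au_label <- function(k) {
    if (is.null(supports)) return("")
    key <- paste(memb[[k]], collapse = ";")
    hit <- match(key, supports$members)
    if (is.na(hit) || is.na(supports$au[hit])) return("")
    format(round(100 * supports$au[hit], 1))
  }
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  node_str <- function(node, parent_h) {
    if (node < 0L)
      return(paste0(quote_lab(labs[-node]), ":", fmt(parent_h)))
    h <- dend$height[node]
    paste0("(", node_str(dend$merge[node, 1], h), ",",
           node_str(dend$merge[node, 2], h), ")", au_label(node),
           if (!is.na(parent_h)) paste0(":", fmt(parent_h - h)) else "")
  }
  paste0(node_str(nrow(dend$merge), NA), ";")
}

#' Cut a dendrogram into k groups
#'
#' @param dend A `song_dendrogram`.
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_dendrogram <- function(dend, k) {
  stats::cutree(as.hclust(dend), k = k)
}

#' Write division supports as CSV
#'
#' @param supports Result of [au_support()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_supports <- function(supports, path) {
  utils::write.csv(supports, path, row.names = FALSE)
  invisible(path)
}
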