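# Robustness check of a manual unit-type classification: a bagged ensemble
# of CART-style decision trees (Gini impurity, sqrt(p) features sampled per
# split) grown on bootstrap resamples of a numeric acoustic-feature table,
# scored by the out-of-bag (OOB) misclassification rate — the fraction of
# exemplars whose majority vote over trees not trained on them differs from
# the manual label.
#
# No tree package is assumed; the ensemble is self-contained.

validate_feature_table <- function(table) {
  stopifnot(is.data.frame(table))
  if (!"label" %in% names(table)) stop("feature table needs a 'label' column")
  if (anyNA(table$label)) stop("feature table has missing labels")
  y <- factor(table$label)
  if (nlevels(y) < 2L) stop("need at least 2 unit-type classes")
  small <- names(which(table(y) < 2L))
  if (length(small))
    stop("class(es) with a single exemplar: ", paste(small, collapse = ", "))
  X <- as.matrix(table[, setdiff(names(table), "label"), drop = FALSE])
  if (!is.numeric(X)) stop("all feature columns must be numeric")
  if (ncol(X) < 1L) stop("feature table has no feature columns")
  list(X = X, y = y)
}

# grow one CART tree; nodes accumulated in an environment.
# Split search: per node, `mtry` features sampled without replacement; for
# each, thresholds at midpoints between distinct sorted values; best Gini
# decrease wins.
grow_tree <- function(X, y, k, mtry, min_split = 2L, max_depth = 25L) {
  env <- new.env(parent = emptyenv())
  env$feature <- integer(0); env$threshold <- numeric(0)
  env$left <- integer(0); env$right <- integer(0); env$class <- integer(0)
  new_node <- function() {
    i <- length(env$feature) + 1L
    env$feature[i] <- NA_integer_; env$threshold[i] <- NA_real_
    env$left[i] <- 0L; env$right[i] <- 0L; env$class[i] <- NA_integer_
    i
  }
  majority <- function(yy) which.max(tabulate(yy, k))
  build <- function(idx, depth) {
    node <- new_node()
    yy <- y[idx]
    if (length(idx) < min_split || depth >= max_depth ||
        length(unique(yy)) == 1L) {
      env$class[node] <- majority(yy)
      return(node)
    }
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
    n <- length(idx)
    tot <- tabulate(yy, k)
    g_parent <- 1 - sum((tot / n)^2)
    for (f in feats) {
      x <- X[idx, f]
      ord <- order(x)
      xs <- x[ord]
      valid <- which(xs[-n] < xs[-1])      # split between distinct values
      if (!length(valid)) next
      cnt <- matrix(0L, n, k)
      cnt[cbind(seq_len(n), as.integer(yy[ord]))] <- 1L
      cum <- apply(cnt, 2L, cumsum)
      nl <- seq_len(n)
      gl <- 1 - rowSums((cum / nl)^2)
      nr <- n - nl
      right_cnt <- sweep(cum, 2L, tot, "-") * -1
      gr <- 1 - rowSums((right_cnt / pmax(nr, 1L))^2)
      wg <- (nl * gl + nr * gr) / n
      cand <- valid[which.min(wg[valid])]
      gain <- g_parent - wg[cand]
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = f,
                     threshold = (xs[cand] + xs[cand + 1L]) / 2)
      }
    }
    if (is.na(best$feature)) {
      env$class[node] <- majority(yy)
      return(node)
    }
    go_left <- X[idx, best$feature] <= best$threshold
    env$feature[node] <- best$feature
    env$threshold[node] <- best$threshold
    env$left[node] <- build(idx[go_left], depth + 1L)
    env$right[node] <- build(idx[!go_left], depth + 1L)
    node
  }
  build(seq_along(y), 0L)
  list(feature = env$feature, threshold = env$threshold,
       left = env$left, right = env$right, class = env$class)
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  stack <- list(list(node = 1L, idx = seq_len(n)))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node; idx <- top$idx
    if (!length(idx)) next
    if (!is.na(tree$class[node])) {
      out[idx] <- tree$class[node]
      next
    }
    go_left <- X[idx, tree$feature[node]] <= tree$threshold[node]
    stack[[length(stack) + 1L]] <- list(node = tree$left[node], idx = idx[go_left])
    stack[[length(stack) + 1L]] <- list(node = tree$right[node], idx = idx[!go_left])
  }
  out
}

# shared engine: accumulate OOB votes over the bagged ensemble.
# Rows are canonically reordered (by label, then features) before any random
# draw, so results are invariant to input row order at fixed seed.
oob_votes <- function(table, n_trees, seed, mtry = NULL) {
  vt <- validate_feature_table(table)
  if (n_trees < 100) stop("n_trees must be >= 100")
  ord <- do.call(order, c(list(as.character(vt$y)),
                          as.data.frame(vt$X, optional = TRUE)))
  X <- vt$X[ord, , drop = FALSE]
  y <- vt$y[ord]
  n <- nrow(X); k <- nlevels(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(as.integer(seed))
  votes <- matrix(0L, n, k)
  for (t in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob <- which(!(seq_len(n) %in% boot))
    tree <- grow_tree(X[boot, , drop = FALSE], y[boot], k, mtry)
    if (!length(oob)) next
    pred <- predict_tree(tree, X[oob, , drop = FALSE])
    votes[cbind(oob, pred)] <- votes[cbind(oob, pred)] + 1L
  }
  uncovered <- which(rowSums(votes) == 0L)
  pred <- max.col(votes, ties.method = "first")
  if (length(uncovered)) {
    # practically impossible for n_trees >= 100; fall back to the prior
    pred[uncovered] <- which.max(tabulate(as.integer(y), k))
  }
  list(y = y, pred = factor(levels(y)[pred], levels = levels(y)),
       votes = votes, uncovered = length(uncovered))
}

#' Out-of-bag misclassification rate
#'
#' @param table `data.frame` with numeric feature columns and a `label`
#'   column; every class needs at least two exemplars.
#' @param n_trees Trees in the ensemble (default 500; >= 100 enforced).
#' @param seed Integer seed (results are bit-identical per seed and
#'   invariant to row order).
#' @param mtry Features considered per split (default `floor(sqrt(p))`).
#' @return Misclassification rate in `[0, 1]`.
#' @export
oob_error <- function(table, n_trees = 500, seed, mtry = NULL) {
  if (missing(seed)) stop("oob_error requires a seed")
  v <- oob_votes(table, n_trees, seed, mtry)
  mean(v$pred != v$y)
}

#' OOB confusion matrix
#'
#' Rows are manual labels, columns OOB majority-vote predictions; rows sum
#' to class sizes, and `1 - sum(diag)/sum` equals [oob_error()] at the same
#' seed.
#'
#' @inheritParams oob_error
#' @return Integer matrix with class dimnames; the overall OOB error is
#'   attached as `attr(, "oob_error")`.
#' @export
per_class_confusion <- function(table, n_trees = 500, seed, mtry = NULL) {
  if (missing(seed)) stop("per_class_confusion requires a seed")
  v <- oob_votes(table, n_trees, seed, mtry)
  cm <- table(truth = v$y, predicted = v$pred)
  m <- matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  attr(m, "oob_error") <- 1 - sum(diag(m)) / sum(m)
  m
}
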