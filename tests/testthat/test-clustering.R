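sym <- function(v, labels) {
  n <- length(labels)
  m <- matrix(v, n, n, dimnames = list(labels, labels))
  m
}

test_that("single linkage merges forced orderings correctly", {
  S <- sym(c(1, .9, .1, .9, 1, .1, .1, .1, 1), c("A", "B", "C"))
  d <- single_linkage(S)
  mem <- cluster_members(d)
  expect_identical(mem[[1]], c("A", "B"))
  expect_equal(d$height, c(0.1, 0.9))

  # block-diagonal: two groups, within 0.8, between 0: last merge at 1.0
  labs <- paste0("s", 1:6)
  S <- sym(0, labs)
  S[1:3, 1:3] <- 0.8; S[4:6, 4:6] <- 0.8; diag(S) <- 1
  d <- single_linkage(S)
  expect_equal(max(d$height), 1.0)
  mem <- cluster_members(d)
  expect_true(any(vapply(mem, identical, logical(1), c("s1", "s2", "s3"))))
  expect_true(any(vapply(mem, identical, logical(1), c("s4", "s5", "s6"))))

  # identical rows merge at height 0
  S <- sym(1, c("A", "B", "C"))
  expect_equal(single_linkage(S)$height, c(0, 0))
  expect_error(single_linkage(matrix(c(1, .2, .5, 1), 2)), "symmetric")
})

test_that("heights agree with stats::hclust single linkage", {
  set.seed(31)
  for (i in 1:5) {
    n <- 10
    S <- matrix(runif(n * n), n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    dimnames(S) <- list(paste0("x", 1:n), paste0("x", 1:n))
    mine <- single_linkage(S)
    ref <- stats::hclust(stats::as.dist(1 - S), method = "single")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
  }
})

test_that("heights are non-decreasing and invariant to leaf permutation", {
  set.seed(32)
  for (i in 1:8) {
    n <- sample(4:12, 1)
    S <- matrix(runif(n * n), n); S <- (S + t(S)) / 2; diag(S) <- 1
    dimnames(S) <- list(paste0("x", 1:n), paste0("x", 1:n))
    d <- single_linkage(S)
    expect_true(all(diff(d$height) >= -1e-12))
    perm <- sample(n)
    dp <- single_linkage(S[perm, perm])
    expect_equal(sort(d$height), sort(dp$height))
    expect_setequal(vapply(cluster_members(d), paste, character(1),
                           collapse = "|"),
                    vapply(cluster_members(dp), paste, character(1),
                           collapse = "|"))
  }
})

test_that("newick export matches the worked example and round-trips", {
  S <- sym(c(1, .6, .6, 1), c("A", "B"))
  expect_identical(export_newick(single_linkage(S)), "(A:0.4,B:0.4);")

  set.seed(33)
  n <- 7
  S <- matrix(runif(n * n), n); S <- (S + t(S)) / 2; diag(S) <- 1
  dimnames(S) <- list(paste0("x", 1:n), paste0("x", 1:n))
  d <- single_linkage(S)
  tr <- ape::read.tree(text = export_newick(d))
  expect_identical(sort(tr$tip.label), sort(d$labels))
  ref <- ape::as.phylo(as.hclust(d))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  # singer ids with spaces and slashes survive quoting
  S2 <- sym(c(1, .5, .5, 1), c("G3 13/04/11", "W1305/06/13"))
  tr2 <- ape::read.tree(text = export_newick(single_linkage(S2)))
  # ape keeps the quotes on quoted labels; strip before comparing
  expect_setequal(gsub("^'|'$", "", tr2$tip.label),
                  c("G3 13/04/11", "W1305/06/13"))
})

test_that("AU support separates disjoint synthetic groups", {
  sim <- generate_song_groups(t4_config(seed = 61))
  X <- repertoire_matrix(lapply(sim$singers, `[[`, "repertoire"))
  sup <- au_support(X, "dci", n_boot = 200, seed = 62)
  g1 <- names(sim$truth)[sim$truth == 1]
  g2 <- names(sim$truth)[sim$truth == 2]
  expect_gt(division_support(sup, g1), 0.95)
  expect_gt(division_support(sup, g2), 0.95)
  # supports written as AU x 100 labels inside the newick, all in [0, 100]
  nwk <- export_newick(attr(sup, "dendrogram"), sup)
  labs <- as.numeric(regmatches(nwk, gregexpr("(?<=\\))[0-9.]+(?=[:,;)])",
                                              nwk, perl = TRUE))[[1]])
  expect_true(all(labs >= 0 & labs <= 100))
})

test_that("degenerate and reduced-scale AU fits follow the stated rules", {
  # 4 singers with two disjoint full catalogues: the two-group division is
  # in every replicate at every scale -> BP = 1 everywhere -> AU = 1
  reps <- list(a1 = c("Aa", "Ab"), a2 = c("Aa", "Ab"),
               b1 = c("Ca", "Cb"), b2 = c("Ca", "Cb"))
  sup <- au_support(reps, "dci", n_boot = 100, seed = 5)
  top <- sup[sup$members == "a1;a2", ]
  expect_equal(top$au, 1)
  expect_match(top$flag, "degenerate_all_one")
  # scales = {1}: BP is reported but AU flagged unavailable
  sup1 <- au_support(reps, "dci", n_boot = 100, scales = 1, seed = 5)
  expect_true(all(is.na(sup1$au)))
  expect_true(all(sup1$flag == "insufficient_scales"))
  expect_true(all(sup1$bp >= 0 & sup1$bp <= 1))
  expect_error(au_support(reps, "dci", n_boot = 100), "seed")
  expect_error(au_support(reps, "dci", n_boot = 10, seed = 1), ">= 100")
})

test_that("AU grows with group separation and stays low on noise", {
  # overlapping groups vs disjoint groups, same seed: AU should not shrink
  make_reps <- function(shared) {
    core1 <- paste0("A", letters[1:4]); core2 <- paste0("C", letters[1:4])
    both <- paste0("E", letters[seq_len(shared)])
    c(lapply(1:5, function(i) c(core1, both)),
      lapply(1:5, function(i) c(core2, both))) |>
      stats::setNames(paste0("s", 1:10))
  }
  au_of <- function(reps, seed) {
    sup <- au_support(reps, "dci", n_boot = 200, seed = seed)
    division_support(sup, paste0("s", 1:5))
  }
  # averaged over seeds: AU never decreases with separation beyond
  # bootstrap sampling error at n_boot = 200
  weak <- mean(vapply(71:73, function(s) au_of(make_reps(4), s), numeric(1)))
  strong <- mean(vapply(71:73, function(s) au_of(make_reps(0), s), numeric(1)))
  expect_gte(strong, weak - 0.02)
  expect_gt(strong, 0.95)

  # pure noise: a fixed random bipartition is rarely strongly supported
  set.seed(72)
  high_au <- 0L
  for (s in 1:5) {
    X <- matrix(rbinom(8 * 20, 1, 0.5), 8, 20,
                dimnames = list(paste0("n", 1:8), NULL))
    X[rowSums(X) == 0, 1] <- 1L
    sup <- au_support(X, "dci", n_boot = 200, seed = 100 + s)
    au <- division_support(sup, paste0("n", 1:4))
    if (!is.na(au) && au > 0.95) high_au <- high_au + 1L
  }
  expect_lte(high_au, 1L)
})

test_that("LSI bootstrap resamples songs and recomputes set medians", {
  songs <- list(
    e1 = list(c("Aa", "Ab", "Ac"), c("Aa", "Ab", "Ac"), c("Aa", "Ab")),
    e2 = list(c("Aa", "Ab", "Ac"), c("Aa", "Ab", "Ac"), c("Ab", "Ac")),
    w1 = list(c("Ga", "Gb", "Gc"), c("Ga", "Gb", "Gc"), c("Ga", "Gb")),
    w2 = list(c("Ga", "Gb", "Gc"), c("Ga", "Gb", "Gc"), c("Ga", "Gc")))
  sup <- au_support(songs, "lsi", n_boot = 100, scales = c(0.6, 1, 1.4),
                    seed = 9)
  expect_identical(nrow(sup), 3L)
  au <- division_support(sup, c("w1", "w2"))
  expect_gt(au, 0.95)
})

test_that("cut_dendrogram recovers planted partitions", {
  sim <- generate_song_groups(synth_config(seed = 41))
  sm <- similarity_matrix(lapply(sim$singers, `[[`, "repertoire"), "dci")
  grp <- cut_dendrogram(single_linkage(sm), 2)
  expect_true(same_partition(grp, sim$truth[names(grp)]))
})
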