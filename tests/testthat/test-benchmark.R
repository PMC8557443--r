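toy_ogs <- function(clusters) {
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters), vapply(clusters, `[`, "", 1))
  clusters <- clusters[ord]
  names(clusters) <- paste0("OG", seq_along(clusters) - 1)
  structure(list(clusters = clusters,
                 membership = setNames(rep(names(clusters),
                                           lengths(clusters)),
                                       unlist(clusters)),
                 unassigned = character(0)),
            class = "orthogroup_set")
}

test_that("family scores follow the analytic precision/recall/F formulas", {
  ogs <- toy_ogs(list(c("a", "b", "e"), "c"))
  ref <- list(F1 = c("a", "b", "c", "d"))
  best <- score_families(ref, ogs, mode = "best")
  expect_equal(best$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(best$recall, 1 / 2, tolerance = 1e-12)
  expect_equal(best$f_score, 4 / 7, tolerance = 1e-12)
  maj <- score_families(ref, ogs, mode = "majority")
  expect_equal(maj$precision, 3 / 4, tolerance = 1e-12)
  expect_equal(maj$recall, 3 / 4, tolerance = 1e-12)

  # perfect prediction scores 1 everywhere in both modes
  perfect <- toy_ogs(list(c("a", "b", "c", "d"), c("x", "y")))
  ref2 <- list(F1 = c("a", "b", "c", "d"), F2 = c("x", "y"))
  for (mode in c("best", "majority")) {
    sc <- score_families(ref2, perfect, mode = mode)
    expect_true(all(sc$precision == 1 & sc$recall == 1 & sc$f_score == 1))
  }
  expect_error(score_families(list(A = "a", B = "a"), perfect), "overlap")
})

test_that("majority mode raises recall when it keeps the best match", {
  # provable part: whenever the best-matched orthogroup qualifies for the
  # majority union, the union's recall cannot be lower (it is a superset)
  set.seed(7)
  gains <- c()
  for (rep in 1:20) {
    genes <- paste0("g", 1:30)
    ref <- split(genes, sample(3, 30, replace = TRUE))
    names(ref) <- paste0("F", seq_along(ref))
    ogs <- toy_ogs(unname(split(genes, sample(6, 30, replace = TRUE))))
    b <- score_families(ref, ogs, "best")
    m <- score_families(ref, ogs, "majority")
    kept <- mapply(function(mm, bb) bb %in% strsplit(mm, "+", fixed = TRUE)[[1]],
                   m$matched, b$matched)
    expect_true(all(m$recall[kept] >= b$recall[kept] - 1e-12))
    gains <- c(gains, m$recall - b$recall)
  }
  # the analytic example realizes a strict gain (0.75 vs 0.5)
  ogs <- toy_ogs(list(c("a", "b", "e"), "c"))
  ref <- list(F1 = c("a", "b", "c", "d"))
  expect_gt(score_families(ref, ogs, "majority")$recall,
            score_families(ref, ogs, "best")$recall)
})

test_that("the universe argument confines scoring to covered genes", {
  ogs <- toy_ogs(list(c("a", "b", "e"), "c"))
  ref <- list(F1 = c("a", "b", "c", "d"))
  sc <- score_families(ref, ogs, "best", universe = c("a", "b", "c", "d"))
  expect_equal(sc$precision, 1)         # e is outside the universe: no FP
  expect_equal(sc$recall, 1 / 2)
})

test_that("weighted means weight by family size", {
  sc <- data.frame(precision = c(1, 0.5), recall = c(1, 1),
                   f_score = c(1, 2 / 3), size = c(4, 1))
  wm <- weighted_mean_scores(sc)
  expect_equal(unname(wm["precision"]), 0.9)
  # equal sizes reduce to the plain mean
  sc2 <- data.frame(precision = c(0.2, 0.8), recall = c(1, 0),
                    f_score = c(0.5, 0.5), size = c(3, 3))
  expect_equal(unname(weighted_mean_scores(sc2)["precision"]), 0.5)
  one <- data.frame(precision = 0.7, recall = 0.6, f_score = 0.646,
                    size = 9)
  expect_equal(unname(weighted_mean_scores(one)["recall"]), 0.6)
  expect_error(weighted_mean_scores(sc[0, ]), "no family")
})

test_that("adjusted Rand index matches closed forms and is symmetric", {
  p <- list(c("a", "b"), c("c", "d"))
  expect_equal(adjusted_rand_index(p, p), 1.0)
  expect_equal(adjusted_rand_index(p, list(c("a", "b", "c", "d"))), 0.0)
  expect_error(adjusted_rand_index(p, list(c("a", "b"), c("c", "e"))),
               "same element set")
  set.seed(99)
  for (rep in 1:10) {
    x <- setNames(sample(4, 20, replace = TRUE), paste0("e", 1:20))
    y <- setNames(sample(3, 20, replace = TRUE), paste0("e", 1:20))
    expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
  }
})

test_that("ARI agrees with an independent reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(123)
  for (rep in 1:100) {
    x <- setNames(sample(5, 20, replace = TRUE), paste0("e", 1:20))
    y <- setNames(sample(5, 20, replace = TRUE), paste0("e", 1:20))
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y[names(x)]),
                 tolerance = 1e-12)
  }
})

test_that("tip randomization permutes only the sampled labels", {
  gt <- sim_random_tree(21, n_species = 6, dup_rate = 0.3)$tree
  # fraction 0: identity
  expect_identical(randomize_tips(gt, 0, seed = 1)$phylo$tip.label,
                   gt$phylo$tip.label)
  # fraction 1: the label multiset and the topology are conserved
  r1 <- randomize_tips(gt, 1, seed = 1)
  expect_setequal(r1$phylo$tip.label, gt$phylo$tip.label)
  expect_equal(r1$phylo$edge, gt$phylo$edge)
  expect_equal(r1$phylo$edge.length, gt$phylo$edge.length)
  # seeded runs reproduce; different seeds explore different permutations
  expect_identical(randomize_tips(gt, 0.5, seed = 7)$phylo$tip.label,
                   randomize_tips(gt, 0.5, seed = 7)$phylo$tip.label)
  # partial corruption moves at most ceiling(fraction * n) labels
  n <- ape::Ntip(gt$phylo)
  moved <- sum(randomize_tips(gt, 0.5, seed = 3)$phylo$tip.label !=
                 gt$phylo$tip.label)
  expect_lte(moved, ceiling(0.5 * n))
  # species assignments track the new labels
  r <- randomize_tips(gt, 0.5, seed = 3)
  expect_identical(names(r$species), r$phylo$tip.label)
  expect_error(randomize_tips(gt, 1.5), "fraction")
})
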