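toy_pairs <- function() {
  structure(data.frame(gene1 = c("A_x1", "A_x2"),
                       gene2 = c("B_y1", "B_y2"),
                       node = c(6L, 7L),
                       support = c(0.9, 0.8),
                       stringsAsFactors = FALSE),
            class = c("ortholog_pairs", "data.frame"))
}

test_that("graph building prunes below-threshold edges, keeping the node set", {
  genes <- c("A_x1", "B_y1", "A_x2", "B_y2")
  g <- build_graph(toy_pairs(), genes, min_support = 0)
  expect_equal(sum(g$adjacency > 0) / 2, 2)
  expect_equal(g$adjacency["A_x1", "B_y1"], 0.9)

  g2 <- build_graph(toy_pairs(), genes, min_support = 0.85)
  expect_equal(sum(g2$adjacency > 0) / 2, 1)
  expect_equal(g2$n_pruned, 1)
  expect_equal(sum(g2$adjacency["A_x2", ]), 0)   # isolated after pruning

  # an edge exactly at the threshold is kept
  g3 <- build_graph(toy_pairs(), genes, min_support = 0.8)
  expect_equal(sum(g3$adjacency > 0) / 2, 2)

  g4 <- build_graph(toy_pairs(), genes, weighted = FALSE)
  expect_true(all(g4$adjacency[g4$adjacency > 0] == 1))
})

test_that("MCL separates weakly bridged cliques and keeps cliques whole", {
  # two 3-cliques joined by a single weight-0.1 edge -> two clusters
  # (expected clusters verified against an independent MCL implementation)
  A <- clique_union_adjacency(list(1:3, 4:6), 6)
  A[3, 4] <- A[4, 3] <- 0.1
  expect_equal(mcl(A, inflation = 1.6), c(1, 1, 1, 2, 2, 2))
  # complete graph K4 -> one cluster
  expect_equal(mcl(clique_union_adjacency(list(1:4), 4), 1.6), rep(1, 4))
  # two disjoint 2-cliques at several inflations
  B <- clique_union_adjacency(list(1:2, 3:4), 4)
  for (I in c(1.2, 1.6, 2.0))
    expect_equal(mcl(B, I), c(1, 1, 2, 2))
  expect_error(mcl(matrix(1, 2, 3)), "square")
  expect_error(mcl(matrix(-1, 2, 2)), "non-negative")
})

test_that("MCL equals connected components on clique unions (<= 6 nodes)", {
  for (n in 1:6) for (p in all_partitions(n)) {
    A <- clique_union_adjacency(p, n)
    truth <- integer(n)
    for (ci in seq_along(p)) truth[p[[ci]]] <- ci
    for (I in c(1.2, 2.0))
      expect_true(same_partition(mcl(A, I), truth))
  }
})

test_that("MCL is equivariant under node relabeling", {
  set.seed(42)
  A <- clique_union_adjacency(list(1:3, 4:7, 8), 8)
  A[3, 4] <- A[4, 3] <- 0.05
  base <- mcl(A, 1.6)
  for (rep in 1:5) {
    perm <- sample(8)
    got <- mcl(A[perm, perm], 1.6)
    expect_true(same_partition(got, base[perm]))
  }
})

test_that("orthogroup ids are deterministic: by size, then smallest member", {
  genes <- c("A_x1", "B_y1", "A_x2", "B_y2")
  ogs <- assign_orthogroups(build_graph(toy_pairs(), genes))
  expect_equal(names(ogs$clusters), c("OG0", "OG1"))
  # equal sizes: OG0 owns the lexicographically smallest gene
  expect_equal(ogs$clusters$OG0, c("A_x1", "B_y1"))
  expect_equal(unname(ogs$membership[genes]),
               c("OG0", "OG0", "OG1", "OG1"))

  # no edges: all singletons
  empty <- toy_pairs()[0, ]
  ogs2 <- assign_orthogroups(build_graph(empty, c("A_x1", "A_x2")))
  expect_equal(lengths(ogs2$clusters), c(OG0 = 1L, OG1 = 1L))

  # the 5-edge dense graph from one speciation-rich tree: one orthogroup
  gt <- read_gene_tree("((A_x1,(B_y1,B_y2)0.5)0.9,C_z1);")
  fit <- orthogroups(gt$phylo, root = "keep")
  expect_equal(length(fit$orthogroups$clusters), 1)
  expect_equal(lengths(fit$orthogroups$clusters), c(OG0 = 4L))
})

test_that("pruning monotonicity: higher min_support never grows a cluster", {
  for (seed in c(2, 9)) {
    sim <- sim_random_tree(seed, dup_rate = 0.6)
    if (sim$extinct) next
    sim <- assign_supports(sim, spec_beta = c(2, 2), dup_beta = c(2, 2),
                           seed = seed)
    gt <- sim$tree
    ev <- classify_events(gt)
    pr <- extract_ortholog_pairs(gt, ev)
    genes <- gt$phylo$tip.label
    base <- assign_orthogroups(build_graph(pr, genes, min_support = 0))
    for (ms in c(0.3, 0.6, 0.9)) {
      pruned <- assign_orthogroups(build_graph(pr, genes, min_support = ms))
      for (cl in pruned$clusters) {
        host <- unique(base$membership[cl])
        expect_equal(length(host), 1)      # pruning only splits, never merges
        expect_lte(length(cl), length(base$clusters[[host]]))
      }
    }
  }
})

test_that("orthogroup support is the members' MRCA support", {
  gt <- read_gene_tree("((A_x1:1,B_y1:1)0.9:1,(A_x2:1,B_y2:1)0.8:1);")
  expect_equal(orthogroup_support(gt, c("A_x1", "B_y1")), 0.9)
  expect_true(is.na(orthogroup_support(gt, "A_x1")))          # singleton
  expect_true(is.na(orthogroup_support(gt, gt$phylo$tip.label))) # root: none
  expect_error(orthogroup_support(gt, "missing_gene"), "not in tree")
})

test_that("ingroup restriction splits hub-mediated orthogroups", {
  # ingroup genes h1,f1 and h2,f2 joined only through outgroup gene n1
  tx <- "(((H_h1:1,F_f1:1)0.9:1,(H_h2:1,F_f2:1)0.9:1)0.5:1,N_n1:3);"
  gt <- read_gene_tree(tx)
  ev <- classify_events(gt)
  pr <- extract_ortholog_pairs(gt, ev)
  genes <- gt$phylo$tip.label
  full <- assign_orthogroups(build_graph(pr, genes))
  expect_equal(lengths(full$clusters), c(OG0 = 5L))
  restr <- restrict_to_species(pr, genes, gt$species, c("H", "F"))
  expect_setequal(restr$clusters, list(c("F_f1", "H_h1"), c("F_f2", "H_h2")))
  expect_equal(restr$unassigned, "N_n1")

  # ingroup = all species reproduces the unrestricted clustering
  all_sp <- restrict_to_species(pr, genes, gt$species, c("H", "F", "N"))
  expect_equal(all_sp$clusters, full$clusters)

  # ingroup disjoint from the tree: everything unassigned, with a warning
  expect_warning(none <- restrict_to_species(pr, genes, gt$species, "Z"),
                 "unassigned")
  expect_equal(none$unassigned, genes)
})
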