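test_that("midpoint root halves the longest leaf-to-leaf path", {
  # longest path A-C = 12, so the root sits 6.0 from C on its terminal branch
  mr <- midpoint_root(read_gene_tree("(A_x1:1,(B_y1:1,C_z1:10):1);"))
  d <- ape::dist.nodes(mr$phylo)
  root <- ape::Ntip(mr$phylo) + 1
  tips <- setNames(d[root, 1:3], mr$phylo$tip.label)
  expect_equal(unname(tips["C_z1"]), 6.0)
  expect_equal(unname(tips["A_x1"]), 6.0)
  expect_equal(max(d[root, 1:3]), 6.0)

  # two leaves: symmetric halving of the single edge
  mr2 <- midpoint_root(read_gene_tree("(A_x1:1,B_y1:3);"))
  expect_equal(unname(ape::dist.nodes(mr2$phylo)[3, 1:2]), c(2, 2))

  # a balanced midpoint-rooted tree is a fixed point (topology unchanged)
  bal <- read_gene_tree("((A_x1:1,B_y1:1):1,(A_x2:1,B_y2:1):1);")
  mr3 <- midpoint_root(bal)
  expect_true(ape::all.equal.phylo(mr3$phylo, bal$phylo,
                                   use.edge.length = FALSE))
})

test_that("missing branch lengths error unless unit lengths are requested", {
  gt <- read_gene_tree("((A_x1,B_y1),C_z1);")
  expect_error(midpoint_root(gt), "unit_lengths")
  expect_s3_class(midpoint_root(gt, unit_lengths = TRUE), "gene_tree")
})

test_that("candidate ranking matches a brute-force positional scan", {
  # slide a root along every edge at 0.01 resolution; distance from an
  # interior point to any tip goes through one of the edge's endpoints
  brute_edge_scores <- function(gt) {
    un <- ape::reorder.phylo(ape::unroot(gt$phylo), "cladewise")
    dn <- ape::dist.nodes(un)
    ntip <- ape::Ntip(un)
    vapply(seq_len(nrow(un$edge)), function(i) {
      p <- un$edge[i, 1]; ch <- un$edge[i, 2]; L <- un$edge.length[i]
      best <- Inf
      for (y in seq(0, L, by = 0.01)) {
        h <- max(vapply(seq_len(ntip), function(tp)
          min(y + dn[ch, tp], (L - y) + dn[p, tp]), 0))
        best <- min(best, h)
      }
      best
    }, 0)
  }
  trees <- c("(A_a1:10,B_b1:1,(A_a2:1,B_b2:1):1);",
             "(A_x1:1,(B_y1:1,C_z1:10):1);",
             "((A_x1:2,B_y1:0.5):1,(C_z1:3,(D_w1:1,E_v1:2):0.5):2);")
  for (tx in trees) {
    gt <- read_gene_tree(tx)
    cand <- rank_root_candidates(gt, n = 100)
    brute <- sort(brute_edge_scores(gt))
    expect_equal(cand$score, brute[seq_len(nrow(cand))], tolerance = 0.011)
  }
})

test_that("quartet example: best edge is the long terminal branch", {
  cand <- rank_root_candidates(
    read_gene_tree("(A_a1:10,B_b1:1,(A_a2:1,B_b2:1):1);"), n = 10)
  expect_equal(nrow(cand), 5)            # n capped at the edge count
  expect_equal(cand$score[1], 6)
  expect_equal(sort(cand$score), c(6, 10, 10, 11, 11))
  n1 <- rank_root_candidates(
    read_gene_tree("(A_a1:10,B_b1:1,(A_a2:1,B_b2:1):1);"), n = 1)
  expect_equal(nrow(n1), 1)
})

test_that("iterative rooting minimizes the orthogroup count", {
  tx <- "(A_a1:10,B_b1:1,(A_a2:1,B_b2:1):1);"
  fit_mid <- orthogroups(tx, root = "midpoint")
  fit_it <- orthogroups(tx, root = "iterative", iter_n = 3)
  expect_equal(length(fit_mid$orthogroups$clusters), 3)
  expect_equal(length(fit_it$orthogroups$clusters), 2)
  expect_setequal(fit_it$orthogroups$clusters,
                  list(c("A_a1", "B_b1"), c("A_a2", "B_b2")))

  # when midpoint is already optimal the lower rank wins the tie
  bal <- "((A_x1:1,B_y1:1):1,(A_x2:1,B_y2:1):1);"
  it <- iterative_root(read_gene_tree(bal), n = 5)
  expect_equal(attr(it, "root_rank"), 1)

  # single-species tree: every rooting gives all-singleton orthogroups
  one <- "((A_x1:1,A_x2:1):1,A_x3:2);"
  it1 <- iterative_root(read_gene_tree(one), n = 5)
  expect_equal(attr(it1, "root_rank"), 1)
  expect_equal(min(attr(it1, "og_counts")), 3)
})

test_that("iterative never yields more orthogroups than plain midpoint", {
  for (seed in 1:12) {
    sim <- sim_random_tree(seed)
    if (sim$extinct || ape::Ntip(sim$tree$phylo) < 4) next
    gt <- sim$tree
    n_mid <- length(orthogroups(gt, root = "midpoint")$orthogroups$clusters)
    n_it <- length(orthogroups(gt, root = "iterative",
                               iter_n = 5)$orthogroups$clusters)
    expect_lte(n_it, n_mid)
  }
})

test_that("supports survive rerooting via their bipartitions", {
  gt <- read_gene_tree("((A_x1:1,(B_y1:1,C_z1:1)0.7:1)0.9:1,(A_x2:1,B_y2:1)0.8:2);")
  mr <- midpoint_root(gt)
  # the 0.7 and 0.8 clades exist in any rooting and keep their values
  desc <- lapply((ape::Ntip(mr$phylo) + 1):(ape::Ntip(mr$phylo) + mr$phylo$Nnode),
                 function(nd) sort(ape::extract.clade(mr$phylo, nd)$tip.label))
  sup_of <- function(tips) {
    i <- which(vapply(desc, identical, NA, sort(tips)))
    mr$support[i]
  }
  expect_equal(sup_of(c("B_y1", "C_z1")), 0.7)
  expect_equal(sup_of(c("A_x2", "B_y2")), 0.8)
})
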