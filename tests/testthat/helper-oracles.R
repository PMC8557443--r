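# Independent oracles and small generators used across tests. These
# deliberately avoid the package's own traversal helpers so they can serve
# as cross-checks.

# -- brute-force ortholog pairs: for every gene pair, find the MRCA by path
#    intersection and re-derive the event from scratch ----------------------
oracle_pairs_and_events <- function(tree, threshold = 0) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  path_to_root <- function(v) {
    out <- v
    while (parent[v] != 0) { v <- parent[v]; out <- c(out, v) }
    out
  }
  tips_under <- function(v) {
    if (v <= ntip) return(v)
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    unlist(lapply(kids, tips_under))
  }
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  node_event <- function(v) {
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    sets <- lapply(kids, function(k) unique(tree$species[tips_under(k)]))
    best <- 0
    for (a in seq_len(length(sets) - 1)) for (b in (a + 1):length(sets))
      best <- max(best, jacc(sets[[a]], sets[[b]]))
    if (best > threshold) "duplication" else "speciation"
  }
  events <- vapply((ntip + 1):(ntip + phy$Nnode), node_event, "")
  names(events) <- as.character((ntip + 1):(ntip + phy$Nnode))
  pairs <- character(0)
  if (ntip >= 2) {
    for (i in 1:(ntip - 1)) for (j in (i + 1):ntip) {
      pi <- path_to_root(i); pj <- path_to_root(j)
      mrca <- intersect(pi, pj)[1]
      if (events[[as.character(mrca)]] == "speciation") {
        g <- sort(phy$tip.label[c(i, j)])
        pairs <- c(pairs, paste(g[1], g[2]))
      }
    }
  }
  list(events = events, pairs = sort(pairs))
}

pair_keys <- function(pairs_df) sort(paste(pairs_df$gene1, pairs_df$gene2))

# -- all set partitions of 1..n (for the clique-components MCL check) ------
all_partitions <- function(n) {
  if (n == 0) return(list(list()))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (i in seq_along(p)) {
      q <- p; q[[i]] <- c(q[[i]], n); out <- c(out, list(q))
    }
    out <- c(out, list(c(p, list(n))))
  }
  out
}

clique_union_adjacency <- function(blocks, n) {
  A <- matrix(0, n, n)
  for (blk in blocks) for (i in blk) for (j in blk) if (i != j) A[i, j] <- 1
  A
}

same_partition <- function(memb1, memb2) {
  p1 <- lapply(unname(split(seq_along(memb1), memb1)), sort)
  p2 <- lapply(unname(split(seq_along(memb2), memb2)), sort)
  setequal(p1, p2)
}

# -- simulated trees under the standard study conditions -------------------
sim_random_tree <- function(seed, n_species = NULL, dup_rate = NULL, k = 1) {
  set.seed(seed)
  if (is.null(n_species)) n_species <- 4 + (seed %% 5)
  if (is.null(dup_rate)) dup_rate <- c(0, 0.3, 0.6)[1 + (seed %% 3)]
  sp <- ape::rtree(n_species, tip.label = LETTERS[seq_len(n_species)])
  simulate_gene_tree(sp, dup_rate = dup_rate, loss_rate = 0, k = k,
                     seed = seed)
}
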