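# Species-overlap event calling: each internal node of a rooted gene tree is
# a duplication when its child subtrees share species, a speciation
# otherwise. Ortholog pairs are the gene pairs whose MRCA is a speciation.

#' Species-overlap score of two species sets
#'
#' The Jaccard index of the species sets of two sister subtrees:
#' `|L intersect R| / |L union R|`. Zero when the sets are disjoint, one when
#' identical. At the default threshold 0 any shared species marks the parent
#' node as a duplication.
#'
#' @param left,right non-empty character vectors of species names.
#' @return overlap score in `[0, 1]`.
#' @examples
#' species_overlap_score(c("A", "B", "C"), c("A", "D"))  # 0.25
#' @export
species_overlap_score <- function(left, right) {
  left <- unique(left); right <- unique(right)
  if (length(left) == 0L || length(right) == 0L)
    stop("species sets must be non-empty")
  length(intersect(left, right)) / length(union(left, right))
}

#' Classify internal nodes as speciations or duplications
#'
#' Walks a rooted gene tree and scores every internal node by the species
#' overlap of its child subtrees; a node is a duplication when the score
#' strictly exceeds `threshold` (so threshold 0 keeps species-disjoint
#' bipartitions as speciations). Polytomies take the maximum score over all
#' unordered child pairs.
#'
#' @param tree a rooted `gene_tree`.
#' @param threshold species-overlap threshold in `[0, 1)`; larger values
#'   tolerate more species sharing and give more inclusive, less granular
#'   orthology calls.
#' @return object of class `node_events`: data.frame with one row per
#'   internal node (`node`, `event` = `"speciation"`/`"duplication"`,
#'   `score`, `support`), with the threshold and per-node child structures
#'   stored as attributes.
#' @export
classify_events <- function(tree, threshold = 0) {
  stopifnot(inherits(tree, "gene_tree"), threshold >= 0, threshold < 1)
  phy <- tree$phylo
  if (!ape::is.rooted(phy))
    stop("tree is unrooted; root it first (midpoint_root(), iterative_root() ",
         "or a precomputed root)", call. = FALSE)
  ntip <- ape::Ntip(phy)
  desc <- descendant_tips(phy)
  kids <- node_children(phy)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  score <- numeric(length(nodes))
  child_sets <- vector("list", length(nodes))
  for (j in seq_along(nodes)) {
    ch <- kids[[nodes[j]]]
    sets <- lapply(ch, function(c) unique(unname(tree$species[desc[[c]]])))
    child_sets[[j]] <- sets
    best <- 0
    for (a in seq_len(length(sets) - 1L))
      for (b in (a + 1L):length(sets))
        best <- max(best, species_overlap_score(sets[[a]], sets[[b]]))
    score[j] <- best
  }
  out <- data.frame(
    node = nodes,
    event = ifelse(score > threshold, "duplication", "speciation"),
    score = score,
    support = tree$support)
  attr(out, "threshold") <- threshold
  attr(out, "children") <- kids
  attr(out, "desc_tips") <- desc
  class(out) <- c("node_events", "data.frame")
  out
}

#' Extract all ortholog pairs implied by the event classification
#'
#' A gene pair is orthologous when the most recent common ancestor of the two
#' genes is a speciation node. For binary speciation nodes all cross-child
#' gene pairs are emitted; at polytomies pairs are emitted only across child
#' subtrees whose pairwise overlap score is at or below the threshold. Each
#' pair carries the support of its MRCA (`NA` when the input tree had none;
#' consumers treat missing as 1).
#'
#' @param tree the rooted `gene_tree` used for `events`.
#' @param events a `node_events` object from [classify_events()].
#' @return object of class `ortholog_pairs`: data.frame with columns
#'   `gene1`, `gene2` (unordered, stored with `gene1 < gene2`), `node`
#'   (MRCA) and `support`.
#' @export
extract_ortholog_pairs <- function(tree, events) {
  stopifnot(inherits(events, "node_events"))
  phy <- tree$phylo
  labs <- phy$tip.label
  desc <- attr(events, "desc_tips")
  kids <- attr(events, "children")
  threshold <- attr(events, "threshold")
  g1 <- character(0); g2 <- character(0); nd <- integer(0); sup <- numeric(0)
  spec_nodes <- events$node[events$event == "speciation"]
  for (v in spec_nodes) {
    ch <- kids[[v]]
    s <- node_support(tree, v)
    for (a in seq_len(length(ch) - 1L)) {
      for (b in (a + 1L):length(ch)) {
        ta <- desc[[ch[a]]]; tb <- desc[[ch[b]]]
        if (length(ch) > 2L) {      # polytomy: emit only non-overlapping pairs
          sc <- species_overlap_score(tree$species[ta], tree$species[tb])
          if (sc > threshold) next
        }
        grid <- expand.grid(x = labs[ta], y = labs[tb],
                            stringsAsFactors = FALSE)
        lo <- pmin(grid$x, grid$y); hi <- pmax(grid$x, grid$y)
        g1 <- c(g1, lo); g2 <- c(g2, hi)
        nd <- c(nd, rep(v, nrow(grid))); sup <- c(sup, rep(s, nrow(grid)))
      }
    }
  }
  out <- data.frame(gene1 = g1, gene2 = g2, node = nd, support = sup,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_pairs", "data.frame")
  out
}
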