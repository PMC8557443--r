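# Rooting: midpoint, ranked midpoint-like candidates, and the iterative
# procedure that keeps the candidate minimizing the orthogroup count.
#
# Every edge of the unrooted topology is scored by the smallest maximum
# root-to-tip distance achievable when the root is placed optimally on that
# edge; the best-scoring edge hosts the classical midpoint root, and the
# ranked runners-up are the candidates tried by iterative rooting.

#' Rank candidate root positions
#'
#' Scores every edge of the unrooted topology by the minimal achievable
#' maximum root-to-tip path length when rooting on that edge, and returns the
#' `n` best candidates in ascending score order (ties broken by preorder edge
#' index). Candidate 1 is the midpoint root.
#'
#' @param tree a `gene_tree` with branch lengths.
#' @param n number of candidates to return (capped at the edge count).
#' @param unit_lengths if `TRUE`, missing branch lengths are replaced by 1;
#'   otherwise their absence is an error.
#' @return a data.frame with one row per candidate: `rank`, `edge` (preorder
#'   index in the unrooted tree), `child` (node below the edge), `position`
#'   (distance of the root point above `child`) and `score`.
#' @export
rank_root_candidates <- function(tree, n = 10L, unit_lengths = FALSE) {
  stopifnot(inherits(tree, "gene_tree"), n >= 1L)
  phy <- tree$phylo
  if (ape::Ntip(phy) < 2L) stop("tree must have at least 2 leaves")
  if (is.null(phy$edge.length)) {
    if (!unit_lengths)
      stop("tree has no branch lengths; pass unit_lengths = TRUE to assume ",
           "unit-length branches", call. = FALSE)
    phy$edge.length <- rep(1, nrow(phy$edge))
  }
  if (ape::Ntip(phy) == 2L) {
    # a 2-leaf tree has one unrooted edge; the only candidate halves it
    total <- sum(phy$edge.length)
    out <- data.frame(rank = 1L, edge = 1L, child = 1L,
                      position = total / 2, score = total / 2)
    attr(out, "unrooted") <- phy
    attr(out, "two_tip_total") <- total
    return(out)
  }
  un <- if (ape::is.rooted(phy)) ape::unroot(phy) else phy
  un <- ape::reorder.phylo(un, "cladewise")        # preorder edge indexing
  ntip <- ape::Ntip(un)
  desc <- descendant_tips(un)
  dn <- ape::dist.nodes(un)
  scores <- numeric(nrow(un$edge))
  pos <- numeric(nrow(un$edge))
  for (i in seq_len(nrow(un$edge))) {
    p <- un$edge[i, 1L]; ch <- un$edge[i, 2L]; len <- un$edge.length[i]
    below <- desc[[ch]]
    above <- setdiff(seq_len(ntip), below)
    h_c <- max(dn[ch, below])                       # deepest tip below
    h_p <- max(dn[p, above])                        # deepest tip above
    y <- min(max((h_p + len - h_c) / 2, 0), len)    # distance above `ch`
    scores[i] <- max(h_c + y, h_p + len - y)
    pos[i] <- y
  }
  ord <- order(scores, seq_along(scores))
  keep <- ord[seq_len(min(n, length(ord)))]
  out <- data.frame(rank = seq_along(keep), edge = keep,
                    child = un$edge[keep, 2L], position = pos[keep],
                    score = scores[keep])
  attr(out, "unrooted") <- un
  out
}

# root the unrooted tree at a given candidate row; supports are recovered by
# bipartition lookup so they survive the node renumbering
root_at_candidate <- function(tree, candidates, rank) {
  un <- attr(candidates, "unrooted")
  row <- candidates[candidates$rank == rank, , drop = FALSE]
  if (nrow(row) != 1L) stop("no candidate with rank ", rank)
  if (!is.null(attr(candidates, "two_tip_total"))) {
    total <- attr(candidates, "two_tip_total")
    out <- tree
    out$phylo <- un
    out$phylo$edge.length <- rep(total / 2, 2L)
    return(out)
  }
  len <- un$edge.length[row$edge]
  # phytools measures `position` from the parent end of the child's edge
  p <- len - row$position
  p <- min(max(p, 0), len)
  rooted <- phytools::reroot(un, row$child, position = p)
  map <- split_support_map(tree)
  out <- tree
  out$phylo <- rooted
  out$species <- out$species[rooted$tip.label]
  apply_split_supports(out, map)
}

#' Midpoint-root a gene tree
#'
#' Places the root halfway along the longest leaf-to-leaf path, so the two
#' deepest root-to-tip distances are equal (or as equal as the hosting edge
#' allows).
#'
#' @inheritParams rank_root_candidates
#' @return the rooted `gene_tree` (supports preserved by bipartition).
#' @export
midpoint_root <- function(tree, unit_lengths = FALSE) {
  cand <- rank_root_candidates(tree, n = 1L, unit_lengths = unit_lengths)
  root_at_candidate(tree, cand, 1L)
}

#' Iterative root selection minimizing the orthogroup count
#'
#' Tries the `n` best midpoint-like root candidates; for each, classifies
#' speciation/duplication events, extracts ortholog pairs and clusters them,
#' then keeps the root giving the fewest orthogroups (an implicit parsimony
#' criterion on ancestral gene copies). Ties go to the lower rank, i.e. the
#' candidate closest to the plain midpoint. Useful when a long internal
#' branch would be mistaken for the root by plain midpoint rooting.
#'
#' @inheritParams rank_root_candidates
#' @param overlap_threshold species-overlap threshold (see
#'   [classify_events()]).
#' @param inflation MCL inflation.
#' @param min_support edge-pruning threshold for the ortholog graph.
#' @param weighted use supports as edge weights.
#' @return the rooted `gene_tree`, with attributes `root_rank` (chosen
#'   candidate) and `og_counts` (orthogroup count per candidate).
#' @export
iterative_root <- function(tree, n = 10L, overlap_threshold = 0,
                           inflation = 1.6, min_support = 0,
                           weighted = TRUE, unit_lengths = FALSE) {
  cand <- rank_root_candidates(tree, n = n, unit_lengths = unit_lengths)
  counts <- integer(nrow(cand))
  for (r in cand$rank) {
    rooted <- root_at_candidate(tree, cand, r)
    ev <- classify_events(rooted, threshold = overlap_threshold)
    pr <- extract_ortholog_pairs(rooted, ev)
    g <- build_graph(pr, rooted$phylo$tip.label, weighted = weighted,
                     min_support = min_support)
    ogs <- assign_orthogroups(g, inflation = inflation)
    counts[r] <- length(ogs$clusters)
  }
  chosen <- which.min(counts)                      # first minimum: lowest rank
  out <- root_at_candidate(tree, cand, chosen)
  attr(out, "root_rank") <- chosen
  attr(out, "og_counts") <- counts
  out
}
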