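# Pair-level evolutionary relationships: orthologs, in-paralogs and
# out-paralogs, relative to orthogroup membership.
#
# Operational definitions: a pair whose MRCA is a speciation node is an
# ortholog pair; a pair with a duplication MRCA is an in-paralog pair when
# the two genes share an orthogroup and an out-paralog pair otherwise. Note
# that "in/out" here is relative to orthogroup co-membership, not to the
# classical species-pair-relative definition; after support pruning the
# graph and the tree can disagree, so ortholog pairs split across
# orthogroups are still reported as orthologs, with `same_orthogroup =
# FALSE`.

#' Classify the relationship of one gene pair
#'
#' @param tree the rooted `gene_tree`.
#' @param events a `node_events` object from [classify_events()].
#' @param ogs an `orthogroup_set` covering the tree's genes.
#' @param g,h two distinct gene ids.
#' @return one-row data.frame: `gene1`, `gene2`, `relation` (`"ortholog"`,
#'   `"in-paralog"` or `"out-paralog"`), `same_orthogroup`, `mrca_support`.
#' @export
classify_pair <- function(tree, events, ogs, g, h) {
  phy <- tree$phylo
  idx <- match(c(g, h), phy$tip.label)
  if (anyNA(idx))
    stop("gene(s) not in tree: ",
         paste(c(g, h)[is.na(idx)], collapse = ", "), call. = FALSE)
  if (g == h) stop("the two genes must differ")
  m <- mrca_node(phy, idx)
  ev <- events$event[match(m, events$node)]
  same <- !is.na(ogs$membership[g]) && !is.na(ogs$membership[h]) &&
    ogs$membership[g] == ogs$membership[h]
  relation <- if (ev == "speciation") "ortholog"
              else if (same) "in-paralog" else "out-paralog"
  data.frame(gene1 = g, gene2 = h, relation = relation,
             same_orthogroup = same,
             mrca_support = node_support(tree, m),
             stringsAsFactors = FALSE)
}

#' Classify every gene against a focal gene
#'
#' One record per other gene, in tree preorder (the order tips appear in the
#' plotted tree), e.g. to dissect all homologs of one gene of interest into
#' orthologs, in-paralogs and out-paralogs.
#'
#' @inheritParams classify_pair
#' @param focal the focal gene id.
#' @return data.frame as in [classify_pair()], `gene1` = focal throughout.
#' @export
classify_all_vs_focal <- function(tree, events, ogs, focal) {
  phy <- ape::reorder.phylo(tree$phylo, "cladewise")
  if (!focal %in% phy$tip.label)
    stop("focal gene not in tree: ", focal, call. = FALSE)
  others <- phy$tip.label[phy$edge[phy$edge[, 2L] <= ape::Ntip(phy), 2L]]
  others <- setdiff(others, focal)
  if (length(others) == 0L)
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      relation = character(0), same_orthogroup = logical(0),
                      mrca_support = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(others, function(h)
    classify_pair(tree, events, ogs, focal, h)))
}
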