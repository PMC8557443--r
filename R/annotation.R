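# Reference-based naming: annotate genes by their reference orthologs, name
# orthogroups by the reference genes they contain, and propagate "like:"
# labels from named to unnamed orthogroups along the tree.

#' Read a reference-name dictionary
#'
#' Tab-separated file with two columns: reference gene id (as it appears in
#' the tree leaf labels) and gene name. No header.
#'
#' @param file path to the TSV file.
#' @return named character vector: gene id -> name.
#' @export
read_annotation_dict <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  if (ncol(d) < 2L) stop("dictionary must have two tab-separated columns")
  if (anyDuplicated(d[[1L]])) stop("duplicated reference gene ids in dictionary")
  stats::setNames(as.character(d[[2L]]), as.character(d[[1L]]))
}

#' Annotate genes with reference gene names
#'
#' Each gene receives the names of all reference genes it forms an ortholog
#' pair with (one-to-one, one-to-many and many-to-many relationships all
#' reduce to this pairwise rule). The annotation support is the support of
#' the deepest qualifying node: the MRCA closest to the root among the
#' gene's pairs with reference genes.
#'
#' @param tree the rooted `gene_tree`.
#' @param pairs an `ortholog_pairs` data.frame.
#' @param dict named character vector, reference gene id -> name (see
#'   [read_annotation_dict()]).
#' @return data.frame with one row per gene: `gene`, `annotation`
#'   (`"/"`-joined natural-sorted unique names, `""` when none) and
#'   `annotation_support` (`NA` when none or unsupported).
#' @export
annotate_genes <- function(tree, pairs, dict) {
  labs <- tree$phylo$tip.label
  missing_refs <- setdiff(names(dict), labs)
  if (length(missing_refs))
    warning("reference gene(s) absent from the tree, ignored: ",
            paste(utils::head(missing_refs, 5L), collapse = ", "),
            if (length(missing_refs) > 5L) " ..." else "")
  dict <- dict[names(dict) %in% labs]
  depths <- node_depths(tree$phylo)
  ann <- rep("", length(labs))
  ann_sup <- rep(NA_real_, length(labs))
  names(ann) <- names(ann_sup) <- labs
  # long form: (gene, reference partner, mrca node)
  both <- rbind(
    data.frame(gene = pairs$gene1, ref = pairs$gene2, node = pairs$node),
    data.frame(gene = pairs$gene2, ref = pairs$gene1, node = pairs$node))
  both <- both[both$ref %in% names(dict), , drop = FALSE]
  if (nrow(both)) {
    for (g in unique(both$gene)) {
      rows <- both[both$gene == g, , drop = FALSE]
      nms <- unique(dict[rows$ref])
      ann[g] <- paste(natural_sort(nms), collapse = "/")
      deepest <- rows$node[which.min(depths[rows$node])]
      ann_sup[g] <- node_support(tree, deepest)
    }
  }
  data.frame(gene = labs, annotation = unname(ann),
             annotation_support = unname(ann_sup),
             stringsAsFactors = FALSE)
}

#' Name orthogroups after the reference genes they contain
#'
#' An orthogroup holding one reference gene takes that gene's name; one
#' holding several gets a composite `"A/B"` name (unique names,
#' natural-sorted). Orthogroups with no reference gene are left unnamed
#' (empty string) pending [propagate_like_labels()].
#'
#' @param ogs an `orthogroup_set`.
#' @param dict named character vector, reference gene id -> name.
#' @return named character vector: orthogroup id -> name (possibly `""`).
#' @export
name_orthogroups <- function(ogs, dict) {
  vapply(ogs$clusters, function(members) {
    refs <- intersect(members, names(dict))
    if (length(refs) == 0L) return("")
    paste(natural_sort(unique(unname(dict[refs]))), collapse = "/")
  }, "")
}

#' Propagate "like:" labels to unnamed orthogroups
#'
#' For each orthogroup without a direct reference-based name, ascend from the
#' MRCA of its members toward the root; at the first node whose support
#' passes `min_support` (missing support counts as fully trusted) and whose
#' descendant leaves include members of at least one directly named
#' orthogroup, the unnamed orthogroup is labeled
#' `"like:"` + the `"/"`-joined natural-sorted unique names of all named
#' orthogroups under that node. `min_support` controls the greediness of the
#' propagation; at the default 0 a label is always found when any named
#' orthogroup exists.
#'
#' @param tree the rooted `gene_tree`.
#' @param ogs an `orthogroup_set`.
#' @param names named character vector from [name_orthogroups()].
#' @param min_support minimum support of the connecting ancestor, in `[0,1]`.
#' @return data.frame with one row per orthogroup: `orthogroup`, `name`
#'   (direct, `like:`-propagated, or `""`), `propagated` (logical) and
#'   `propagation_support` (support of the connecting ancestor, `NA`
#'   otherwise).
#' @export
propagate_like_labels <- function(tree, ogs, names, min_support = 0) {
  phy <- tree$phylo
  labs <- phy$tip.label
  parent <- node_parent(phy)
  desc <- descendant_tips(phy)
  named <- names[nzchar(names)]
  out <- data.frame(orthogroup = base::names(names), name = unname(names),
                    propagated = FALSE, propagation_support = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(named) == 0L) return(out)
  # genes of each directly named orthogroup
  og_of <- ogs$membership
  for (i in seq_len(nrow(out))) {
    if (nzchar(out$name[i])) next
    members <- ogs$clusters[[out$orthogroup[i]]]
    node <- mrca_node(phy, match(members, labs))
    repeat {
      ok_sup <- effective_support(tree, node) >= min_support ||
        node <= ape::Ntip(phy)            # a tip start point carries no support
      if (ok_sup) {
        under <- labs[desc[[node]]]
        hit_ogs <- unique(og_of[under])
        hit_ogs <- hit_ogs[hit_ogs %in% base::names(named)]
        if (length(hit_ogs)) {
          nms <- unique(unlist(strsplit(unname(named[hit_ogs]), "/",
                                        fixed = TRUE)))
          out$name[i] <- paste0("like:",
                                paste(natural_sort(nms), collapse = "/"))
          out$propagated[i] <- TRUE
          out$propagation_support[i] <- node_support(tree, node)
          break
        }
      }
      node <- parent[node]
      if (is.na(node)) break              # reached past the root: stays unnamed
    }
  }
  out
}
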