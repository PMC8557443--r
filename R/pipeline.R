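# End-to-end pipeline: parse -> normalize supports -> root -> classify
# events -> extract ortholog pairs -> build graph -> MCL -> supports ->
# annotate -> propagate labels. Returned as a single classed object with
# print/summary/plot methods and tabular writers.

#' Infer orthogroups from a species-labeled gene tree
#'
#' The main entry point: runs the whole orthology pipeline on one gene tree
#' and returns everything it computed — the rooted tree, per-node
#' speciation/duplication events, ortholog pairs, the MCL orthogroups with
#' their supports, and (when a reference dictionary is supplied) gene and
#' orthogroup names.
#'
#' @param tree a `gene_tree` (see [read_gene_tree()]), a `phylo` object, or
#'   a NEWICK string/path (parsed with `delimiter`/`species_field`).
#' @param sos species-overlap threshold in `[0, 1)`; 0 (default) tolerates
#'   no species sharing at speciation nodes.
#' @param inflation MCL inflation parameter, default 1.6.
#' @param min_support prune ortholog-graph edges whose MRCA support is below
#'   this value (default 0: keep all).
#' @param weighted use node supports as edge weights (default `TRUE`).
#' @param root rooting mode: `"keep"` (input tree must be rooted),
#'   `"midpoint"`, or `"iterative"` (try the `iter_n` best midpoint
#'   candidates, keep the one minimizing the orthogroup count).
#' @param iter_n candidates tried by iterative rooting, default 10.
#' @param ingroup optional character vector of species: clustering is
#'   restricted to genes of these species and other genes are reported
#'   unassigned (hierarchical orthogroups).
#' @param reference_names optional named character vector (reference gene id
#'   -> gene name) or path to a two-column TSV, enabling annotation.
#' @param min_annot_support support gate for "like:" label propagation.
#' @param delimiter,species_field leaf-label parsing (see
#'   [read_gene_tree()]).
#' @param unit_lengths assume unit branch lengths when absent (rooting only).
#' @return object of class `orthology_fit`: list with elements `tree` (the
#'   rooted `gene_tree`), `events`, `pairs`, `orthogroups`, `og_support`
#'   (named numeric), `gene_annotation`, `og_names` (data.frame incl.
#'   propagated labels), and `config`.
#' @examples
#' fit <- orthogroups("((A_x1:1,B_y1:1)90:1,(A_x2:1,B_y2:1)80:1);",
#'                    root = "keep")
#' fit
#' membership_table(fit)
#' @export
orthogroups <- function(tree, sos = 0, inflation = 1.6, min_support = 0,
                        weighted = TRUE,
                        root = c("keep", "midpoint", "iterative"),
                        iter_n = 10L, ingroup = NULL, reference_names = NULL,
                        min_annot_support = 0, delimiter = "_",
                        species_field = 0L, unit_lengths = FALSE) {
  root <- match.arg(root)
  if (is.character(tree))
    tree <- read_gene_tree(tree, delimiter, species_field)
  else if (inherits(tree, "phylo"))
    tree <- as_gene_tree(tree, delimiter, species_field)
  stopifnot(inherits(tree, "gene_tree"))
  tree <- normalize_supports(tree)
  tree <- switch(root,
    keep = {
      if (!is_rooted(tree))
        stop("input tree is unrooted; use root = \"midpoint\" or ",
             "\"iterative\"", call. = FALSE)
      tree
    },
    midpoint = midpoint_root(tree, unit_lengths = unit_lengths),
    iterative = iterative_root(tree, n = iter_n, overlap_threshold = sos,
                               inflation = inflation,
                               min_support = min_support,
                               weighted = weighted,
                               unit_lengths = unit_lengths))
  events <- classify_events(tree, threshold = sos)
  pairs <- extract_ortholog_pairs(tree, events)
  genes <- tree$phylo$tip.label
  if (is.null(ingroup)) {
    graph <- build_graph(pairs, genes, weighted = weighted,
                         min_support = min_support)
    ogs <- assign_orthogroups(graph, inflation = inflation)
  } else {
    ogs <- restrict_to_species(pairs, genes, tree$species, ingroup,
                               inflation = inflation, weighted = weighted,
                               min_support = min_support)
  }
  og_sup <- vapply(ogs$clusters, function(m) orthogroup_support(tree, m),
                   NA_real_)
  ann <- NULL; og_names <- NULL
  if (!is.null(reference_names)) {
    dict <- if (is.character(reference_names) && is.null(names(reference_names))
                && length(reference_names) == 1L)
      read_annotation_dict(reference_names) else reference_names
    ann <- annotate_genes(tree, pairs, dict)
    direct <- name_orthogroups(ogs, dict)
    og_names <- propagate_like_labels(tree, ogs, direct,
                                      min_support = min_annot_support)
  }
  structure(list(tree = tree, events = events, pairs = pairs,
                 orthogroups = ogs, og_support = og_sup,
                 gene_annotation = ann, og_names = og_names,
                 config = list(sos = sos, inflation = inflation,
                               min_support = min_support,
                               weighted = weighted, root = root,
                               iter_n = iter_n, ingroup = ingroup,
                               min_annot_support = min_annot_support,
                               delimiter = delimiter,
                               species_field = species_field)),
            class = "orthology_fit")
}

#' @export
print.orthology_fit <- function(x, ...) {
  cat("orthology_fit\n")
  cat("  genes:       ", length(x$tree$phylo$tip.label), " (",
      length(unique(x$tree$species)), " species)\n", sep = "")
  cat("  events:      ", sum(x$events$event == "speciation"), "speciations,",
      sum(x$events$event == "duplication"), "duplications\n")
  cat("  ortholog pairs:", nrow(x$pairs), "\n")
  cat("  orthogroups: ", length(x$orthogroups$clusters),
      if (length(x$orthogroups$unassigned))
        paste0(" (+", length(x$orthogroups$unassigned), " unassigned genes)")
      else "", "\n", sep = "")
  cat("  settings: sos=", x$config$sos, ", inflation=", x$config$inflation,
      ", min_support=", x$config$min_support, ", root=", x$config$root,
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.orthology_fit <- function(object, ...) {
  mt <- membership_table(object)
  print(object)
  cat("\northogroup sizes:\n")
  print(stats::setNames(lengths(object$orthogroups$clusters),
                        names(object$orthogroups$clusters)))
  invisible(mt)
}

#' Plot the annotated gene tree
#'
#' Draws the rooted gene tree with tips colored by orthogroup; a quick
#' visual check of the clustering against the topology.
#'
#' @param x an `orthology_fit`.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot.orthology_fit <- function(x, ...) {
  phy <- x$tree$phylo
  memb <- x$orthogroups$membership[phy$tip.label]
  ogs <- names(x$orthogroups$clusters)
  cols <- grDevices::hcl.colors(max(length(ogs), 2L), "Dark 3")
  tipcol <- cols[match(memb, ogs)]
  tipcol[is.na(tipcol)] <- "grey50"
  ape::plot.phylo(phy, tip.color = tipcol, ...)
  invisible(x)
}

#' Membership table of an orthology fit
#'
#' One row per gene: orthogroup assignment, orthogroup support, gene
#' annotation (when a reference dictionary was given), annotation support
#' and the (possibly propagated) orthogroup name. Rows are sorted by
#' orthogroup then gene for reproducible output.
#'
#' @param fit an `orthology_fit`.
#' @return data.frame with columns `gene`, `orthogroup`, `og_support`,
#'   `annotation`, `annotation_support`, `og_name`.
#' @export
membership_table <- function(fit) {
  stopifnot(inherits(fit, "orthology_fit"))
  genes <- fit$tree$phylo$tip.label
  memb <- fit$orthogroups$membership
  og <- unname(memb[genes])
  og[is.na(og)] <- ""
  out <- data.frame(gene = genes, orthogroup = og,
                    og_support = unname(fit$og_support[og]),
                    stringsAsFactors = FALSE)
  if (!is.null(fit$gene_annotation)) {
    i <- match(genes, fit$gene_annotation$gene)
    out$annotation <- fit$gene_annotation$annotation[i]
    out$annotation_support <- fit$gene_annotation$annotation_support[i]
    j <- match(og, fit$og_names$orthogroup)
    out$og_name <- ifelse(is.na(j), "", fit$og_names$name[j])
  } else {
    out$annotation <- ""
    out$annotation_support <- NA_real_
    out$og_name <- ""
  }
  ogn <- suppressWarnings(as.integer(sub("^OG", "", out$orthogroup)))
  out <- out[order(is.na(ogn), ogn, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ortholog-pair table of an orthology fit
#'
#' One row per ortholog pair with the MRCA support and whether the two genes
#' ended up in the same orthogroup (they can differ after support pruning).
#'
#' @param fit an `orthology_fit`.
#' @return data.frame with columns `gene1`, `gene2`, `support`, `same_og`.
#' @export
pairs_table <- function(fit) {
  stopifnot(inherits(fit, "orthology_fit"))
  p <- fit$pairs
  memb <- fit$orthogroups$membership
  same <- !is.na(memb[p$gene1]) & !is.na(memb[p$gene2]) &
    memb[p$gene1] == memb[p$gene2]
  out <- data.frame(gene1 = p$gene1, gene2 = p$gene2, support = p$support,
                    same_og = unname(same), stringsAsFactors = FALSE)
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the pipeline's output files
#'
#' Writes `<prefix>.ortholog_pairs.tsv`, `<prefix>.ortholog_groups.tsv` and
#' `<prefix>.annotated.newick` (leaf labels suffixed with
#' `"|<orthogroup>"`; the file re-parses to the same topology). Tables are
#' deterministically sorted, so repeated runs are byte-identical.
#'
#' @param fit an `orthology_fit`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_outputs <- function(fit, prefix) {
  stopifnot(inherits(fit, "orthology_fit"))
  f_pairs <- paste0(prefix, ".ortholog_pairs.tsv")
  f_groups <- paste0(prefix, ".ortholog_groups.tsv")
  f_tree <- paste0(prefix, ".annotated.newick")
  fmt <- function(x) {
    out <- formatC(x, format = "g", digits = 6)
    out[is.na(x)] <- "NA"
    out
  }
  pt <- pairs_table(fit)
  pt$support <- fmt(pt$support)
  utils::write.table(pt, f_pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mt <- membership_table(fit)
  mt$og_support <- fmt(mt$og_support)
  mt$annotation_support <- fmt(mt$annotation_support)
  utils::write.table(mt, f_groups, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann_tree <- fit$tree
  memb <- fit$orthogroups$membership[ann_tree$phylo$tip.label]
  memb[is.na(memb)] <- "unassigned"
  ann_tree$phylo$tip.label <- paste0(ann_tree$phylo$tip.label, "|", memb)
  writeLines(write_gene_tree(ann_tree), f_tree)
  invisible(c(pairs = f_pairs, groups = f_groups, tree = f_tree))
}
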