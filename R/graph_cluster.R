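# Ortholog graph construction and Markov clustering (MCL) into orthogroups.
#
# The MCL implementation is deliberately self-contained: add self-loops,
# column-normalize to a stochastic matrix, then alternate expansion (matrix
# power) and inflation (elementwise power + renormalization) with pruning of
# tiny entries until the matrix is (numerically) idempotent; clusters are
# read from the attractor rows.

#' Build the ortholog graph
#'
#' Nodes are all leaf genes of the tree; undirected edges come from the
#' ortholog pair set. Edges whose MRCA support falls below `min_support` are
#' pruned (edges exactly at the threshold are kept; missing supports count
#' as 1, i.e. fully trusted). In weighted mode edge weights are the supports,
#' otherwise 1.
#'
#' @param pairs an `ortholog_pairs` data.frame.
#' @param genes character vector of all gene ids (isolated genes allowed).
#' @param weighted use supports as weights (default `TRUE`).
#' @param min_support prune edges with support below this value, in `[0,1]`.
#' @return object of class `ortholog_graph`: list with `adjacency` (dense
#'   symmetric named matrix), `genes`, and `n_pruned`.
#' @export
build_graph <- function(pairs, genes, weighted = TRUE, min_support = 0) {
  stopifnot(min_support >= 0, min_support <= 1)
  genes <- as.character(genes)
  adj <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
  w <- ifelse(is.na(pairs$support), 1.0, pairs$support)
  keep <- w >= min_support
  if (nrow(pairs)) {
    kp <- pairs[keep, , drop = FALSE]
    wk <- if (weighted) w[keep] else rep(1.0, sum(keep))
    adj[cbind(kp$gene1, kp$gene2)] <- wk
    adj[cbind(kp$gene2, kp$gene1)] <- wk
  }
  structure(list(adjacency = adj, genes = genes,
                 n_pruned = sum(!keep)),
            class = "ortholog_graph")
}

#' Markov clustering of a weighted graph
#'
#' Standard MCL on a symmetric non-negative adjacency matrix: self-loops of
#' `loop_value` are added, columns are normalized, then expansion (matrix
#' power) and inflation (elementwise power, renormalize) alternate, with
#' entries below `prune_cutoff` zeroed, until the sup-norm change drops below
#' `tol` or `max_iter` is reached. Clusters are read from attractor rows
#' (non-zero diagonal); attractors reaching each other are merged into one
#' attractor system, and a node attracted by several systems goes to the one
#' holding its largest steady-state mass (ties to the lowest cluster index).
#'
#' @param adjacency square symmetric non-negative matrix.
#' @param inflation inflation parameter (> 1); larger values give more, finer
#'   clusters. Default 1.6.
#' @param expansion integer matrix-power exponent, default 2.
#' @param loop_value self-loop weight added to every node, default 1.
#' @param max_iter iteration cap, default 100.
#' @param tol convergence tolerance on the max absolute change, default 1e-6.
#' @param prune_cutoff entries below this are zeroed each iteration.
#' @return integer vector of cluster ids (1-based, in order of each
#'   cluster's smallest node index), one per matrix row.
#' @export
mcl <- function(adjacency, inflation = 1.6, expansion = 2L, loop_value = 1,
                max_iter = 100L, tol = 1e-6, prune_cutoff = 1e-5) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (any(A < 0)) stop("adjacency matrix must be non-negative")
  if (inflation <= 1) stop("inflation must be > 1")
  n <- nrow(A)
  if (n == 0L) return(integer(0))
  diag(A) <- loop_value
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M
    for (e in seq_len(expansion - 1L)) M2 <- M2 %*% M
    M2 <- M2^inflation
    M2[M2 < prune_cutoff] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; clustering the last iterate")
  attractors <- which(diag(M) > 0)
  clusters <- lapply(attractors, function(i) which(M[i, ] > 0))
  # merge attractor systems: attractors appearing in each other's rows
  sys <- seq_along(attractors)
  repeat {
    changed <- FALSE
    for (a in seq_along(attractors)) for (b in seq_along(attractors)) {
      if (sys[a] != sys[b] &&
          (attractors[b] %in% clusters[[a]] ||
           attractors[a] %in% clusters[[b]])) {
        sys[sys == max(sys[a], sys[b])] <- min(sys[a], sys[b])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  usys <- sort(unique(sys))
  merged <- lapply(usys, function(s) sort(unique(unlist(clusters[sys == s]))))
  att_rows <- lapply(usys, function(s) attractors[sys == s])
  # deterministic cluster order: smallest member index
  ord <- order(vapply(merged, min, 0L))
  merged <- merged[ord]
  att_rows <- att_rows[ord]
  membership <- rep(NA_integer_, n)
  for (ci in seq_along(merged)) {
    for (v in merged[[ci]]) {
      if (is.na(membership[v])) { membership[v] <- ci; next }
      # overlap: keep the cluster holding the larger steady-state mass
      if (max(M[att_rows[[ci]], v]) > max(M[att_rows[[membership[v]]], v]))
        membership[v] <- ci
    }
  }
  # nodes never attracted (numerically lost mass): own singleton clusters
  if (anyNA(membership)) {
    nxt <- max(membership, na.rm = TRUE)
    for (v in which(is.na(membership))) { nxt <- nxt + 1L; membership[v] <- nxt }
  }
  # renumber by smallest member
  first <- tapply(seq_len(n), membership, min)
  relabel <- rank(first, ties.method = "first")
  as.integer(relabel[as.character(membership)])
}

#' Partition the ortholog graph into orthogroups
#'
#' Runs MCL on the graph adjacency. Isolated genes become singleton
#' orthogroups. Orthogroup ids are `"OG0"`, `"OG1"`, ... assigned by
#' decreasing cluster size, ties broken by the lexicographically smallest
#' member, so output is reproducible.
#'
#' @param graph an `ortholog_graph`.
#' @param inflation MCL inflation (default 1.6).
#' @param ... further arguments passed to [mcl()].
#' @return object of class `orthogroup_set`: list with `clusters` (named
#'   list of member vectors, each sorted), `membership` (named character:
#'   gene -> orthogroup id) and `unassigned` (genes outside the clustering
#'   scope; empty here, used by [restrict_to_species()]).
#' @export
assign_orthogroups <- function(graph, inflation = 1.6, ...) {
  stopifnot(inherits(graph, "ortholog_graph"))
  genes <- graph$genes
  if (length(genes) == 0L)
    return(structure(list(clusters = list(),
                          membership = stats::setNames(character(0), character(0)),
                          unassigned = character(0)),
                     class = "orthogroup_set"))
  memb <- mcl(graph$adjacency, inflation = inflation, ...)
  raw <- split(genes, memb)
  raw <- lapply(raw, sort)
  ord <- order(-lengths(raw), vapply(raw, `[`, "", 1L))
  raw <- raw[ord]
  names(raw) <- paste0("OG", seq_along(raw) - 1L)
  membership <- stats::setNames(rep(names(raw), lengths(raw)),
                                unlist(raw, use.names = FALSE))
  structure(list(clusters = raw, membership = membership[genes],
                 unassigned = character(0)),
            class = "orthogroup_set")
}

#' @export
print.orthogroup_set <- function(x, ...) {
  cat("orthogroup_set:", length(x$clusters), "orthogroups over",
      length(x$membership), "genes")
  if (length(x$unassigned)) cat(";", length(x$unassigned), "unassigned")
  cat("\n")
  k <- min(length(x$clusters), 10L)
  for (i in seq_len(k))
    cat("  ", names(x$clusters)[i], " (", length(x$clusters[[i]]), "): ",
        paste(utils::head(x$clusters[[i]], 6L), collapse = " "),
        if (length(x$clusters[[i]]) > 6L) " ..." else "", "\n", sep = "")
  if (length(x$clusters) > k) cat("  ...\n")
  invisible(x)
}

#' Statistical support of an orthogroup
#'
#' The support of the MRCA node of the orthogroup's members; `NA` for
#' singletons and for MRCAs without support (never imputed).
#'
#' @param tree a rooted `gene_tree`.
#' @param members character vector of gene ids.
#' @return support in `[0,1]` or `NA`.
#' @export
orthogroup_support <- function(tree, members) {
  stopifnot(length(members) >= 1L)
  phy <- tree$phylo
  idx <- match(members, phy$tip.label)
  if (anyNA(idx))
    stop("gene(s) not in tree: ",
         paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
  if (length(idx) == 1L) return(NA_real_)
  node_support(tree, mrca_node(phy, idx))
}

#' Cluster only an ingroup of species
#'
#' Builds the ortholog graph from pairs whose two genes both belong to
#' ingroup species, clusters it as usual, and reports outgroup genes as
#' unassigned. Restricting the orthology-calling scope this way yields more
#' granular (hierarchical) orthogroups: orthology edges running through
#' outgroup genes are ignored.
#'
#' @param pairs an `ortholog_pairs` data.frame.
#' @param genes all gene ids of the tree.
#' @param species named character vector gene -> species.
#' @param ingroup character vector of ingroup species names.
#' @param inflation MCL inflation.
#' @param weighted,min_support see [build_graph()].
#' @return an `orthogroup_set` whose `unassigned` holds the outgroup genes.
#' @export
restrict_to_species <- function(pairs, genes, species, ingroup,
                                inflation = 1.6, weighted = TRUE,
                                min_support = 0) {
  stopifnot(length(ingroup) >= 1L)
  genes <- as.character(genes)
  in_genes <- genes[species[genes] %in% ingroup]
  if (length(in_genes) == 0L) {
    warning("no genes belong to the ingroup species; all genes unassigned")
    return(structure(list(clusters = list(),
                          membership = stats::setNames(character(0), character(0)),
                          unassigned = genes),
                     class = "orthogroup_set"))
  }
  keep <- pairs$gene1 %in% in_genes & pairs$gene2 %in% in_genes
  g <- build_graph(pairs[keep, , drop = FALSE], in_genes,
                   weighted = weighted, min_support = min_support)
  ogs <- assign_orthogroups(g, inflation = inflation)
  ogs$unassigned <- setdiff(genes, in_genes)
  ogs
}
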