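# Duplication-loss simulator: evolves gene lineages down a species tree and
# returns the realized gene tree together with its true orthogroup
# partition and per-node event log, so every pipeline stage can be tested
# against known truth without external data.
#
# Model: k gene copies sit at the species-tree root. Along every species
# branch of length t each lineage accrues duplications as a Poisson process
# of rate dup_rate; each lineage present at the end of a branch survives it
# with probability exp(-loss_rate * t) (loss is resolved per branch, not at
# a mid-branch death time — the truth partition and event log are what the
# simulator is for, not waiting-time realism). At every species-tree
# speciation each surviving lineage bifurcates into both daughters. Extinct
# subtrees are pruned and unifurcations suppressed. Truth orthogroups are
# the leaf sets descending from each surviving root copy: one ancestral gene
# at the root scope = one orthogroup.

#' Simulate a gene tree with known orthogroup truth
#'
#' @param species_tree an `ape` phylo object (or NEWICK string) with branch
#'   lengths; its tip labels become the species names.
#' @param dup_rate duplication rate per unit branch length (>= 0).
#' @param loss_rate loss rate per unit branch length (>= 0).
#' @param k number of gene copies at the species-tree root (>= 1).
#' @param seed integer seed; one seed drives all randomness.
#' @param delimiter delimiter used in the generated leaf labels
#'   `<species><delimiter>g<counter>`.
#' @return object of class `sim_truth`: list with `tree` (a rooted
#'   `gene_tree`, supports absent until [assign_supports()]), `truth`
#'   (named character gene -> true orthogroup `"T1"`, `"T2"`, ...),
#'   `events` (character vector of `"speciation"`/`"duplication"` indexed
#'   by internal node number) and `extinct` (`TRUE` when nothing survived;
#'   the other fields are then empty and the caller may re-seed).
#' @examples
#' sp <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' sim <- simulate_gene_tree(sp, dup_rate = 0.3, loss_rate = 0, seed = 1)
#' sim$truth
#' @export
simulate_gene_tree <- function(species_tree, dup_rate = 0.3, loss_rate = 0,
                               k = 1L, seed = NULL, delimiter = "_") {
  if (is.character(species_tree))
    species_tree <- ape::read.tree(text = species_tree)
  stopifnot(inherits(species_tree, "phylo"), dup_rate >= 0, loss_rate >= 0,
            k >= 1L)
  if (ape::Ntip(species_tree) < 2L)
    stop("species tree must have at least 2 leaves")
  if (is.null(species_tree$edge.length))
    stop("species tree must have branch lengths")
  if (!is.null(seed)) set.seed(seed)
  sp <- ape::reorder.phylo(species_tree, "cladewise")
  kids <- node_children(sp)
  edge_len <- stats::setNames(sp$edge.length, sp$edge[, 2L])
  ntip_sp <- ape::Ntip(sp)
  counter <- 0L
  leaf_copy <- character(0)      # leaf label -> root-copy id

  # evolve one lineage from `a` time units into the branch above `sp_node`
  # (branch length t); returns list(newick fragment, stem length) or NULL
  piece <- function(sp_node, a, t, copy) {
    wait <- if (dup_rate > 0) stats::rexp(1L, dup_rate) else Inf
    if (a + wait < t) {
      left <- piece(sp_node, a + wait, t, copy)
      right <- piece(sp_node, a + wait, t, copy)
      alive <- Filter(Negate(is.null), list(left, right))
      if (length(alive) == 0L) return(NULL)
      if (length(alive) == 1L)
        return(list(frag = alive[[1L]]$frag,
                    stem = wait + alive[[1L]]$stem))
      return(list(frag = paste0("(",
                                paste(vapply(alive, frag_txt, ""),
                                      collapse = ","), ")D"),
                  stem = wait))
    }
    # reached the end of the branch: per-branch survival
    if (loss_rate > 0 && stats::runif(1L) > exp(-loss_rate * t)) return(NULL)
    at_node(sp_node, t - a, copy)
  }

  frag_txt <- function(x) paste0(x$frag, ":", format_len(x$stem))
  format_len <- function(x) formatC(x, format = "g", digits = 12)

  # the lineage arrives at species node `sp_node`; `stem` is the remaining
  # segment of the branch above it
  at_node <- function(sp_node, stem, copy) {
    if (sp_node <= ntip_sp) {
      counter <<- counter + 1L
      lab <- paste0(sp$tip.label[sp_node], delimiter, "g", counter)
      leaf_copy[lab] <<- copy
      return(list(frag = lab, stem = stem))
    }
    subs <- lapply(kids[[sp_node]], function(ch)
      piece(ch, 0, edge_len[[as.character(ch)]], copy))
    alive <- Filter(Negate(is.null), subs)
    if (length(alive) == 0L) return(NULL)
    if (length(alive) == 1L)
      return(list(frag = alive[[1L]]$frag, stem = stem + alive[[1L]]$stem))
    list(frag = paste0("(", paste(vapply(alive, frag_txt, ""),
                                  collapse = ","), ")S"),
         stem = stem)
  }

  root <- ntip_sp + 1L
  copies <- lapply(seq_len(k), function(j) at_node(root, 0, paste0("T", j)))
  alive <- Filter(Negate(is.null), copies)
  if (length(alive) == 0L || counter < 2L) {
    return(structure(list(tree = NULL, truth = character(0),
                          events = character(0), extinct = TRUE),
                     class = "sim_truth"))
  }
  # join surviving root copies pairwise (zero-length duplication ladder), so
  # the gene tree stays strictly rooted-binary at the top for any k
  while (length(alive) > 2L) {
    m <- length(alive)
    joined <- list(frag = paste0("(", frag_txt(alive[[m - 1L]]), ",",
                                 frag_txt(alive[[m]]), ")D"),
                   stem = 0)
    alive <- c(alive[seq_len(m - 2L)], list(joined))
  }
  newick <- if (length(alive) == 1L) {
    paste0(frag_txt(alive[[1L]]), ";")
  } else {
    paste0("(", paste(vapply(alive, frag_txt, ""), collapse = ","), ")D;")
  }
  phy <- ape::read.tree(text = newick)
  events <- stats::setNames(
    ifelse(phy$node.label == "S", "speciation", "duplication"),
    as.character(ape::Ntip(phy) + seq_len(phy$Nnode)))
  phy$node.label <- NULL
  gt <- as_gene_tree(phy, delimiter = delimiter, species_field = 0L)
  # renumber truth ids by first appearance in the tip order
  truth <- leaf_copy[phy$tip.label]
  truth <- stats::setNames(paste0("T", match(truth, unique(truth))),
                           names(truth))
  structure(list(tree = gt, truth = truth, events = events, extinct = FALSE),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  if (x$extinct) {
    cat("sim_truth: all lineages extinct\n")
    return(invisible(x))
  }
  cat("sim_truth:", ape::Ntip(x$tree$phylo), "genes,",
      length(unique(x$truth)), "true orthogroups,",
      sum(x$events == "duplication"), "duplication nodes\n")
  invisible(x)
}

#' Draw node supports from event-specific Beta distributions
#'
#' Emulates the statistical supports of a real inference: each internal node
#' gets a support drawn from a Beta distribution chosen by the node's true
#' event. The defaults, Beta(9, 1) for both event types (mean 0.9), mimic a
#' well-resolved tree; skewed choices (e.g. `spec_beta = c(1, 9)`) inject
#' poorly supported nodes to exercise edge pruning and annotation gating.
#'
#' @param sim a `sim_truth` from [simulate_gene_tree()].
#' @param spec_beta,dup_beta length-2 positive numeric: Beta shape
#'   parameters for speciation and duplication nodes.
#' @param seed integer seed.
#' @return the `sim_truth` with supports filled into its `tree`.
#' @export
assign_supports <- function(sim, spec_beta = c(9, 1), dup_beta = c(9, 1),
                            seed = NULL) {
  stopifnot(inherits(sim, "sim_truth"), !sim$extinct,
            all(spec_beta > 0), all(dup_beta > 0))
  if (!is.null(seed)) set.seed(seed)
  nnode <- sim$tree$phylo$Nnode
  is_dup <- unname(sim$events) == "duplication"
  sup <- numeric(nnode)
  sup[!is_dup] <- stats::rbeta(sum(!is_dup), spec_beta[1L], spec_beta[2L])
  sup[is_dup] <- stats::rbeta(sum(is_dup), dup_beta[1L], dup_beta[2L])
  sim$tree$support <- sup
  sim$tree$support_scale <- "fraction"
  sim
}

#' True orthogroup partition as a reference-family list
#'
#' Convenience accessor converting the simulator's truth vector into the
#' named-list form taken by [score_families()] and
#' [adjusted_rand_index()].
#'
#' @param sim a `sim_truth`.
#' @return named list: true orthogroup id -> gene ids.
#' @export
truth_families <- function(sim) {
  stopifnot(inherits(sim, "sim_truth"), !sim$extinct)
  split(names(sim$truth), unname(sim$truth))
}
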