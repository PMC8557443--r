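# Gene-tree container: an ape "phylo" plus per-tip species assignments and
# normalized node supports. All downstream modules operate on this object.

#' Parse a species-labeled gene tree
#'
#' Reads a NEWICK gene tree whose leaf labels carry the species as a prefix,
#' e.g. `Hsap_ENSG01` with delimiter `"_"`. Internal node labels, when
#' numeric, are interpreted as statistical supports (bootstrap percentages or
#' posterior probabilities) and normalized to `[0, 1]` (any value above 1
#' triggers division of all supports by 100). Branch lengths, supports and
#' polytomies are preserved.
#'
#' @param newick either a path to a NEWICK file or a NEWICK string
#'   (recognized by a terminal `";"`).
#' @param delimiter character separating the species prefix from the rest of
#'   the leaf label (default `"_"`).
#' @param species_field 0-based index of the last delimiter-separated field
#'   that belongs to the species name; the default `0` takes the first field.
#'   `species_field = 1` would take the first two fields, and so on.
#' @param normalize if `TRUE` (default) supports are rescaled to `[0, 1]`.
#' @return an object of class `gene_tree`: a list with elements `phylo`
#'   (the [ape::read.tree()] tree), `species` (character vector named by tip
#'   label), `support` (numeric vector of length `Nnode`, `NA` where the
#'   input had none), `delimiter`, `species_field` and `support_scale`
#'   (`"percent"`, `"fraction"` or `"none"`).
#' @details The full original leaf label (species prefix included) is kept as
#'   the gene identifier, so identifiers are globally unique across species.
#' @examples
#' gt <- read_gene_tree("((A_x1:1,B_y1:1)90:1,(A_x2:1,B_y2:1)80:1);")
#' gt$species
#' gt$support
#' @export
read_gene_tree <- function(newick, delimiter = "_", species_field = 0L,
                           normalize = TRUE) {
  stopifnot(is.character(newick), length(newick) == 1L, nzchar(delimiter))
  if (grepl(";\\s*$", newick)) {
    phy <- tryCatch(ape::read.tree(text = newick),
                    error = function(e) NULL, warning = function(w) NULL)
  } else {
    if (!file.exists(newick))
      stop("input tree file not found: ", newick, call. = FALSE)
    phy <- tryCatch(ape::read.tree(newick),
                    error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed NEWICK input (could not be parsed): ",
         substr(newick, 1L, 60L), call. = FALSE)
  as_gene_tree(phy, delimiter = delimiter, species_field = species_field,
               normalize = normalize)
}

#' Build a gene_tree from an ape phylo object
#'
#' @param phy an [ape::read.tree()] `phylo` object with species-prefixed tip
#'   labels; node labels are read as supports when numeric.
#' @inheritParams read_gene_tree
#' @return a `gene_tree` object; see [read_gene_tree()].
#' @export
as_gene_tree <- function(phy, delimiter = "_", species_field = 0L,
                         normalize = TRUE) {
  stopifnot(inherits(phy, "phylo"))
  species <- species_from_labels(phy$tip.label, delimiter, species_field)
  support <- supports_from_labels(phy$node.label, phy$Nnode)
  gt <- structure(
    list(phylo = phy, species = species, support = support,
         delimiter = delimiter, species_field = as.integer(species_field),
         support_scale = "unknown"),
    class = "gene_tree")
  if (normalize) gt <- normalize_supports(gt)
  gt
}

species_from_labels <- function(labels, delimiter, species_field) {
  parts <- strsplit(labels, delimiter, fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("leaf label(s) lacking the species delimiter '", delimiter, "': ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  k <- as.integer(species_field) + 1L
  sp <- vapply(parts, function(p) paste(p[seq_len(min(k, length(p) - 1L))],
                                        collapse = delimiter), "")
  names(sp) <- labels
  sp
}

supports_from_labels <- function(node_label, nnode) {
  if (is.null(node_label)) return(rep(NA_real_, nnode))
  s <- suppressWarnings(as.numeric(node_label))
  s[!is.na(node_label) & !nzchar(node_label)] <- NA_real_
  length(s) <- nnode
  s
}

#' Normalize node supports to the [0, 1] scale
#'
#' Auto-detects the support scale: if any support exceeds 1 the whole vector
#' is taken to be on the bootstrap percentage scale and divided by 100;
#' otherwise values are assumed to be posterior probabilities / fractions and
#' left unchanged. Missing supports stay missing: consumers (edge weighting,
#' pruning, annotation gating) treat them as 1.0, i.e. fully trusted, but
#' reports keep showing them as `NA`. Idempotent.
#'
#' @param tree a `gene_tree`.
#' @param scale `"auto"` (default), or force `"percent"` / `"fraction"`.
#' @return the tree with `support` in `[0, 1]` and `support_scale` recorded.
#' @export
normalize_supports <- function(tree, scale = c("auto", "percent", "fraction")) {
  stopifnot(inherits(tree, "gene_tree"))
  scale <- match.arg(scale)
  s <- tree$support
  present <- !is.na(s)
  if (!any(present)) {
    tree$support_scale <- "none"
    return(tree)
  }
  if (any(s[present] < 0 | s[present] > 100))
    stop("node supports outside [0, 100]: ",
         paste(s[present][s[present] < 0 | s[present] > 100], collapse = ", "),
         call. = FALSE)
  is_percent <- switch(scale,
                       auto = any(s[present] > 1),
                       percent = TRUE,
                       fraction = FALSE)
  if (is_percent) s[present] <- s[present] / 100
  tree$support <- s
  tree$support_scale <- if (is_percent) "percent" else "fraction"
  tree
}

# support of a node (internal numbering); NA for tips and unsupported nodes
node_support <- function(tree, node) {
  ntip <- ape::Ntip(tree$phylo)
  ifelse(node > ntip, tree$support[node - ntip], NA_real_)
}

# support with the "missing = fully trusted" rule applied
effective_support <- function(tree, node) {
  s <- node_support(tree, node)
  ifelse(is.na(s), 1.0, s)
}

#' @export
print.gene_tree <- function(x, ...) {
  ntip <- ape::Ntip(x$phylo)
  nsp <- length(unique(x$species))
  nsup <- sum(!is.na(x$support))
  cat("gene_tree: ", ntip, " genes from ", nsp, " species, ",
      x$phylo$Nnode, " internal nodes (", nsup, " with support, scale: ",
      x$support_scale, "), ",
      if (ape::is.rooted(x$phylo)) "rooted" else "unrooted", "\n", sep = "")
  cat("species:", paste(sort(unique(x$species)), collapse = " "), "\n")
  invisible(x)
}

#' Is the gene tree rooted?
#' @param tree a `gene_tree`.
#' @return logical.
#' @export
is_rooted <- function(tree) ape::is.rooted(tree$phylo)

#' Serialize a gene tree back to NEWICK
#'
#' Supports are written as internal node labels on the scale they were read
#' (fractions in `[0,1]` after normalization); missing supports give empty
#' labels. Branch lengths are kept to full precision.
#'
#' @param tree a `gene_tree`.
#' @param file optional path; when `NULL` the NEWICK string is returned.
#' @return NEWICK string (invisibly when written to `file`).
#' @export
write_gene_tree <- function(tree, file = NULL) {
  phy <- tree$phylo
  lab <- formatC(tree$support, format = "g", digits = 15)
  lab[is.na(tree$support)] <- ""
  phy$node.label <- lab
  txt <- ape::write.tree(phy, digits = 10)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# ---- split map: carry supports across reroots ------------------------------
# A support belongs to an unrooted bipartition of the leaf set, not to a node
# number; after rerooting we recover each internal node's support by looking
# up its bipartition. The key is the sorted leaf-label set of the side NOT
# containing an (alphabetically fixed) anchor leaf.

split_key <- function(side_labels, all_labels, anchor) {
  if (anchor %in% side_labels)
    side_labels <- setdiff(all_labels, side_labels)
  paste(sort(side_labels), collapse = "\r")
}

# map from split key -> support, for all supported internal nodes
split_support_map <- function(tree) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  labs <- phy$tip.label
  anchor <- sort(labs)[1L]
  desc <- descendant_tips(phy)
  keys <- character(0); vals <- numeric(0); direct <- logical(0)
  for (nd in (ntip + 1L):(ntip + phy$Nnode)) {
    s <- tree$support[nd - ntip]
    if (is.na(s)) next
    side <- labs[desc[[nd]]]
    k <- split_key(side, labs, anchor)
    if (!nzchar(k)) next                     # root: not a bipartition
    # both children of a binary root describe the same split; prefer the
    # node whose own clade is the keyed side
    is_direct <- !(anchor %in% side)
    i <- match(k, keys)
    if (is.na(i)) {
      keys <- c(keys, k); vals <- c(vals, s); direct <- c(direct, is_direct)
    } else if (is_direct && !direct[i]) {
      vals[i] <- s; direct[i] <- TRUE
    }
  }
  stats::setNames(vals, keys)
}

# reassign supports of `tree` (already rerooted) from a split map built on
# the pre-rooting tree
apply_split_supports <- function(tree, map) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  labs <- phy$tip.label
  anchor <- sort(labs)[1L]
  desc <- descendant_tips(phy)
  sup <- rep(NA_real_, phy$Nnode)
  for (nd in (ntip + 1L):(ntip + phy$Nnode)) {
    k <- split_key(labs[desc[[nd]]], labs, anchor)
    if (nzchar(k) && k %in% names(map)) sup[nd - ntip] <- map[[k]]
  }
  tree$support <- sup
  tree
}
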