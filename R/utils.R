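# Internal helpers shared across modules.

#' Natural (numeric-aware) sort
#'
#' Orders strings so that embedded integers compare numerically:
#' `"NKX2-2" < "NKX2-8" < "NKX2-10"`. Used wherever composite gene-family
#' names are assembled, so that output names are deterministic and read in
#' the order a biologist would write them.
#'
#' @param x character vector.
#' @return `x` sorted in natural order (unique values are NOT dropped).
#' @examples
#' natural_sort(c("OG10", "OG2", "OG1"))
#' @export
natural_sort <- function(x) {
  if (length(x) <= 1L) return(x)
  # split each string into alternating non-digit / digit runs
  chunks <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  nmax <- max(lengths(chunks))
  keys <- vector("list", 2L * nmax)
  for (i in seq_len(nmax)) {
    piece <- vapply(chunks, function(ch) if (length(ch) >= i) ch[[i]] else "", "")
    is_num <- grepl("^[0-9]+$", piece) & nzchar(piece)
    num <- suppressWarnings(as.numeric(piece))
    num[!is_num] <- -Inf                       # text runs sort before numbers
    txt <- piece
    txt[is_num] <- ""                          # numeric runs compare by value
    keys[[2L * i - 1L]] <- txt
    keys[[2L * i]] <- num
  }
  x[do.call(order, keys)]
}

# children of every node: list indexed by node number (empty for tips)
node_children <- function(phy) {
  n_all <- ape::Ntip(phy) + phy$Nnode
  out <- vector("list", n_all)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    out[[p]] <- c(out[[p]], phy$edge[i, 2L])
  }
  out
}

# parent of every node (NA for the root)
node_parent <- function(phy) {
  n_all <- ape::Ntip(phy) + phy$Nnode
  par <- rep(NA_integer_, n_all)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

# tip indices descending from every node (a tip descends from itself);
# list indexed by node number
descendant_tips <- function(phy) {
  ntip <- ape::Ntip(phy)
  n_all <- ntip + phy$Nnode
  out <- vector("list", n_all)
  for (i in seq_len(ntip)) out[[i]] <- i
  # postorder: children before parents
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    out[[p]] <- c(out[[p]], out[[po$edge[i, 2L]]])
  }
  out
}

# depth in edges from the root, for every node
node_depths <- function(phy) {
  n_all <- ape::Ntip(phy) + phy$Nnode
  dep <- rep(NA_real_, n_all)
  root <- ape::Ntip(phy) + 1L
  dep[root] <- 0
  pre <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(pre$edge)))
    dep[pre$edge[i, 2L]] <- dep[pre$edge[i, 1L]] + 1
  dep
}

# MRCA of a set of tip indices (handles singletons, unlike ape::getMRCA)
mrca_node <- function(phy, tips) {
  if (length(tips) == 1L) return(as.integer(tips))
  ape::getMRCA(phy, as.integer(tips))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
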