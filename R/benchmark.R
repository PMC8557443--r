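# Benchmarking: per-family precision/recall/F against reference families,
# size-weighted means, adjusted Rand index, and the tip-randomization
# robustness experiment.

#' Score predicted orthogroups against reference families
#'
#' Two matching modes:
#' \describe{
#'   \item{best}{each family is matched to the single orthogroup maximizing
#'     the F-score (ties: larger intersection, then smaller orthogroup, then
#'     id).}
#'   \item{majority}{the predicted set is the union of all orthogroups in
#'     which strictly more than half of the members belong to the family; a
#'     more inclusive metric that can raise recall.}
#' }
#' When the reference families cover only part of the tree (e.g. a curated
#' subset of species), pass their gene universe via `universe`: genes
#' outside it are then dropped from the predicted orthogroups before any
#' counting, so they contribute neither false positives nor majority votes.
#'
#' @param reference named list: family id -> character vector of gene ids;
#'   families must be disjoint.
#' @param ogs an `orthogroup_set`.
#' @param mode `"best"` (default) or `"majority"`.
#' @param universe optional character vector restricting the evaluation;
#'   default `NULL` scores complete orthogroups.
#' @return data.frame with one row per family: `family`, `matched`
#'   (orthogroup id(s), `"+"`-joined in majority mode), `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_score`, `size`.
#' @export
score_families <- function(reference, ogs, mode = c("best", "majority"),
                           universe = NULL) {
  mode <- match.arg(mode)
  all_ref <- unlist(reference, use.names = FALSE)
  if (anyDuplicated(all_ref))
    stop("reference families overlap: ",
         paste(utils::head(unique(all_ref[duplicated(all_ref)]), 5L),
               collapse = ", "), call. = FALSE)
  if (is.null(universe)) {
    restricted <- ogs$clusters
  } else {
    reference <- lapply(reference, intersect, universe)
    restricted <- lapply(ogs$clusters, intersect, universe)
  }
  restricted <- restricted[lengths(restricted) > 0L]
  rows <- lapply(names(reference), function(fam) {
    truth <- reference[[fam]]
    if (mode == "best") {
      if (length(restricted) == 0L) {
        pred <- character(0); matched <- ""
      } else {
        cand <- data.frame(og = names(restricted),
                           inter = vapply(restricted, function(m)
                             length(intersect(m, truth)), 0L),
                           size = lengths(restricted),
                           stringsAsFactors = FALSE)
        cand$prec <- ifelse(cand$size > 0, cand$inter / cand$size, 0)
        cand$rec <- cand$inter / length(truth)
        cand$f <- ifelse(cand$prec + cand$rec > 0,
                         2 * cand$prec * cand$rec / (cand$prec + cand$rec), 0)
        best <- cand[order(-cand$f, -cand$inter, cand$size, cand$og), ][1L, ]
        matched <- best$og
        pred <- restricted[[matched]]
      }
    } else {
      maj <- vapply(restricted, function(m)
        length(intersect(m, truth)) > length(m) / 2, NA)
      matched <- paste(names(restricted)[maj], collapse = "+")
      pred <- unique(unlist(restricted[maj], use.names = FALSE))
    }
    tp <- length(intersect(pred, truth))
    fp <- length(setdiff(pred, truth))
    fn <- length(setdiff(truth, pred))
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(family = fam, matched = matched, tp = tp, fp = fp, fn = fn,
               precision = prec, recall = rec, f_score = f,
               size = length(truth), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Family-size-weighted mean accuracy
#'
#' @param scores data.frame from [score_families()].
#' @return named numeric: `precision`, `recall`, `f_score`, each the mean
#'   over families weighted by family size.
#' @export
weighted_mean_scores <- function(scores) {
  if (nrow(scores) == 0L) stop("no family scores to average")
  w <- scores$size / sum(scores$size)
  c(precision = sum(w * scores$precision),
    recall = sum(w * scores$recall),
    f_score = sum(w * scores$f_score))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting similarity between two clusterings of the
#' same element set: 1 for identical partitions, expected 0 under random
#' labeling.
#'
#' @param p,q partitions of the same elements, given either as named
#'   membership vectors (element -> cluster label) or as lists of disjoint
#'   element vectors.
#' @return the ARI (a real number, at most 1).
#' @export
adjusted_rand_index <- function(p, q) {
  as_membership <- function(x) {
    if (is.list(x))
      x <- stats::setNames(rep(seq_along(x), lengths(x)),
                           unlist(x, use.names = FALSE))
    x
  }
  p <- as_membership(p); q <- as_membership(q)
  if (is.null(names(p)) || is.null(names(q)) ||
      !setequal(names(p), names(q)) || length(p) != length(q))
    stop("partitions must cover the same element set", call. = FALSE)
  q <- q[names(p)]
  tab <- table(p, q)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  if (n2 == 0) return(1)                       # a single element: identical
  expected <- a * b / n2
  maxidx <- (a + b) / 2
  if (maxidx == expected) return(1)            # both partitions degenerate
  (sum_ij - expected) / (maxidx - expected)
}

#' Randomize tip placements
#'
#' Corrupts a gene tree by permuting the labels of a random subset of
#' leaves: `ceiling(fraction * n)` leaves are sampled uniformly and their
#' full labels permuted uniformly among themselves. Topology, branch lengths
#' and supports are untouched, so only gene placement is degraded — the
#' probe used to study how tree errors affect orthology calls.
#'
#' @param tree a `gene_tree`.
#' @param fraction fraction of leaves to displace, in `[0, 1]`.
#' @param seed integer seed making the corruption reproducible.
#' @return the corrupted `gene_tree`.
#' @export
randomize_tips <- function(tree, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  phy <- tree$phylo
  n <- ape::Ntip(phy)
  m <- ceiling(fraction * n)
  if (m >= 1L) {
    idx <- sample.int(n, m)
    phy$tip.label[idx] <- phy$tip.label[idx][sample.int(m)]
  }
  out <- tree
  out$phylo <- phy
  out$species <- species_from_labels(phy$tip.label, tree$delimiter,
                                     tree$species_field)
  out
}
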