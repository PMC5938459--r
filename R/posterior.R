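# Weighted sets of unique topologies: the in-memory form of a Bayesian
# posterior sample of trees.  Posterior probabilities are estimated as
# empirical frequencies of topologies in the post-burn-in sample.

#' Construct a weighted tree set
#'
#' A `tree_posterior` holds pairwise-distinct topologies over one common
#' leaf set together with positive weights summing to 1.  Most users build
#' one with [build_posterior()] from a raw tree sample.
#'
#' @param trees list of `phylo` trees, pairwise distinct in shape, on one
#'   common leaf set.
#' @param weights positive numeric weights aligned with `trees`, summing
#'   to 1 (renormalized if within 1e-9).
#' @return an object of class `tree_posterior` with elements `trees`,
#'   `weights`, `keys` (canonical topology keys) and `leaves` (sorted leaf
#'   labels).
#' @export
tree_posterior <- function(trees, weights) {
  if (!length(trees)) stop("empty tree set", call. = FALSE)
  trees <- lapply(trees, as_topology)
  if (length(weights) != length(trees) || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    stop("weights must be positive, finite and aligned with trees",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1 (got ", format(sum(weights)), ")",
         call. = FALSE)
  }
  weights <- weights / sum(weights)
  leaves <- sort(trees[[1L]]$tip.label)
  check_kernel_size(length(leaves))
  keys <- vapply(trees, function(t) {
    if (!setequal(t$tip.label, leaves)) {
      stop("trees do not share one common leaf set", call. = FALSE)
    }
    topology_key(t, leaves)
  }, "")
  if (anyDuplicated(keys)) {
    stop("tree set contains shape-equal duplicates; use build_posterior()",
         call. = FALSE)
  }
  structure(list(trees = trees, weights = as.numeric(weights), keys = keys,
                 leaves = leaves),
            class = "tree_posterior")
}

#' Build a weighted tree set from a raw posterior sample
#'
#' Collapses an ordered sample of trees (e.g. a post-burn-in MCMC sample)
#' into its unique topologies, weighting each by its sample frequency.  The
#' representative tree of each topology is its first occurrence (so its
#' branch lengths, if any, are those of the first occurrence); with
#' `average_lengths = TRUE` branch lengths are instead averaged edge-wise
#' over all occurrences.
#'
#' @param trees list of `phylo` trees over one common leaf set.
#' @param average_lengths average branch lengths across occurrences of the
#'   same topology instead of keeping the first occurrence's lengths.
#' @return a [tree_posterior()].
#' @export
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,D));")
#' t2 <- ape::read.tree(text = "((A,C),(B,D));")
#' build_posterior(list(t1, t1, t2))$weights
build_posterior <- function(trees, average_lengths = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree sample", call. = FALSE)
  trees <- lapply(trees, as_topology)
  leaves <- sort(trees[[1L]]$tip.label)
  check_kernel_size(length(leaves))
  keys <- vapply(trees, function(t) {
    if (!setequal(t$tip.label, leaves)) {
      stop("trees in the sample do not share one common leaf set",
           call. = FALSE)
    }
    topology_key(t, leaves)
  }, "")
  first <- !duplicated(keys)
  ukeys <- keys[first]
  counts <- as.vector(table(factor(keys, levels = ukeys)))
  utrees <- trees[first]
  if (average_lengths && !is.null(trees[[1L]]$edge.length)) {
    utrees <- lapply(seq_along(ukeys), function(i) {
      occ <- trees[keys == ukeys[i]]
      rep_tree <- occ[[1L]]
      # edge-wise average keyed by the split below each edge
      ids <- lapply(occ, edge_split_ids, labels = leaves)
      len <- lapply(occ, function(t) t$edge.length)
      tab <- tapply(unlist(len), unlist(ids), mean)
      rep_tree$edge.length <- as.numeric(tab[edge_split_ids(rep_tree,
                                                           leaves)])
      rep_tree
    })
  }
  tree_posterior(utrees, counts / length(trees))
}

# Per-edge identifier: the normalized mask (as hex) of the leaf set below
# each edge, used to align edges of shape-equal trees.
edge_split_ids <- function(tree, labels) {
  e <- aligned_edges(tree, labels)
  n <- length(labels)
  if (n > 52L) stop("branch-length averaging supports at most 52 leaves",
                    call. = FALSE)
  nn <- max(e)
  mask <- rep(0, nn)
  # accumulate tip masks up the (arbitrary) ape ordering: process edges in
  # postorder so children are filled before parents
  tree2 <- ape::reorder.phylo(tree, "postorder")
  ep <- aligned_edges(tree2, labels)
  for (i in seq_len(nrow(ep))) {
    ch <- ep[i, 2L]
    if (ch <= n) mask[ch] <- 2^(ch - 1)
    mask[ep[i, 1L]] <- mask[ep[i, 1L]] + mask[ch]
  }
  full <- 2^n - 1
  ids <- vapply(seq_len(nrow(e)), function(i) {
    m <- mask[e[i, 2L]]
    if (m %% 2 == 1) m <- full - m
    sprintf("%.0f", m)
  }, "")
  ids
}

#' Prune a taxon from a weighted tree set a posteriori
#'
#' Removes the focal leaf (and its incident edge) from every topology,
#' suppressing the resulting degree-2 node (merged branch lengths are
#' summed when present).  Topologies that become shape-equal after pruning
#' are merged and their weights summed, so total weight is conserved.
#'
#' @param set a [tree_posterior()].
#' @param taxon leaf label to remove; the set must have at least 4 leaves.
#' @return a [tree_posterior()] on the reduced leaf set.
#' @export
prune_taxon <- function(set, taxon) {
  stopifnot(inherits(set, "tree_posterior"))
  taxon <- normalize_label(taxon)
  if (!taxon %in% set$leaves) {
    stop("taxon '", taxon, "' is not a leaf of this tree set",
         call. = FALSE)
  }
  if (length(set$leaves) < 4L) {
    stop("pruning requires at least 4 leaves so trees keep >= 3",
         call. = FALSE)
  }
  pruned <- lapply(set$trees, function(t) {
    as_topology(ape::drop.tip(t, taxon))
  })
  leaves <- setdiff(set$leaves, taxon)
  keys <- vapply(pruned, topology_key, "", labels = sort(leaves))
  first <- !duplicated(keys)
  ukeys <- keys[first]
  w <- as.vector(tapply(set$weights, factor(keys, levels = ukeys), sum))
  tree_posterior(pruned[first], w)
}

#' Credible subset of a weighted tree set
#'
#' The smallest prefix of topologies, sorted by descending weight, whose
#' cumulative weight reaches `level`.  Weight ties are broken by
#' first-seen order.  Weights in the returned set are renormalized.
#'
#' @param set a [tree_posterior()].
#' @param level coverage fraction in (0, 1].
#' @param renormalize renormalize the retained weights to sum to 1
#'   (default); otherwise an attribute `coverage` records the retained
#'   cumulative weight.
#' @return a [tree_posterior()] over the retained topologies.
#' @export
credible_set <- function(set, level, renormalize = TRUE) {
  stopifnot(inherits(set, "tree_posterior"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level > 1) {
    stop("level must be in (0, 1]", call. = FALSE)
  }
  ord <- order(-set$weights)            # stable: ties keep first-seen order
  cum <- cumsum(set$weights[ord])
  k <- which(cum >= level - 1e-12)[1L]
  if (is.na(k)) k <- length(ord)
  keep <- ord[seq_len(k)]
  w <- set$weights[keep]
  out <- tree_posterior(set$trees[keep], w / sum(w))
  attr(out, "coverage") <- sum(w)
  out
}

#' @export
print.tree_posterior <- function(x, ...) {
  cat("Weighted tree set: ", length(x$trees), " unique topolog",
      if (length(x$trees) == 1L) "y" else "ies", " on ",
      length(x$leaves), " leaves\n", sep = "")
  cat("  max weight ", format(max(x$weights), digits = 4),
      ", min weight ", format(min(x$weights), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Number of unique topologies in a tree set
#' @param set a [tree_posterior()].
#' @return integer count.
#' @export
n_topologies <- function(set) {
  stopifnot(inherits(set, "tree_posterior"))
  length(set$trees)
}
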