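# Tree-to-tree distances on a shared leaf set.  RF and branch-score are
# standard comparators (delegated to phangorn); the SPR distance, the
# maximum agreement subtree, and their ratio -- the SPR excess, the
# distance the taxon influence index is built on -- are computed by the
# package's own kernels.

#' Distance specification
#'
#' Bundles the choice of tree metric with the exact-search policy for SPR
#' distances.  The SPR distance is NP-hard, so exact values (breadth-first
#' search over the SPR graph with canonical-form deduplication) are only
#' attempted within `max_leaves`/`max_distance`/`max_states` limits; beyond
#' them a deterministic greedy upper bound is used and flagged.
#'
#' @param metric one of `"spr_excess"` (SPR distance scaled by MAST size),
#'   `"rf"` (Robinson-Foulds), `"bsd"` (branch-score), `"spr"`, `"mast"`
#'   (MAST size itself, a similarity).
#' @param spr_mode `"auto"` (exact within limits, else heuristic),
#'   `"exact"`, or `"heuristic"`.
#' @param max_leaves largest leaf count for which exact search is always
#'   attempted.
#' @param max_distance largest heuristic bound for which exact search is
#'   attempted on bigger trees.
#' @param max_states cap on stored canonical forms during the breadth-first
#'   search.
#' @return an object of class `distance_spec`.
#' @export
distance_spec <- function(metric = c("spr_excess", "rf", "bsd", "spr",
                                     "mast"),
                          spr_mode = c("auto", "exact", "heuristic"),
                          max_leaves = 10L, max_distance = 3L,
                          max_states = 200000L) {
  metric <- match.arg(metric)
  spr_mode <- match.arg(spr_mode)
  stopifnot(max_leaves >= 4L, max_distance >= 1L, max_states >= 1000L)
  structure(list(metric = metric, spr_mode = spr_mode,
                 max_leaves = as.integer(max_leaves),
                 max_distance = as.integer(max_distance),
                 max_states = as.integer(max_states)),
            class = "distance_spec")
}

# Validate a pair and return aligned edge matrices for the kernels.
pair_edges <- function(t1, t2, binary = FALSE, min_leaves = 4L) {
  t1 <- as_topology(t1)
  t2 <- as_topology(t2)
  check_same_leaves(t1, t2)
  n <- n_leaves(t1)
  if (n < min_leaves) {
    stop("distance computations need at least ", min_leaves, " leaves",
         call. = FALSE)
  }
  check_kernel_size(n)
  if (binary) {
    check_binary(t1, "SPR/MAST")
    check_binary(t2, "SPR/MAST")
  }
  labels <- sort(t1$tip.label)
  list(e1 = aligned_edges(t1, labels), e2 = aligned_edges(t2, labels),
       n = n, labels = labels)
}

#' Robinson-Foulds distance
#'
#' Number of nontrivial bipartitions present in exactly one of the two
#' trees (the symmetric-difference metric).
#'
#' @param t1,t2 `phylo` trees on the same leaf set (>= 4 leaves).
#' @return a nonnegative integer.
#' @export
#' @examples
#' rf_distance(ape::read.tree(text = "((A,B),(C,D));"),
#'             ape::read.tree(text = "((A,C),(B,D));"))
rf_distance <- function(t1, t2) {
  t1 <- as_topology(t1)
  t2 <- as_topology(t2)
  check_same_leaves(t1, t2)
  if (n_leaves(t1) < 4L) stop("RF needs at least 4 leaves", call. = FALSE)
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Branch-score distance
#'
#' Square root of the sum, over the union of the two trees' bipartitions
#' (pendant branches included), of squared branch-length differences; a
#' bipartition absent from one tree contributes its length in the other
#' against zero.
#'
#' @param t1,t2 `phylo` trees on the same leaf set, both with branch
#'   lengths.
#' @return a nonnegative real.
#' @export
branch_score_distance <- function(t1, t2) {
  t1 <- as_topology(t1)
  t2 <- as_topology(t2)
  check_same_leaves(t1, t2)
  if (is.null(t1$edge.length) || is.null(t2$edge.length)) {
    stop("branch-score distance requires branch lengths on both trees",
         call. = FALSE)
  }
  as.numeric(phangorn::KF.dist(t1, t2, check.labels = TRUE))
}

#' Maximum agreement subtree size
#'
#' The largest leaf subset on which the two (binary, unrooted) trees agree:
#' restricted to that subset, with degree-2 nodes suppressed, they are
#' shape-equal.  Computed by maximizing a rooted agreement-subtree dynamic
#' program over all choices of a shared leaf as root; any agreement subtree
#' contains some leaf, so the maximum over root leaves is the unrooted
#' optimum.
#'
#' @param t1,t2 binary `phylo` trees on the same leaf set (>= 4 leaves).
#' @return a list with `size` (integer) and `leaves` (one witness leaf
#'   subset of that size).
#' @export
mast_size <- function(t1, t2) {
  p <- pair_edges(t1, t2, binary = TRUE)
  res <- .mast_cpp(p$e1, p$e2, p$n)
  list(size = as.integer(res$size), leaves = p$labels[res$tips])
}

#' Subtree-prune-and-regraft distance
#'
#' The minimum number of SPR rearrangements turning one unrooted binary
#' tree into the other.  Exact values come from a bidirectional
#' breadth-first search over the SPR graph with canonical-form
#' deduplication; the heuristic is a deterministic greedy RF hill-climb
#' whose result is an upper bound (completed, if the climb stalls, by
#' relocating each leaf outside a maximum agreement subtree, one move per
#' leaf).
#'
#' @param t1,t2 binary `phylo` trees on the same leaf set.
#' @param spec a [distance_spec()]; its `spr_mode` and exact limits govern
#'   the search.
#' @return a list with `distance` (integer) and `exact` (`TRUE` for the
#'   exact minimum, `FALSE` for an upper bound).
#' @export
#' @examples
#' spr_distance(ape::read.tree(text = "((A,B),(C,D));"),
#'              ape::read.tree(text = "((A,C),(B,D));"))
spr_distance <- function(t1, t2, spec = distance_spec()) {
  stopifnot(inherits(spec, "distance_spec"))
  p <- pair_edges(t1, t2, binary = TRUE)
  spr_dist_core(p$e1, p$e2, p$n, spec)
}

# Kernel-level SPR distance on aligned edge matrices (validation done by
# the caller); implements the exact-within-limits policy.
spr_dist_core <- function(e1, e2, n, spec) {
  bound <- .spr_greedy_cpp(e1, e2, n)
  if (bound == 0L) return(list(distance = 0L, exact = TRUE))
  # distinct trees one greedy move apart: the bound of 1 is already minimal
  if (bound == 1L) return(list(distance = 1L, exact = TRUE))
  if (spec$spr_mode == "heuristic") {
    return(list(distance = as.integer(bound), exact = FALSE))
  }
  eligible <- n <= spec$max_leaves || bound <= spec$max_distance
  if (eligible && spec$spr_mode == "auto") {
    # predicted search work: the bidirectional frontier reaches depth
    # ceiling((bound - 1) / 2) on one side before the bound is decisive
    neighborhood <- 2 * (n - 3) * (2 * n - 7)
    eligible <- neighborhood^ceiling((bound - 1) / 2) <= spec$max_states
  }
  if (!eligible) {
    if (spec$spr_mode == "exact") {
      stop("exact SPR search is outside the configured limits (",
           n, " leaves, heuristic bound ", bound,
           "); use spr_mode = \"heuristic\" or raise the limits",
           call. = FALSE)
    }
    return(list(distance = as.integer(bound), exact = FALSE))
  }
  res <- .spr_exact_cpp(e1, e2, n, max_depth = bound,
                        max_states = spec$max_states)
  if (res$status == 0L) {
    return(list(distance = as.integer(res$distance), exact = TRUE))
  }
  if (res$status == 1L) {
    # all lengths below the bound are excluded, so the bound is the minimum
    return(list(distance = as.integer(bound), exact = TRUE))
  }
  if (spec$spr_mode == "exact") {
    stop("exact SPR search exceeded max_states = ", spec$max_states,
         "; use spr_mode = \"heuristic\" or raise the limit",
         call. = FALSE)
  }
  list(distance = as.integer(bound), exact = FALSE)
}

#' SPR excess
#'
#' The SPR distance between two trees divided by the number of taxa in
#' their maximum agreement subtree: topological disagreement measured
#' relative to the size of the tree the two topologies share.  Zero iff
#' the topologies are identical.
#'
#' @inheritParams spr_distance
#' @return a nonnegative real, with attribute `"exact"` carrying the SPR
#'   exactness flag.
#' @export
#' @examples
#' spr_excess(ape::read.tree(text = "((A,B),(C,D));"),
#'            ape::read.tree(text = "((A,C),(B,D));"))  # 1/3
spr_excess <- function(t1, t2, spec = distance_spec()) {
  d <- spr_distance(t1, t2, spec)
  m <- mast_size(t1, t2)
  structure(d$distance / m$size, exact = d$exact)
}

#' Evaluate the metric named in a distance specification
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @param spec a [distance_spec()] naming the metric.
#' @return the numeric distance (for `metric = "mast"`, the MAST size).
#' @export
tree_distance <- function(t1, t2, spec = distance_spec()) {
  stopifnot(inherits(spec, "distance_spec"))
  switch(spec$metric,
         rf = as.numeric(rf_distance(t1, t2)),
         bsd = branch_score_distance(t1, t2),
         spr = as.numeric(spr_distance(t1, t2, spec)$distance),
         mast = as.numeric(mast_size(t1, t2)$size),
         spr_excess = as.numeric(spr_excess(t1, t2, spec)))
}
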