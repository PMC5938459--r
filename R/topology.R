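# Internal topology utilities.
#
# Public-facing trees are ape "phylo" objects, handled unrooted throughout.
# For the C++ kernels every tree is re-expressed as an edge matrix whose tip
# ids follow one shared label ordering (the sorted leaf labels), so that the
# same taxon has the same integer id in both trees of a comparison.

#' @useDynLib tii, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Normalize a taxon label: trim outer whitespace, inner whitespace -> "_".
normalize_label <- function(x) {
  gsub("[ \t]+", "_", trimws(x))
}

# Coerce to an unrooted phylo with normalized labels; validates leaves.
as_topology <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("expected a 'phylo' tree object", call. = FALSE)
  }
  tree$tip.label <- normalize_label(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(tree$tip.label))) {
    stop("empty leaf label in tree", call. = FALSE)
  }
  tree <- ape::collapse.singles(tree)
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length in tree", call. = FALSE)
  }
  tree
}

n_leaves <- function(tree) length(tree$tip.label)

is_binary_unrooted <- function(tree) {
  tree$Nnode == n_leaves(tree) - 2L
}

check_same_leaves <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    only1 <- setdiff(t1$tip.label, t2$tip.label)
    only2 <- setdiff(t2$tip.label, t1$tip.label)
    stop("trees do not share the same leaf set (",
         "only in first: ", paste(only1, collapse = ","),
         "; only in second: ", paste(only2, collapse = ","), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

check_binary <- function(tree, what = "this operation") {
  if (!is_binary_unrooted(tree)) {
    stop(what, " requires binary (fully resolved) trees", call. = FALSE)
  }
  invisible(TRUE)
}

check_kernel_size <- function(n) {
  if (n > 64L) {
    stop("tree kernels support at most 64 leaves (got ", n, ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Edge matrix of `tree` with tip ids remapped onto `labels` (a sorted
# character vector defining the shared tip ordering).
aligned_edges <- function(tree, labels = sort(tree$tip.label)) {
  n <- n_leaves(tree)
  idx <- match(tree$tip.label, labels)
  if (anyNA(idx) || length(labels) != n) {
    stop("tree leaves do not match the reference label set", call. = FALSE)
  }
  e <- tree$edge
  tip <- e <= n
  e[tip] <- idx[e[tip]]
  storage.mode(e) <- "integer"
  e
}

# Canonical topology key: sorted bipartition masks, hex-encoded.  Two trees
# on the same leaf set are shape-equal iff their keys are equal.
topology_key <- function(tree, labels = sort(tree$tip.label)) {
  check_kernel_size(length(labels))
  .tree_key_cpp(aligned_edges(tree, labels), length(labels))
}

#' Test two trees for topological identity
#'
#' Two unrooted leaf-labeled trees are shape-equal when they induce the same
#' set of bipartitions of their (shared) leaf set; branch lengths are
#' ignored.
#'
#' @param t1,t2 trees of class `phylo` on the same leaf set.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,D));")
#' t2 <- ape::read.tree(text = "((C,D),(B,A));")
#' topologies_equal(t1, t2)
topologies_equal <- function(t1, t2) {
  t1 <- as_topology(t1)
  t2 <- as_topology(t2)
  check_same_leaves(t1, t2)
  labels <- sort(t1$tip.label)
  identical(topology_key(t1, labels), topology_key(t2, labels))
}

# Rebuild a phylo from an adjacency edge matrix (tips 1..ntips aligned to
# `labels`), via a newick string rooted at an arbitrary internal node.
edges_to_phylo <- function(edges, labels) {
  n <- length(labels)
  nn <- max(edges)
  nbr <- vector("list", nn)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
  }
  recurse <- function(u, parent) {
    if (u <= n) return(labels[u])
    kids <- setdiff(nbr[[u]], parent)
    paste0("(", paste(vapply(kids, recurse, "", parent = u), collapse = ","),
           ")")
  }
  root <- nbr[[1L]][1L]  # internal node adjacent to tip 1
  kids <- setdiff(nbr[[root]], 1L)
  txt <- paste0("(", labels[1L], ",",
                paste(vapply(kids, recurse, "", parent = root),
                      collapse = ","), ");")
  ape::read.tree(text = txt)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
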