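# Seeded synthetic topologies and pseudo-posteriors.  These emulate the
# objects a Bayesian tree search produces -- peaked weighted sets of
# topologies scattered a bounded number of SPR moves around a center --
# with a planted displacement structure, so recovery of known influence
# orderings is testable without running any tree inference.

#' Uniformly random unrooted binary topology
#'
#' Grows a labeled topology by sequential random edge attachment: starting
#' from the 3-leaf star, each further leaf subdivides an edge drawn
#' uniformly at random, which makes every labeled unrooted binary shape
#' equally likely.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param labels leaf labels (default `t01, t02, ...`).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a `phylo` tree without branch lengths.
#' @export
random_topology <- function(n_taxa, labels = NULL, seed = NULL) {
  if (n_taxa < 4L) stop("n_taxa must be at least 4", call. = FALSE)
  check_kernel_size(n_taxa)
  if (is.null(labels)) {
    labels <- sprintf("t%0*d", max(2L, nchar(n_taxa)), seq_len(n_taxa))
  }
  stopifnot(length(labels) == n_taxa, !anyDuplicated(labels))
  with_seed(seed, {
    edges <- rbind(c(n_taxa + 1L, 1L), c(n_taxa + 1L, 2L),
                   c(n_taxa + 1L, 3L))
    for (k in seq.int(4L, n_taxa)) {
      i <- sample.int(nrow(edges), 1L)
      v <- n_taxa + k - 2L              # new internal node
      ab <- edges[i, ]
      edges <- rbind(edges[-i, , drop = FALSE],
                     c(ab[1L], v), c(v, ab[2L]), c(v, k))
    }
    edges_to_phylo(edges, normalize_label(labels))
  })
}

#' Apply random SPR moves
#'
#' Applies `moves` subtree-prune-and-regraft rearrangements, each drawn
#' uniformly from the tree's SPR neighborhood.  Regrafting a pruned subtree
#' back onto its original position (a no-op) is never proposed, so `moves`
#' bounds the displacement meaningfully.
#'
#' @param tree a binary `phylo` tree (>= 4 leaves).
#' @param moves number of successive moves (>= 0).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a `phylo` tree on the same leaves.
#' @export
random_spr <- function(tree, moves = 1L, seed = NULL) {
  tree <- as_topology(tree)
  check_binary(tree, "random_spr")
  stopifnot(moves >= 0L)
  labels <- sort(tree$tip.label)
  check_kernel_size(length(labels))
  with_seed(seed, {
    e <- aligned_edges(tree, labels)
    for (i in seq_len(moves)) {
      nb <- .spr_neighbors_cpp(e, length(labels))
      e <- nb[[sample.int(length(nb), 1L)]]
    }
    edges_to_phylo(e, labels)
  })
}

#' Generate a pseudo-posterior around a center topology
#'
#' A weighted tree set emulating a peaked posterior sample: the center plus
#' `n_unique - 1` distinct topologies obtained by 1..`max_moves` random SPR
#' moves from the center.  Weights are drawn from a symmetric Dirichlet
#' (via normalized gamma draws) with the given concentration and sorted so
#' the center receives the largest weight; `flat = TRUE` gives uniform
#' weights instead (a stress-test option).
#'
#' @param center a binary `phylo` tree.
#' @param n_unique number of unique topologies (>= 1).
#' @param max_moves maximum SPR displacement of any member from the center.
#' @param concentration Dirichlet concentration; small values give more
#'   dispersed weights.
#' @param flat use uniform weights.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param max_tries proposal budget per requested topology before giving
#'   up.
#' @return a [tree_posterior()] whose first tree is the center.
#' @export
pseudo_posterior <- function(center, n_unique, max_moves = 2L,
                             concentration = 1, flat = FALSE, seed = NULL,
                             max_tries = 500L) {
  center <- as_topology(center)
  check_binary(center, "pseudo_posterior")
  stopifnot(n_unique >= 1L, max_moves >= 0L, concentration > 0)
  if (n_unique > 1L && max_moves < 1L) {
    stop("cannot generate ", n_unique, " distinct topologies with ",
         "max_moves = 0", call. = FALSE)
  }
  labels <- sort(center$tip.label)
  with_seed(seed, {
    trees <- list(center)
    keys <- topology_key(center, labels)
    tries <- 0L
    budget <- max_tries * n_unique
    while (length(trees) < n_unique) {
      if (tries >= budget) {
        stop("could not realize ", n_unique, " distinct topologies within ",
             budget, " proposals (got ", length(trees),
             "); raise max_moves or lower n_unique", call. = FALSE)
      }
      tries <- tries + 1L
      k <- if (max_moves == 1L) 1L else sample.int(max_moves, 1L)
      cand <- random_spr(center, moves = k)
      key <- topology_key(cand, labels)
      if (!key %in% keys) {
        trees <- c(trees, list(cand))
        keys <- c(keys, key)
      }
    }
    w <- if (flat) rep(1 / n_unique, n_unique) else {
      g <- stats::rgamma(n_unique, shape = concentration, rate = 1)
      sort(g / sum(g), decreasing = TRUE)
    }
    tree_posterior(trees, w)
  })
}

#' Planted-influence scenario
#'
#' Builds a synthetic full posterior plus one dropped-taxon posterior per
#' focal taxon, with a known influence structure: the dropped posterior for
#' taxon `i` is centered on a tree `displacement[i]` SPR moves away from
#' the pruned full center (`0` means centered on the pruned center itself),
#' so the planted displacement is the ground-truth influence ordering.
#'
#' @param n_taxa number of leaves in the base topology (>= 6).
#' @param displacement named nonnegative integer vector mapping focal taxa
#'   to their planted SPR displacement; default: every taxon, with
#'   displacements 0, 1, 2, 3 recycled over the (sorted) leaf names.
#' @param n_unique unique topologies per pseudo-posterior.
#' @param max_moves dispersion (SPR moves) of each pseudo-posterior around
#'   its center.
#' @param concentration,flat weight parameters, as in [pseudo_posterior()].
#' @param base optional base topology; random when `NULL`.
#' @param seed integer seed; the whole suite is reproducible from it.
#' @return a list with `full` (a [tree_posterior()]), `dropped` (named list
#'   of [tree_posterior()]), `truth` (the displacement vector) and `base`
#'   (the base topology).
#' @export
planted_influence_suite <- function(n_taxa, displacement = NULL,
                                    n_unique = 5L, max_moves = 2L,
                                    concentration = 1, flat = FALSE,
                                    base = NULL, seed = NULL) {
  stopifnot(n_taxa >= 6L)
  with_seed(seed, {
    if (is.null(base)) base <- random_topology(n_taxa)
    base <- as_topology(base)
    check_binary(base, "planted_influence_suite")
    leaves <- sort(base$tip.label)
    if (is.null(displacement)) {
      displacement <- stats::setNames(rep(0:3, length.out = n_taxa), leaves)
    }
    if (is.null(names(displacement)) ||
        !all(names(displacement) %in% leaves)) {
      stop("displacement must be named by leaves of the base topology",
           call. = FALSE)
    }
    stopifnot(all(displacement >= 0))
    full <- pseudo_posterior(base, n_unique, max_moves = max_moves,
                             concentration = concentration, flat = flat)
    dropped <- lapply(names(displacement), function(tx) {
      center <- ape::drop.tip(base, tx)
      k <- displacement[[tx]]
      if (k > 0) center <- random_spr(center, moves = k)
      pseudo_posterior(center, n_unique, max_moves = max_moves,
                       concentration = concentration, flat = flat)
    })
    names(dropped) <- names(displacement)
    list(full = full, dropped = dropped, truth = displacement, base = base)
  })
}

#' Random character matrix with missing data
#'
#' A synthetic standard-datatype matrix (states drawn uniformly from
#' `symbols`) with each cell independently replaced by the missing code
#' `"?"` at rate `missing_rate`.  Useful for exercising the missing-data
#' ranking and jackknife-writer plumbing.
#'
#' @param taxa taxon names (or a count, expanded to `t01, t02, ...`).
#' @param n_char number of characters.
#' @param missing_rate per-cell probability of `"?"`.
#' @param symbols observed state symbols.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a [character_matrix()].
#' @export
random_character_matrix <- function(taxa, n_char = 50L, missing_rate = 0.2,
                                    symbols = c("0", "1"), seed = NULL) {
  if (is.numeric(taxa) && length(taxa) == 1L) {
    taxa <- sprintf("t%0*d", max(2L, nchar(taxa)), seq_len(taxa))
  }
  stopifnot(length(taxa) >= 1L, n_char >= 1L,
            missing_rate >= 0, missing_rate < 1)
  with_seed(seed, {
    m <- matrix(sample(symbols, length(taxa) * n_char, replace = TRUE),
                nrow = length(taxa))
    miss <- matrix(stats::runif(length(m)) < missing_rate, nrow = nrow(m))
    m[miss] <- "?"
    rownames(m) <- taxa
    character_matrix(m)
  })
}

#' Write a planted-influence scenario as tree-sample files
#'
#' Materializes a [planted_influence_suite()] as newick tree samples
#' consumable by [read_trees()]/[build_posterior()] (and the `compute` CLI
#' subcommand): each weighted set is expanded into a sample in which every
#' topology occurs with frequency proportional to its weight.  Also writes
#' the ground-truth displacements (`truth.tsv`) and a synthetic character
#' matrix (`matrix.nex`) for the missing-data plumbing.
#'
#' @param outdir output directory (created if absent).
#' @param sample_size number of trees per written sample.
#' @inheritParams planted_influence_suite
#' @return invisibly, a list with `full` (file path), `dropped` (named
#'   paths), `truth` (path), `matrix` (path).
#' @export
simulate_influence_files <- function(outdir, n_taxa = 12L,
                                     displacement = NULL, n_unique = 5L,
                                     max_moves = 2L, concentration = 1,
                                     flat = FALSE, sample_size = 200L,
                                     seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    suite <- planted_influence_suite(n_taxa, displacement,
                                     n_unique = n_unique,
                                     max_moves = max_moves,
                                     concentration = concentration,
                                     flat = flat)
    write_sample <- function(set, path) {
      counts <- pmax(1L, round(set$weights * sample_size))
      sample <- structure(rep(set$trees, counts), class = "multiPhylo")
      ape::write.tree(sample, file = path)
      path
    }
    full_path <- write_sample(suite$full, file.path(outdir, "full.nwk"))
    dropped_paths <- vapply(names(suite$dropped), function(tx) {
      write_sample(suite$dropped[[tx]],
                   file.path(outdir, paste0("drop_", tx, ".nwk")))
    }, "")
    truth_path <- file.path(outdir, "truth.tsv")
    utils::write.table(
      data.frame(taxon = names(suite$truth),
                 displacement = as.integer(suite$truth)),
      truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
    mat <- random_character_matrix(sort(suite$full$leaves))
    mat_path <- file.path(outdir, "matrix.nex")
    write_nexus_matrix(mat, mat_path)
    invisible(list(full = full_path, dropped = dropped_paths,
                   truth = truth_path, matrix = mat_path))
  })
}
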