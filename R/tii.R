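# The taxon influence index (TII).
#
# TII(i) is the expected tree distance between the full-taxon posterior
# (with taxon i pruned a posteriori) and the posterior re-inferred with
# taxon i jackknifed out of the data:
#
#   TII(i) = E[ d(T*_i, T'_i) ] = sum_{T*, T'} w(T*) w(T') d(T*_i, T'_i)
#
# over unique topologies T* of the pruned full posterior and T' of the
# dropped-taxon posterior, weighted by their posterior probabilities.  The
# full double sum has |T*| x |T'| terms; the resampling estimator draws
# min(|T*|, |T'|) topologies without replacement from each side per
# iteration and reports the median over iterations.

# All pairwise distances between two tree sets on the same leaf set.
# Distances are memoized by unordered topology-pair key (every metric here
# is symmetric), so repeated topologies across resampling replicates or
# tree sets cost one evaluation.
distance_matrix <- function(setA, setB, spec) {
  stopifnot(inherits(setA, "tree_posterior"),
            inherits(setB, "tree_posterior"),
            inherits(spec, "distance_spec"))
  if (!identical(setA$leaves, setB$leaves)) {
    stop("tree sets are not on the same leaf set", call. = FALSE)
  }
  labels <- setA$leaves
  n <- length(labels)
  if (spec$metric %in% c("spr", "mast", "spr_excess")) {
    for (t in c(setA$trees, setB$trees)) check_binary(t, "SPR/MAST")
  }
  eA <- lapply(setA$trees, aligned_edges, labels = labels)
  eB <- lapply(setB$trees, aligned_edges, labels = labels)
  memo <- new.env(parent = emptyenv())
  D <- matrix(0, length(eA), length(eB))
  for (i in seq_along(eA)) {
    for (j in seq_along(eB)) {
      kA <- setA$keys[i]
      kB <- setB$keys[j]
      if (kA == kB && spec$metric != "bsd") {
        D[i, j] <- if (spec$metric == "mast") n else 0
        next
      }
      mk <- if (kA < kB) paste0(kA, "|", kB) else paste0(kB, "|", kA)
      hit <- memo[[mk]]
      if (!is.null(hit)) {
        D[i, j] <- hit
        next
      }
      v <- switch(spec$metric,
        rf = .rf_cpp(eA[[i]], eB[[j]], n),
        spr = spr_dist_core(eA[[i]], eB[[j]], n, spec)$distance,
        mast = .mast_cpp(eA[[i]], eB[[j]], n)$size,
        spr_excess = spr_dist_core(eA[[i]], eB[[j]], n, spec)$distance /
          .mast_cpp(eA[[i]], eB[[j]], n)$size,
        bsd = branch_score_distance(setA$trees[[i]], setB$trees[[j]]))
      memo[[mk]] <- v
      D[i, j] <- v
    }
  }
  D
}

# Shared front end: prune the focal taxon from the full posterior and
# check the dropped posterior's leaf set.
tii_prepare <- function(full, dropped, taxon, spec) {
  stopifnot(inherits(full, "tree_posterior"),
            inherits(dropped, "tree_posterior"),
            inherits(spec, "distance_spec"))
  taxon <- normalize_label(taxon)
  pruned <- prune_taxon(full, taxon)
  if (!identical(pruned$leaves, dropped$leaves)) {
    stop("dropped posterior for taxon '", taxon,
         "' is not on the full leaf set minus that taxon", call. = FALSE)
  }
  pruned
}

#' Exact taxon influence index
#'
#' The full double-sum expectation of the tree distance between the pruned
#' full posterior and the dropped-taxon posterior.  Duplicate topologies
#' created by the a posteriori pruning are merged (with weights summed)
#' before summation; the expectation is invariant to that merging.
#'
#' @param full [tree_posterior()] over the complete taxon set.
#' @param dropped [tree_posterior()] from the jackknifed analysis without
#'   `taxon`.
#' @param taxon the focal taxon (a leaf of `full`).
#' @param spec a [distance_spec()]; the index as defined uses
#'   `metric = "spr_excess"`.
#' @return a nonnegative real.
#' @export
#' @examples
#' full <- build_posterior(list(ape::read.tree(text = "((A,B),(C,(D,E)));")))
#' drop <- build_posterior(list(ape::read.tree(text = "((A,C),(B,D));")))
#' tii_exact(full, drop, "E")  # 1/3: one SPR move, MAST of 3 taxa
tii_exact <- function(full, dropped, taxon, spec = distance_spec()) {
  pruned <- tii_prepare(full, dropped, taxon, spec)
  D <- distance_matrix(pruned, dropped, spec)
  as.numeric(pruned$weights %*% D %*% dropped$weights)
}

#' Resampled taxon influence index
#'
#' The resampling estimator of the TII: per iteration,
#' `m = min(|T*|, |T'|)` topologies are drawn without replacement from each
#' posterior by successive draws proportional to the remaining posterior
#' weights; the double sum is evaluated over the drawn subsets and the
#' estimate is the median over `n_iter` iterations, with quartiles and
#' Tukey-fence outlier flags recorded.
#'
#' @inheritParams tii_exact
#' @param n_iter number of resampling iterations (default 100).
#' @param seed integer seed making the replicate list reproducible; `NULL`
#'   uses (and advances) the current RNG stream.
#' @param weighting within-replicate weighting of the drawn subsets:
#'   `"renormalized"` (the subsets' posterior weights renormalized to 1, so
#'   a whole-set draw reproduces [tii_exact()] exactly) or `"uniform"`
#'   (equal weights over draws).
#' @param m resampling depth: how many topologies are drawn from each set
#'   per iteration.  Defaults to `min(|T*|, |T'|)` and is capped at the
#'   smaller set size; smaller values trade accuracy for fewer distance
#'   evaluations.
#' @return an object of class `tii_estimate`: list with `taxon`,
#'   `replicates`, `median`, `q1`, `q3`, `outliers` (replicate indices
#'   outside the Tukey fences), `n_iter`, `seed`, `metric`.
#' @export
tii_resampled <- function(full, dropped, taxon, spec = distance_spec(),
                          n_iter = 100L, seed = NULL,
                          weighting = c("renormalized", "uniform"),
                          m = NULL) {
  weighting <- match.arg(weighting)
  if (!is.numeric(n_iter) || n_iter < 1L) {
    stop("n_iter must be a positive integer", call. = FALSE)
  }
  n_iter <- as.integer(n_iter)
  pruned <- tii_prepare(full, dropped, taxon, spec)
  D <- distance_matrix(pruned, dropped, spec)
  nA <- length(pruned$weights)
  nB <- length(dropped$weights)
  m <- if (is.null(m)) min(nA, nB) else min(as.integer(m), nA, nB)
  if (m < 1L) stop("m must be at least 1", call. = FALSE)
  reps <- with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      ia <- if (m == nA) seq_len(nA) else
        sample.int(nA, m, replace = FALSE, prob = pruned$weights)
      ib <- if (m == nB) seq_len(nB) else
        sample.int(nB, m, replace = FALSE, prob = dropped$weights)
      wa <- if (weighting == "uniform") rep(1 / m, m) else {
        w <- pruned$weights[ia]; w / sum(w)
      }
      wb <- if (weighting == "uniform") rep(1 / m, m) else {
        w <- dropped$weights[ib]; w / sum(w)
      }
      as.numeric(wa %*% D[ia, ib, drop = FALSE] %*% wb)
    }, numeric(1))
  })
  tii_estimate(normalize_label(taxon), reps, seed = seed,
               metric = spec$metric)
}

# Assemble a tii_estimate from its replicate values.
tii_estimate <- function(taxon, replicates, seed = NULL, metric = NA) {
  stopifnot(is.numeric(replicates), length(replicates) >= 1L,
            all(replicates >= 0))
  q <- stats::quantile(replicates, c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  structure(list(taxon = taxon,
                 replicates = as.numeric(replicates),
                 median = q[2L], q1 = q[1L], q3 = q[3L],
                 outliers = if (length(replicates) >= 4L)
                   flag_outliers(replicates) else integer(0),
                 n_iter = length(replicates),
                 seed = seed, metric = metric),
            class = "tii_estimate")
}

#' @export
print.tii_estimate <- function(x, ...) {
  cat(sprintf(
    "TII estimate for '%s': median %.6g (IQR %.6g-%.6g, %d replicates, %d outliers)\n",
    x$taxon, x$median, x$q1, x$q3, x$n_iter, length(x$outliers)))
  invisible(x)
}

#' Flag outlying replicate values
#'
#' Indices of values outside the Tukey fences
#' `[q1 - 1.5 IQR, q3 + 1.5 IQR]`, with quartiles by linear interpolation.
#'
#' @param replicates numeric vector of at least 4 values.
#' @return integer vector of flagged indices (possibly empty).
#' @export
flag_outliers <- function(replicates) {
  stopifnot(is.numeric(replicates), length(replicates) >= 4L)
  q <- stats::quantile(replicates, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  which(replicates < q[1L] - 1.5 * iqr | replicates > q[2L] + 1.5 * iqr)
}

#' Taxon ranking
#'
#' Taxa ordered by non-increasing score; ties broken by taxon name
#' (ascending), so the order is deterministic.
#'
#' @param taxon character vector of unique taxon names.
#' @param score numeric scores.
#' @return an object of class `taxon_ranking`: a data frame with columns
#'   `taxon`, `score`, `rank`.
#' @export
ranking <- function(taxon, score) {
  taxon <- normalize_label(as.character(taxon))
  if (anyDuplicated(taxon)) stop("duplicate taxa in ranking",
                                 call. = FALSE)
  stopifnot(length(taxon) == length(score), is.numeric(score))
  ord <- order(-score, taxon)
  structure(data.frame(taxon = taxon[ord], score = as.numeric(score[ord]),
                       rank = seq_along(taxon), stringsAsFactors = FALSE),
            class = c("taxon_ranking", "data.frame"))
}

#' Rank taxa by median TII
#'
#' @param estimates list of `tii_estimate` objects over distinct taxa.
#' @return a [ranking()] in descending order of median TII.
#' @export
rank_taxa <- function(estimates) {
  if (inherits(estimates, "taxon_influence")) estimates <- estimates$estimates
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, TRUE, "tii_estimate")))
  taxa <- vapply(estimates, `[[`, "", "taxon")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxa among TII estimates", call. = FALSE)
  }
  ranking(taxa, vapply(estimates, `[[`, 0, "median"))
}

#' Taxon influence analysis of a set of jackknifed posteriors
#'
#' The top-level estimator: computes a resampled TII for every jackknifed
#' taxon against one full-taxon posterior and ranks the taxa by median
#' influence.
#'
#' @param full [tree_posterior()] over the complete taxon set.
#' @param dropped named list of [tree_posterior()] objects, one per
#'   jackknifed taxon (names are the taxa).
#' @param spec a [distance_spec()].
#' @param n_iter,seed,weighting passed to [tii_resampled()]; the seed makes
#'   the whole analysis reproducible.
#' @param credible_level optional level in (0, 1]: restrict both posteriors
#'   to their credible sets at this level before computing.
#' @return an object of class `taxon_influence` with elements `estimates`
#'   (named list of `tii_estimate`), `ranking` (a [ranking()]), `spec`,
#'   `n_iter`, `seed`.
#' @seealso [tii_exact()], [tii_resampled()], [rank_taxa()]
#' @export
taxon_influence <- function(full, dropped, spec = distance_spec(),
                            n_iter = 100L, seed = NULL,
                            weighting = c("renormalized", "uniform"),
                            credible_level = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(full, "tree_posterior"), is.list(dropped),
            length(dropped) >= 1L)
  taxa <- names(dropped)
  if (is.null(taxa) || any(!nzchar(taxa)) || anyDuplicated(taxa)) {
    stop("'dropped' must be a list named by distinct jackknifed taxa",
         call. = FALSE)
  }
  if (!is.null(credible_level)) {
    full <- credible_set(full, credible_level)
    dropped <- lapply(dropped, credible_set, level = credible_level)
  }
  estimates <- with_seed(seed, {
    out <- vector("list", length(taxa))
    names(out) <- taxa
    for (tx in taxa) {
      out[[tx]] <- tii_resampled(full, dropped[[tx]], tx, spec = spec,
                                 n_iter = n_iter, seed = NULL,
                                 weighting = weighting)
    }
    out
  })
  structure(list(estimates = estimates, ranking = rank_taxa(estimates),
                 spec = spec, n_iter = as.integer(n_iter), seed = seed),
            class = "taxon_influence")
}

#' @export
print.taxon_influence <- function(x, ...) {
  cat("Taxon influence analysis (", x$spec$metric, " metric, ",
      x$n_iter, " resampling iterations)\n", sep = "")
  print(x$ranking)
  invisible(x)
}

#' @export
summary.taxon_influence <- function(object, ...) {
  est <- object$estimates[object$ranking$taxon]
  df <- data.frame(
    taxon = object$ranking$taxon,
    rank = object$ranking$rank,
    median = vapply(est, `[[`, 0, "median"),
    q1 = vapply(est, `[[`, 0, "q1"),
    q3 = vapply(est, `[[`, 0, "q3"),
    n_outliers = vapply(est, function(e) length(e$outliers), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  class(df) <- c("summary.taxon_influence", "data.frame")
  df
}

#' @export
plot.taxon_influence <- function(x, show_outliers = TRUE, las = 2, ...) {
  est <- x$estimates[x$ranking$taxon]
  reps <- lapply(est, `[[`, "replicates")
  graphics::boxplot(reps, names = x$ranking$taxon, las = las,
                    outline = show_outliers,
                    ylab = paste0("TII (", x$spec$metric, ")"), ...)
  invisible(x)
}

#' @export
coef.taxon_influence <- function(object, ...) {
  stats::setNames(vapply(object$estimates, `[[`, 0, "median"),
                  names(object$estimates))
}
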