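# Comparing taxon rankings: rank-biased overlap (RBO) with a permutation
# test, the missing-data ranking of a character matrix, and the regression
# of TII on missing-data proportion.

#' Rank-biased overlap of two conjoint rankings
#'
#' Top-weighted similarity between two full rankings of the same taxon
#' set: with prefix overlap `A_d` (the proportion of shared taxa among the
#' two top-d prefixes), the extrapolated RBO at persistence `p` over lists
#' of length `n` is
#' `(1 - p) * sum_{d=1..n} p^(d-1) A_d + p^n * A_n`
#' (and `A_n = 1` for conjoint lists).  The persistence parameter sets how
#' top-weighted the comparison is: small `p` looks mostly at the heads of
#' the lists.
#'
#' @param a,b [ranking()] objects over the same taxon set.
#' @param persistence `p`, in (0, 1); default 0.9.
#' @return a real in `[0, 1]`; 1 iff the rankings are identical.
#' @export
#' @examples
#' r1 <- ranking(c("A", "B", "C"), c(3, 2, 1))
#' r2 <- ranking(c("A", "B", "C"), c(3, 1, 2))
#' rbo(r1, r2)
rbo <- function(a, b, persistence = 0.9) {
  stopifnot(inherits(a, "taxon_ranking"), inherits(b, "taxon_ranking"))
  if (!is.numeric(persistence) || length(persistence) != 1L ||
      persistence <= 0 || persistence >= 1) {
    stop("persistence must be in (0, 1)", call. = FALSE)
  }
  if (!setequal(a$taxon, b$taxon)) {
    stop("rankings are over different taxon sets", call. = FALSE)
  }
  rbo_order(a$taxon, b$taxon, persistence)
}

# RBO on two permutations of one item set (internal; used by the
# permutation test so the null permutes orders, not ranking objects).
rbo_order <- function(la, lb, p) {
  n <- length(la)
  pos_b <- match(la, lb)      # position in b of a's d-th item
  pos_a <- match(lb, la)      # position in a of b's d-th item
  overlap <- 0L
  a_d <- numeric(n)
  # incremental prefix overlap: going from depth d-1 to d, the two new
  # items are a[d] and b[d]; a[d] joins the intersection if it sits within
  # b's top-d, b[d] if it sits within a's top-(d-1) (a[d] == b[d] is then
  # counted exactly once)
  for (d in seq_len(n)) {
    if (pos_b[d] <= d) overlap <- overlap + 1L
    if (pos_a[d] < d) overlap <- overlap + 1L
    a_d[d] <- overlap / d
  }
  (1 - p) * sum(p^(seq_len(n) - 1L) * a_d) + p^n * a_d[n]
}

#' Permutation test for rank-biased overlap
#'
#' Tests the observed RBO against the null hypothesis of dissimilar
#' (exchangeable) rankings: the null distribution is built by uniformly
#' random permutations of the second ranking's order, and the one-sided
#' p-value uses the add-one rule
#' `(1 + #(null RBO >= observed)) / (n_permutations + 1)`, so it is never
#' smaller than `1 / (n_permutations + 1)`.
#'
#' @inheritParams rbo
#' @param n_permutations number of random permutations (default 9999).
#' @param seed integer seed for reproducibility; `NULL` uses the current
#'   RNG stream.
#' @return an object of class `rbo_test`: list with `rbo`, `persistence`,
#'   `p_value`, `n_permutations`, `seed`, `null` (the null RBO values).
#' @export
rbo_permutation_test <- function(a, b, persistence = 0.9,
                                 n_permutations = 9999L, seed = NULL) {
  stopifnot(n_permutations >= 1L)
  observed <- rbo(a, b, persistence)
  la <- a$taxon
  lb <- b$taxon
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      rbo_order(la, sample(lb), persistence)
    }, numeric(1))
  })
  p_value <- (1 + sum(null >= observed - 1e-12)) / (n_permutations + 1)
  structure(list(rbo = observed, persistence = persistence,
                 p_value = p_value,
                 n_permutations = as.integer(n_permutations),
                 seed = seed, null = null),
            class = "rbo_test")
}

#' @export
print.rbo_test <- function(x, ...) {
  cat(sprintf("Rank-biased overlap: rbo = %.4g (p = %.4g, persistence %.3g, %d permutations)\n",
              x$rbo, x$p_value, x$persistence, x$n_permutations))
  invisible(x)
}

#' Rank taxa by proportion of missing data
#'
#' Per-taxon score is the proportion of missing (`"?"`) symbols among its
#' characters; the gap/inapplicable symbol `"-"` is not counted as missing
#' unless added to `missing_symbols`.  Taxa are ranked in descending order
#' of missingness.
#'
#' @param matrix a [character_matrix()].
#' @param missing_symbols symbols counted as missing (default `"?"`).
#' @return a [ranking()].
#' @export
missing_proportion_ranking <- function(matrix, missing_symbols = "?") {
  stopifnot(inherits(matrix, "character_matrix"), nrow(matrix) >= 1L)
  miss <- array(as.vector(matrix) %in% missing_symbols, dim = dim(matrix))
  score <- rowMeans(miss)
  ranking(rownames(matrix), score)
}

#' Regress taxon influence on missing-data proportion
#'
#' Ordinary least squares of median TII on the per-taxon proportion of
#' missing characters, reporting the coefficient of determination and the
#' two-sided p-value of the slope test.
#'
#' @param estimates list of `tii_estimate` objects (or a `taxon_influence`
#'   fit) whose taxa all appear in `matrix`; at least 3 taxa.
#' @param matrix a [character_matrix()].
#' @param missing_symbols symbols counted as missing (default `"?"`).
#' @return a list with `r_squared`, `p_value`, and `fit` (the underlying
#'   `lm` object).
#' @export
fit_tii_vs_missing <- function(estimates, matrix, missing_symbols = "?") {
  if (inherits(estimates, "taxon_influence")) estimates <- estimates$estimates
  stopifnot(inherits(matrix, "character_matrix"),
            all(vapply(estimates, inherits, TRUE, "tii_estimate")))
  taxa <- vapply(estimates, `[[`, "", "taxon")
  if (length(taxa) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (!all(taxa %in% rownames(matrix))) {
    stop("estimates include taxa absent from the matrix: ",
         paste(setdiff(taxa, rownames(matrix)), collapse = ", "),
         call. = FALSE)
  }
  mr <- missing_proportion_ranking(matrix, missing_symbols)
  x <- mr$score[match(taxa, mr$taxon)]
  y <- vapply(estimates, `[[`, 0, "median")
  if (stats::var(x) == 0) {
    stop("degenerate fit: no variance in missing-data proportions",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(r_squared = unname(sm$r.squared),
       p_value = unname(stats::coef(sm)[2L, 4L]),
       fit = fit)
}
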