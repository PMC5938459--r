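test_that("exact TII reproduces the worked double-sum values", {
  full <- full_five()
  # pruned full tree equals the dropped tree: zero influence
  expect_equal(tii_exact(full, build_posterior(list(quartet_ab())), "E"), 0)
  # single cross pair at SPR 1 with MAST 3
  expect_equal(tii_exact(full, build_posterior(list(quartet_ac())), "E"),
               1 / 3)
  # two-term sum 0.6 * 0 + 0.4 * (1/3)
  mix <- tree_posterior(list(quartet_ab(), quartet_ac()), c(0.6, 0.4))
  expect_equal(tii_exact(full, mix, "E"), 0.4 / 3)

  expect_error(tii_exact(full, build_posterior(list(quartet_ab())), "Z"),
               "not a leaf")
  wrong <- build_posterior(list(tree_of("((A,B),(C,Q));")))
  expect_error(tii_exact(full, wrong, "E"), "leaf set")
})

test_that("exact TII is invariant to splitting duplicate topologies", {
  full <- pseudo_posterior(random_topology(7, seed = 1), 4, max_moves = 2,
                           seed = 5)
  dropped <- pseudo_posterior(ape::drop.tip(full$trees[[1]], "t03"), 3,
                              max_moves = 1, seed = 6)
  v <- tii_exact(full, dropped, "t03")
  # split the heaviest dropped topology into two equal-weight copies; the
  # constructor forbids duplicates, so emulate the split via the double sum
  pruned <- prune_taxon(full, "t03")
  D <- tii:::distance_matrix(pruned, dropped, distance_spec())
  w_split <- c(dropped$weights[1] / 2, dropped$weights[1] / 2,
               dropped$weights[-1])
  D_split <- D[, c(1L, seq_len(ncol(D))), drop = FALSE]
  expect_equal(as.numeric(pruned$weights %*% D_split %*% w_split), v)
})

test_that("TII is zero iff all weighted cross pairs share one shape", {
  base <- random_topology(8, seed = 42)
  full <- build_posterior(list(base))
  dropped <- build_posterior(list(ape::drop.tip(base, "t05")))
  expect_equal(tii_exact(full, dropped, "t05"), 0)
  moved <- build_posterior(list(random_spr(ape::drop.tip(base, "t05"), 2,
                                           seed = 3)))
  if (!topologies_equal(moved$trees[[1]], dropped$trees[[1]])) {
    expect_gt(tii_exact(full, moved, "t05"), 0)
  }
})

test_that("TII grows with planted displacement for point-mass posteriors", {
  base <- random_topology(10, seed = 7)
  full <- build_posterior(list(base))
  pruned_center <- ape::drop.tip(base, "t02")
  spec <- distance_spec(spr_mode = "exact")
  # build targets at verified exact SPR distances 0..3 from the center
  targets <- list(pruned_center)
  k <- 1L
  seed <- 0L
  while (length(targets) < 4L) {
    seed <- seed + 1L
    cand <- random_spr(pruned_center, k, seed = 1000 + seed)
    if (spr_distance(pruned_center, cand, spec)$distance == k) {
      targets <- c(targets, list(cand))
      k <- k + 1L
    }
  }
  vals <- vapply(targets, function(tt) {
    tii_exact(full, build_posterior(list(tt)), "t02", spec)
  }, numeric(1))
  expect_equal(vals[1], 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("whole-set resampling reproduces the exact TII with zero spread", {
  full <- pseudo_posterior(random_topology(7, seed = 3), 5, max_moves = 2,
                           seed = 11)
  dropped <- pseudo_posterior(ape::drop.tip(full$trees[[1]], "t06"), 5,
                              max_moves = 2, seed = 12)
  pruned_n <- n_topologies(prune_taxon(full, "t06"))
  exact <- tii_exact(full, dropped, "t06")
  est <- tii_resampled(full, dropped, "t06", n_iter = 20, seed = 1)
  if (pruned_n >= n_topologies(dropped) ||
      pruned_n == n_topologies(full)) {
    # when m equals both set sizes every replicate is the exact value
    if (min(pruned_n, n_topologies(dropped)) ==
        max(pruned_n, n_topologies(dropped))) {
      expect_equal(est$replicates, rep(exact, 20))
      expect_equal(est$q3 - est$q1, 0)
    }
  }
  # degenerate point masses: every replicate equals the one distance
  pm_full <- build_posterior(list(full$trees[[1]]))
  pm_drop <- build_posterior(list(dropped$trees[[1]]))
  pm <- tii_resampled(pm_full, pm_drop, "t06", n_iter = 10, seed = 2)
  expect_equal(pm$replicates, rep(tii_exact(pm_full, pm_drop, "t06"), 10))
})

test_that("resampling is bit-reproducible from its seed", {
  full <- pseudo_posterior(random_topology(8, seed = 5), 6, max_moves = 2,
                           seed = 21)
  dropped <- pseudo_posterior(ape::drop.tip(full$trees[[1]], "t04"), 4,
                              max_moves = 2, seed = 22)
  a <- tii_resampled(full, dropped, "t04", n_iter = 25, seed = 99)
  b <- tii_resampled(full, dropped, "t04", n_iter = 25, seed = 99)
  expect_identical(a$replicates, b$replicates)
  c <- tii_resampled(full, dropped, "t04", n_iter = 25, seed = 100)
  expect_false(identical(a$replicates, c$replicates))
})

test_that("uniform within-replicate weighting is exposed and differs", {
  full <- pseudo_posterior(random_topology(7, seed = 6), 5, max_moves = 2,
                           seed = 31)
  dropped <- pseudo_posterior(ape::drop.tip(full$trees[[1]], "t01"), 3,
                              max_moves = 2, seed = 32)
  r <- tii_resampled(full, dropped, "t01", n_iter = 15, seed = 7)
  u <- tii_resampled(full, dropped, "t01", n_iter = 15, seed = 7,
                     weighting = "uniform")
  expect_s3_class(u, "tii_estimate")
  expect_false(identical(r$replicates, u$replicates))
})

test_that("Tukey fences flag extreme replicates", {
  expect_length(flag_outliers(rep(2, 10)), 0L)
  x <- c(rep(1, 9), 100)
  expect_equal(flag_outliers(x), 10L)
  # flags are a set of values, invariant to ordering
  perm <- c(10, 1:9)
  expect_equal(sort(x[flag_outliers(x)]), sort(x[perm][flag_outliers(x[perm])]))
  expect_error(flag_outliers(c(1, 2, 3)), "4")
})

test_that("taxa rank by descending median with lexicographic ties", {
  est <- list(tii_estimate("X", rep(0.3, 5)),
              tii_estimate("Y", rep(0.1, 5)),
              tii_estimate("Z", rep(0.2, 5)))
  r <- rank_taxa(est)
  expect_equal(r$taxon, c("X", "Z", "Y"))
  expect_equal(r$rank, 1:3)

  tie <- list(tii_estimate("X", rep(0.2, 4)), tii_estimate("A", rep(0.2, 4)))
  expect_equal(rank_taxa(tie)$taxon, c("A", "X"))

  single <- rank_taxa(list(tii_estimate("solo", rep(0.5, 4))))
  expect_equal(single$rank, 1L)

  expect_error(rank_taxa(list(tii_estimate("X", 1:5), tii_estimate("X", 1:5))),
               "duplicate")
})

test_that("taxon_influence fits, summarises and plots", {
  suite <- planted_influence_suite(8, n_unique = 3, max_moves = 1,
                                   seed = 15)
  fit <- taxon_influence(suite$full, suite$dropped, n_iter = 10, seed = 4)
  expect_s3_class(fit, "taxon_influence")
  expect_setequal(fit$ranking$taxon, names(suite$dropped))
  expect_equal(unname(coef(fit)[fit$ranking$taxon[1]]),
               max(fit$ranking$score))
  sm <- summary(fit)
  expect_equal(sm$rank, seq_len(nrow(sm)))
  expect_true(all(sm$q1 <= sm$median & sm$median <= sm$q3))
  expect_output(print(fit), "Taxon influence")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))

  # whole-analysis reproducibility from one seed
  fit2 <- taxon_influence(suite$full, suite$dropped, n_iter = 10, seed = 4)
  expect_identical(coef(fit), coef(fit2))
})

test_that("estimates round-trip through the JSON exchange format", {
  suite <- planted_influence_suite(7, n_unique = 2, max_moves = 1, seed = 8)
  fit <- taxon_influence(suite$full, suite$dropped, n_iter = 8, seed = 2)
  path <- tempfile(fileext = ".json")
  write_estimates_json(fit, path, provenance = list(run = "test"))
  back <- read_estimates_json(path)
  expect_setequal(names(back), names(fit$estimates))
  for (tx in names(back)) {
    expect_equal(back[[tx]]$replicates, fit$estimates[[tx]]$replicates)
    expect_equal(back[[tx]]$median, fit$estimates[[tx]]$median)
  }
})
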