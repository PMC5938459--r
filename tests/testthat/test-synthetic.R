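test_that("random topologies are valid, seeded and quartet-complete", {
  tr <- random_topology(9, seed = 1)
  expect_length(tr$tip.label, 9L)
  expect_equal(tr$Nnode, 7L)   # unrooted binary
  expect_true(topologies_equal(tr, random_topology(9, seed = 1)))
  expect_false(topologies_equal(tr, random_topology(9, seed = 2)))
  expect_error(random_topology(3), "at least 4")

  # n = 4 always lands on one of the three quartet shapes, and sequential
  # edge attachment reaches all of them
  shapes <- vapply(1:60, function(i) {
    q <- random_topology(4, labels = c("A", "B", "C", "D"), seed = i)
    which(c(topologies_equal(q, quartet_ab()),
            topologies_equal(q, quartet_ac()),
            topologies_equal(q, quartet_ad())))
  }, integer(1))
  expect_setequal(unique(shapes), 1:3)
})

test_that("random SPR moves are seeded and never no-ops at one step", {
  t0 <- random_topology(8, seed = 3)
  m1 <- random_spr(t0, 1, seed = 10)
  expect_true(topologies_equal(m1, random_spr(t0, 1, seed = 10)))
  expect_setequal(m1$tip.label, t0$tip.label)
  # excluding regraft-to-origin means one move always changes the shape
  for (s in 1:10) {
    expect_false(topologies_equal(t0, random_spr(t0, 1, seed = s)))
  }
  expect_true(topologies_equal(t0, random_spr(t0, 0, seed = 1)))
})

test_that("pseudo-posteriors respect displacement, weights and seeding", {
  center <- random_topology(8, seed = 4)
  pp <- pseudo_posterior(center, 7, max_moves = 2, seed = 6)
  expect_equal(n_topologies(pp), 7L)
  expect_equal(sum(pp$weights), 1, tolerance = 1e-12)
  expect_true(topologies_equal(pp$trees[[1]], center))
  expect_equal(pp$weights[1], max(pp$weights))  # center carries the mode

  # every member within max_moves exact SPR moves of the center
  spec <- distance_spec(spr_mode = "exact")
  for (t in pp$trees) {
    expect_lte(spr_distance(center, t, spec)$distance, 2L)
  }

  pp2 <- pseudo_posterior(center, 7, max_moves = 2, seed = 6)
  expect_identical(pp$keys, pp2$keys)
  expect_identical(pp$weights, pp2$weights)

  expect_equal(n_topologies(pseudo_posterior(center, 1)), 1L)
  flat <- pseudo_posterior(center, 4, max_moves = 2, flat = TRUE, seed = 1)
  expect_equal(flat$weights, rep(0.25, 4))

  # unrealizable requests fail loudly: a quartet has only 3 shapes
  expect_error(pseudo_posterior(random_topology(4, seed = 1), 10,
                                max_moves = 1, max_tries = 20),
               "distinct topologies")
  expect_error(pseudo_posterior(center, 5, max_moves = 0), "max_moves")
})

test_that("planted scenarios record their displacement ground truth", {
  suite <- planted_influence_suite(9, displacement = c(t01 = 0, t04 = 2,
                                                       t07 = 3),
                                   n_unique = 3, max_moves = 1, seed = 20)
  expect_setequal(names(suite$dropped), c("t01", "t04", "t07"))
  expect_equal(suite$truth[["t04"]], 2)
  for (tx in names(suite$dropped)) {
    expect_setequal(suite$dropped[[tx]]$leaves,
                    setdiff(suite$full$leaves, tx))
  }
  # zero displacement with point masses gives zero influence
  pm <- planted_influence_suite(8, displacement = c(t03 = 0), n_unique = 1,
                                seed = 21)
  expect_equal(tii_exact(pm$full, pm$dropped[["t03"]], "t03"), 0)

  again <- planted_influence_suite(9, displacement = c(t01 = 0, t04 = 2,
                                                       t07 = 3),
                                   n_unique = 3, max_moves = 1, seed = 20)
  expect_identical(suite$full$keys, again$full$keys)
  expect_identical(lapply(suite$dropped, `[[`, "keys"),
                   lapply(again$dropped, `[[`, "keys"))
})

test_that("displacement ordering shows up in point-mass TII medians", {
  suite <- planted_influence_suite(10, displacement = c(t02 = 0, t05 = 1,
                                                        t08 = 3),
                                   n_unique = 1, seed = 33)
  spec <- distance_spec()
  v <- vapply(names(suite$dropped), function(tx) {
    tii_exact(suite$full, suite$dropped[[tx]], tx, spec)
  }, numeric(1))
  expect_equal(unname(v[["t02"]]), 0)
  expect_gte(v[["t08"]], v[["t02"]])
})

test_that("random character matrices honour their missingness rate", {
  m <- random_character_matrix(10, n_char = 200, missing_rate = 0.3,
                               seed = 2)
  expect_equal(dim(m), c(10L, 200L))
  rate <- mean(m == "?")
  expect_gt(rate, 0.25)
  expect_lt(rate, 0.35)
  m2 <- random_character_matrix(10, n_char = 200, missing_rate = 0.3,
                                seed = 2)
  expect_identical(unclass(m), unclass(m2))
})

test_that("simulated scenario files are consumable by the readers", {
  outdir <- tempfile()
  paths <- simulate_influence_files(outdir, n_taxa = 7, n_unique = 3,
                                    max_moves = 1, sample_size = 60,
                                    seed = 12)
  full <- build_posterior(read_trees(paths$full))
  expect_equal(length(full$leaves), 7L)
  expect_length(paths$dropped, 7L)
  one <- build_posterior(read_trees(paths$dropped[[1]]))
  expect_equal(length(one$leaves), 6L)
  truth <- utils::read.delim(paths$truth)
  expect_setequal(truth$taxon, full$leaves)
  mat <- read_character_matrix(paths$matrix)
  expect_setequal(rownames(mat), full$leaves)
})
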