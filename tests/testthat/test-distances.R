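test_that("RF distance matches quartet hand values and enumeration", {
  expect_equal(rf_distance(quartet_ab(), quartet_ab()), 0L)
  expect_equal(rf_distance(quartet_ab(), quartet_ac()), 2L)
  for (seed in 1:15) {
    p <- random_pair(sample(6:8, 1), seed = 400 + seed)
    expect_equal(rf_distance(p$t1, p$t2), rf_oracle(p$t1, p$t2))
    expect_equal(rf_distance(p$t1, p$t2), rf_distance(p$t2, p$t1))
  }
  expect_error(rf_distance(quartet_ab(), tree_of("((A,B),(C,E));")),
               "leaf set")
})

test_that("branch-score distance follows the length-difference definition", {
  ta <- tree_of("((A:1,B:2):0.1,(C:1,D:1):0.2);")
  expect_equal(branch_score_distance(ta, ta), 0)
  tb <- tree_of("((A:1,B:2):0.3,(C:1,D:1):0.2);")
  expect_equal(branch_score_distance(ta, tb), 0.2)
  # homogeneity: scaling all lengths scales the distance
  ta2 <- ta; ta2$edge.length <- ta$edge.length * 3
  tb2 <- tb; tb2$edge.length <- tb$edge.length * 3
  expect_equal(branch_score_distance(ta2, tb2),
               3 * branch_score_distance(ta, tb))
  expect_error(branch_score_distance(ta, quartet_ab()), "branch length")
})

test_that("MAST size matches the exhaustive-subset oracle with a valid witness", {
  expect_equal(mast_size(quartet_ab(), quartet_ab())$size, 4L)
  expect_equal(mast_size(quartet_ab(), quartet_ac())$size, 3L)
  for (seed in 1:12) {
    p <- random_pair(7, seed = 500 + seed)
    m <- mast_size(p$t1, p$t2)
    expect_equal(m$size, mast_oracle(p$t1, p$t2))
    expect_length(m$leaves, m$size)
    r1 <- ape::unroot(ape::keep.tip(p$t1, m$leaves))
    r2 <- ape::unroot(ape::keep.tip(p$t2, m$leaves))
    expect_equal(phangorn::RF.dist(r1, r2), 0)
  }
  poly <- tree_of("((A,B),(C,D,E));")
  expect_error(mast_size(poly, poly), "binary")
})

test_that("exact SPR agrees with quartet search and obeys metric axioms", {
  expect_equal(spr_distance(quartet_ab(), quartet_ab()),
               list(distance = 0L, exact = TRUE))
  d <- spr_distance(quartet_ab(), quartet_ac())
  expect_equal(d$distance, 1L)
  expect_true(d$exact)

  for (seed in 1:8) {
    n <- sample(6:8, 1)
    p <- random_pair(n, seed = 600 + seed)
    d12 <- spr_distance(p$t1, p$t2)
    d21 <- spr_distance(p$t2, p$t1)
    expect_true(d12$exact && d21$exact)
    expect_equal(d12$distance, d21$distance)
    h <- spr_distance(p$t1, p$t2,
                      distance_spec(spr_mode = "heuristic"))
    expect_gte(h$distance, d12$distance)
    # triangle inequality through a third random tree
    t3 <- random_topology(n, labels = sort(p$t1$tip.label),
                          seed = 700 + seed)
    expect_lte(d12$distance,
               spr_distance(p$t1, t3)$distance +
                 spr_distance(t3, p$t2)$distance)
  }
})

test_that("one applied SPR move is at exact distance at most 1", {
  for (seed in 1:10) {
    t0 <- random_topology(8, seed = 800 + seed)
    t1 <- random_spr(t0, 1, seed = 900 + seed)
    d <- spr_distance(t0, t1)
    expect_true(d$exact)
    expect_lte(d$distance, 1L)
    if (!topologies_equal(t0, t1)) expect_equal(d$distance, 1L)
  }
})

test_that("exact mode refuses searches beyond its configured limits", {
  p <- random_pair(14, seed = 77)
  tight <- distance_spec(spr_mode = "exact", max_leaves = 6,
                         max_distance = 1, max_states = 1000)
  if (spr_distance(p$t1, p$t2,
                   distance_spec(spr_mode = "heuristic"))$distance > 1) {
    expect_error(spr_distance(p$t1, p$t2, tight), "limits")
  }
  # auto mode falls back to a flagged bound instead
  loose <- distance_spec(spr_mode = "auto", max_leaves = 6,
                         max_distance = 1, max_states = 1000)
  res <- spr_distance(p$t1, p$t2, loose)
  expect_type(res$exact, "logical")
})

test_that("SPR excess is distance over MAST size and label-permutation invariant", {
  expect_equal(as.numeric(spr_excess(quartet_ab(), quartet_ab())), 0)
  expect_equal(as.numeric(spr_excess(quartet_ab(), quartet_ac())), 1 / 3)

  for (seed in 1:6) {
    p <- random_pair(7, seed = 950 + seed)
    v <- as.numeric(spr_excess(p$t1, p$t2))
    expect_gte(v, 0)
    expect_equal(v > 0, !topologies_equal(p$t1, p$t2))
    # permute the labels of both trees identically
    perm <- sample(p$t1$tip.label)
    relab <- function(t) {
      t$tip.label <- perm[match(t$tip.label, sort(t$tip.label))]
      t
    }
    expect_equal(as.numeric(spr_excess(relab(p$t1), relab(p$t2))), v)
  }
})

test_that("tree_distance dispatches on the metric in the spec", {
  t1 <- quartet_ab()
  t2 <- quartet_ac()
  expect_equal(tree_distance(t1, t2, distance_spec("rf")), 2)
  expect_equal(tree_distance(t1, t2, distance_spec("spr")), 1)
  expect_equal(tree_distance(t1, t2, distance_spec("mast")), 3)
  expect_equal(tree_distance(t1, t2, distance_spec("spr_excess")), 1 / 3)
})
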