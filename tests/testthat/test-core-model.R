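# Domain types: forest scoring, Boltzmann factors, structural validation.

test_that("forest scores count charged gains and breaks", {
  # score-0 forest: unique scenario of the single-adjacency instance
  f0 <- backtrack_optimal(compute_tables(fixture1()))
  expect_identical(f0$gains, 0L)
  expect_identical(f0$breaks, 0L)
  expect_equal(score_forest(f0), 0)

  # fixture2's suboptimal forest gains both extant adjacencies independently
  sp2 <- enumerate_forests(fixture2())
  expect_setequal(sp2$scores, c(0, 2))
  f2 <- sp2$forests[[which(sp2$scores == 2)]]
  expect_identical(f2$gains, 2L)
  expect_equal(score_forest(f2), 2)
  expect_equal(score_forest(f2, cost_params(AG = 0.5, AB = 1)), 1)

  # figure-style instance: the parsimonious forest charges exactly one gain
  # (no gain is charged for presence at the instance root pair)
  fig <- figure_instance()
  ff <- backtrack_optimal(compute_tables(fig))
  expect_identical(ff$gains, 1L)
  expect_identical(ff$breaks, 0L)
  expect_equal(score_forest(ff), min(enumerate_forests(fig)$scores))
})

test_that("Boltzmann factor follows exp(-score/kT)", {
  sp3 <- enumerate_forests(fixture3())
  f0 <- sp3$forests[[which(sp3$scores == 0)]]
  f1 <- sp3$forests[[which(sp3$scores == 1)]]
  expect_equal(boltzmann_factor(f0, params = ensemble_params(kT = 0.37)), 1)
  expect_equal(boltzmann_factor(f1, params = ensemble_params(kT = 1)),
               exp(-1))
  expect_equal(boltzmann_factor(f1, params = ensemble_params(kT = 0.1)),
               exp(-10))
  # decreasing in score at fixed kT, increasing in kT at fixed positive score
  expect_lt(boltzmann_factor(f1, params = ensemble_params(kT = 1)),
            boltzmann_factor(f0, params = ensemble_params(kT = 1)))
  expect_gt(boltzmann_factor(f1, params = ensemble_params(kT = 2)),
            boltzmann_factor(f1, params = ensemble_params(kT = 1)))
})

test_that("parameter constructors enforce their invariants", {
  expect_error(cost_params(AG = -1), "AG")
  expect_error(ensemble_params(kT = 0))
  expect_error(ensemble_params(alpha = -2))
  expect_equal(cost_params()$AG, 1)
  expect_equal(ensemble_params()$kT, 0.1)
})

test_that("the structural validator accepts scheme output and rejects corruptions", {
  for (inst in list(fixture1(), fixture2(), fixture3(), figure_instance())) {
    f <- backtrack_optimal(compute_tables(inst))
    expect_length(validate_forest_against_instance(f, inst), 0)
  }

  inst <- fixture2()
  f <- backtrack_optimal(compute_tables(inst))
  # ADup claimed at a (Spec,Spec) gene pair
  g <- f
  g$trees[[1]]$event <- "ADup"
  expect_match(validate_forest_against_instance(g, inst),
               "ADup.*requires both genes", all = FALSE)
  # dropping a subtree loses an observed extant adjacency
  h <- f
  h$trees[[1]]$children <- h$trees[[1]]$children[1]
  expect_match(validate_forest_against_instance(h, inst),
               "missing from forest", all = FALSE)
  # claiming an adjacency that was never observed
  k <- f
  k$trees[[1]]$children[[1]]$lab1 <- "a1"
  k$trees[[1]]$children[[1]]$lab2 <- "a2"
  k$trees[[1]]$children[[2]]$lab1 <- "a1"
  expect_gt(length(validate_forest_against_instance(k, inst)), 0)
})

test_that("every forest produced anywhere validates against its instance", {
  for (seed in c(3, 7, 11)) {
    inst <- random_small_instance(seed)
    if (is.null(inst)) next
    sp <- enumerate_forests(inst, max_count = 2e4)
    for (f in sp$forests)
      expect_length(validate_forest_against_instance(f, inst), 0)
    fs <- sample_forests(inst, params = ensemble_params(kT = 0.5),
                         n = 20, seed = seed)
    for (f in fs)
      expect_length(validate_forest_against_instance(f, inst), 0)
  }
})
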