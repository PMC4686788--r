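# Partition function, rescaling, Boltzmann sampling, inside-outside.

lhs1 <- adjensemble:::lhs1
lhs0 <- adjensemble:::lhs0

test_that("partition function matches closed forms on the micro-instances", {
  expect_equal(partition_function(fixture1(),
                                  params = ensemble_params(kT = 1))$Z, 1)
  expect_equal(partition_function(fixture2(),
                                  params = ensemble_params(kT = 1))$Z,
               1 + exp(-2), tolerance = 1e-12)
  expect_equal(partition_function(fixture3(),
                                  params = ensemble_params(kT = 1))$Z,
               1 + exp(-1), tolerance = 1e-12)
})

test_that("Z agrees with the oracle sum over kT, and counting certifies unambiguity", {
  found <- 0; seed <- 900
  while (found < 25) {
    inst <- random_small_instance(seed)
    seed <- seed + 1
    if (is.null(inst)) next
    space <- tryCatch(enumerate_forests(inst, max_count = 2e4),
                      adjensemble_enum_overflow = function(e) NULL)
    if (is.null(space)) next
    found <- found + 1
    for (kt in c(0.1, 0.5, 1, 10)) {
      z <- partition_function(inst, params = ensemble_params(kT = kt))$Z
      expect_equal(z, sum(exp(-space$scores / kt)), tolerance = 1e-9)
    }
    # counting semiring: kT = Inf makes every Boltzmann factor 1, so Z must
    # equal the number of pairwise-distinct forests as exact integers
    zc <- partition_function(inst, params = ensemble_params(kT = Inf))$Z
    sigs <- vapply(space$forests, forest_signature, "")
    expect_false(anyDuplicated(sigs) > 0)
    expect_identical(zc, as.numeric(length(space$forests)))
  }
})

test_that("prescribed rescaling leaves Z recoverable and probabilities unchanged", {
  inst <- fixture2()
  z1 <- partition_function(inst, params = ensemble_params(kT = 1))$Z
  for (a in c(0.1, 2, 10)) {
    pf <- partition_function(inst, params = ensemble_params(kT = 1,
                                                            alpha = a))
    expect_equal(pf$Z_alpha / a^pf$kappa_root, z1, tolerance = 1e-12)
    expect_equal(pf$Z, z1, tolerance = 1e-12)
    m <- adjacency_probability_matrix(inst,
                                      params = ensemble_params(kT = 1,
                                                               alpha = a))
    expect_equal(m$probability[m$gene1 == "r1"], 1 / (1 + exp(-2)),
                 tolerance = 1e-9)
  }
  expect_equal(choose_rescaling(inst, params = ensemble_params(kT = 1)), 1)
  expect_equal(choose_rescaling(inst, alpha = 2), 2)
})

test_that("underflow is detected and an automatic alpha repairs it", {
  # a deep instance with many forced events underflows at kT = 0.01
  sim <- simulate_instance(sim_params(n_species = 40, p_dup = 0.15,
                                      p_loss = 0.1, p_gain = 0.15,
                                      p_break = 0.4, seed = 2))
  inst <- sim$instance
  params <- ensemble_params(kT = 0.01)
  expect_error(compute_tables(inst, algebra = "sum-times", params = params),
               class = "adjensemble_rescale")
  a <- choose_rescaling(inst, params = params)
  expect_gt(a, 1)
  pf <- partition_function(inst,
                           params = ensemble_params(kT = 0.01, alpha = a))
  expect_true(is.finite(pf$Z_alpha) && pf$Z_alpha > 0)
  # log Z must sit close to -s*/kT (co-optimal forests dominate at small kT)
  s_star <- parsimony_score(compute_tables(inst))
  expect_lt(abs(pf$log_Z - (-s_star / 0.01)) / (s_star / 0.01), 0.05)
  # probabilities do not depend on the rescaling factor
  m1 <- adjacency_probability_matrix(inst,
    params = ensemble_params(kT = 0.01, alpha = a))
  m2 <- adjacency_probability_matrix(inst,
    params = ensemble_params(kT = 0.01, alpha = 2 * a))
  expect_lt(max(abs(m1$probability - m2$probability)), 1e-9)
})

test_that("sampling is seeded, deterministic, and Boltzmann-distributed", {
  inst1 <- fixture1()
  fs <- sample_forests(inst1, params = ensemble_params(kT = 1), n = 50,
                       seed = 5)
  expect_length(fs, 50)
  expect_length(unique(vapply(fs, forest_signature, "")), 1)
  expect_length(sample_forests(inst1, n = 0, seed = 1), 0)

  inst2 <- fixture2()
  fs2 <- sample_forests(inst2, params = ensemble_params(kT = 1), n = 10000,
                        seed = 11)
  space <- enumerate_forests(inst2)
  opt_sig <- forest_signature(space$forests[[which(space$scores == 0)]])
  freq <- mean(vapply(fs2, forest_signature, "") == opt_sig)
  expect_equal(freq, 1 / (1 + exp(-2)), tolerance = 0.01)

  again <- sample_forests(inst2, params = ensemble_params(kT = 1), n = 100,
                          seed = 11)
  expect_identical(vapply(again, forest_signature, ""),
                   vapply(fs2[1:100], forest_signature, ""))

  # homogeneous rescaling does not bias the sampler: with a common seed the
  # per-alternative probabilities (hence the draws) are identical
  a1 <- sample_forests(inst2, params = ensemble_params(kT = 1, alpha = 1),
                       n = 200, seed = 3)
  a10 <- sample_forests(inst2, params = ensemble_params(kT = 1, alpha = 10),
                        n = 200, seed = 3)
  expect_identical(vapply(a1, forest_signature, ""),
                   vapply(a10, forest_signature, ""))
})

test_that("outside values invert the scheme exactly", {
  inst <- fixture2()
  tb <- compute_tables(inst, algebra = "sum-times",
                       params = ensemble_params(kT = 1))
  d <- outside_tables(tb)
  r <- tb$root_pid
  expect_equal(d[lhs1(r)], 1)
  expect_equal(d[lhs0(r)], 1)
  # hand inversion at the extant pair (a1,a2): its presence context weight
  # is the whole Z since the adjacency is observed
  pr <- adjensemble:::deco_pairs(inst)
  pid_a <- which(inst$g1$label[pr$px] == "a1" &
                   inst$g2$label[pr$py] == "a2")
  expect_equal(d[lhs1(pid_a)], 1 + exp(-2), tolerance = 1e-12)
  Z <- attr(d, "Z_alpha")
  expect_equal(tb$v[lhs1(pid_a)] * d[lhs1(pid_a)] / Z, 1, tolerance = 1e-12)

  tb3 <- compute_tables(fixture3(), algebra = "sum-times",
                        params = ensemble_params(kT = 1))
  d3 <- outside_tables(tb3)
  pr3 <- adjensemble:::deco_pairs(fixture3())
  pid3 <- which(fixture3()$g1$label[pr3$px] == "a1" &
                  fixture3()$g2$label[pr3$py] == "a2")
  expect_equal(tb3$v[lhs1(pid3)] * d3[lhs1(pid3)] / attr(d3, "Z_alpha"), 1,
               tolerance = 1e-12)
})

test_that("transition probabilities conserve reach probability", {
  for (inst in list(fixture1(), fixture2(), figure_instance())) {
    tb <- compute_tables(inst, algebra = "sum-times",
                         params = ensemble_params(kT = 1))
    tp <- transition_probabilities(tb)
    agg <- stats::aggregate(probability ~ state + gene1 + gene2, tp, sum)
    key <- paste(agg$state, agg$gene1, agg$gene2)
    reach <- tp$reach_probability[match(key, paste(tp$state, tp$gene1,
                                                   tp$gene2))]
    expect_lt(max(abs(agg$probability - reach)), 1e-12)
    # at the root, entering presence or absence partitions the ensemble
    r <- tb$root_pid
    root_reach <- unique(reach[agg$gene1 ==
                                 inst$g1$label[inst$g1$root] &
                               agg$gene2 == inst$g2$label[inst$g2$root]])
    expect_equal(sum(root_reach), 1, tolerance = 1e-12)
  }
})

test_that("adjacency probabilities match the oracle and honour limits", {
  inst <- fixture2()
  m <- adjacency_probability_matrix(inst, params = ensemble_params(kT = 1))
  expect_equal(m$probability[m$extant], c(1, 1), tolerance = 1e-12)
  expect_equal(m$probability[m$ancestral], 1 / (1 + exp(-2)),
               tolerance = 1e-9)
  # the high-temperature limit spreads mass uniformly over the two forests
  m_hot <- adjacency_probability_matrix(inst,
    params = ensemble_params(kT = 1e6))
  expect_equal(m_hot$probability[m_hot$ancestral], 0.5, tolerance = 1e-3)

  found <- 0; seed <- 1500
  while (found < 10) {
    rinst <- random_small_instance(seed)
    seed <- seed + 1
    if (is.null(rinst)) next
    space <- tryCatch(enumerate_forests(rinst, max_count = 2e4),
                      adjensemble_enum_overflow = function(e) NULL)
    if (is.null(space)) next
    found <- found + 1
    for (kt in c(0.5, 2)) {
      mm <- adjacency_probability_matrix(rinst,
        params = ensemble_params(kT = kt))
      op <- oracle_probabilities(space, kT = kt)$probabilities
      po <- op$probability[match(paste(mm$gene1, mm$gene2),
                                 paste(op$gene1, op$gene2))]
      po[is.na(po)] <- 0
      expect_lt(max(abs(mm$probability - po)), 1e-9)
    }
  }
})
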