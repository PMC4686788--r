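# Threshold filtering, conflict accounting, summaries, frequency estimator.

test_that("candidate ancestral adjacencies are pre-speciation pairs", {
  expect_true(is_ancestral_candidate("Spec", "Spec"))
  expect_false(is_ancestral_candidate("GDup", "Spec"))
  expect_false(is_ancestral_candidate("Extant", "Extant"))
  expect_false(is_ancestral_candidate("Spec", "GLoss"))
  m <- adjacency_probability_matrix(figure_instance(),
                                    params = ensemble_params(kT = 1))
  expect_equal(m$ancestral,
               is_ancestral_candidate(
                 figure_instance()$g1$event[adjensemble:::deco_pairs(
                   figure_instance())$px],
                 figure_instance()$g2$event[adjensemble:::deco_pairs(
                   figure_instance())$py]))
})

test_that("probability filtering honours thresholds and the exact-1 rule", {
  m <- adjacency_probability_matrix(fixture2(),
                                    params = ensemble_params(kT = 1))
  expect_equal(nrow(filter_by_probability(m, 0)), sum(m$ancestral))
  expect_equal(nrow(filter_by_probability(m, 0.5)), 1)
  expect_equal(filter_by_probability(m, 0.5)$gene1, "r1")
  expect_equal(nrow(filter_by_probability(m, 1)), 0)  # root prob ~ 0.88
  expect_error(filter_by_probability(m, 1.2), "probability")
  expect_error(filter_by_probability(m, -0.1), "probability")

  # a pair certain up to floating noise survives the "= 1" row
  m1 <- adjacency_probability_matrix(fixture2(),
                                     params = ensemble_params(kT = 0.01))
  expect_equal(nrow(filter_by_probability(m1, 1)), 1)
})

test_that("conflict counting matches direct degree counts", {
  empty <- tibble::tibble(gene1 = character(0), gene2 = character(0))
  expect_equal(count_conflicts(empty), list(genes = 0L, conflicted = 0L))
  star <- tibble::tibble(gene1 = c("hub", "hub", "hub"),
                         gene2 = c("x", "y", "z"))
  expect_equal(count_conflicts(star)$genes, 4L)
  expect_equal(count_conflicts(star)$conflicted, 1L)
  path <- tibble::tibble(gene1 = c("a", "b"), gene2 = c("b", "c"))
  expect_equal(count_conflicts(path)$genes, 3L)
  expect_equal(count_conflicts(path)$conflicted, 0L)
})

test_that("summaries are monotone in the threshold for every kT", {
  insts <- list(fixture2(), figure_instance())
  kts <- c(0.5, 0.1)
  mats <- lapply(kts, function(kt) {
    do.call(rbind, lapply(insts, function(i) {
      adjacency_probability_matrix(i, params = ensemble_params(kT = kt))
    }))
  })
  names(mats) <- kts
  sm <- summarize_ensemble(mats, seq(0.1, 1, by = 0.1))
  expect_equal(nrow(sm), 20)
  for (kt in unique(sm$kT)) {
    sub <- sm[sm$kT == kt, ]
    sub <- sub[order(sub$threshold), ]
    expect_true(all(diff(sub$ancestral_genes) <= 0))
    expect_true(all(diff(sub$ancestral_adjacencies) <= 0))
    expect_true(all(diff(sub$syntenic_conflicts) <= 0))
  }
  expect_error(summarize_ensemble(mats, c(0.5, 0.1)), "ascending")

  empty <- summarize_ensemble(list(`0.1` = NULL), c(0.1, 0.5))
  expect_true(all(empty$ancestral_adjacencies == 0))

  lines <- write_summary(sm)
  expect_length(lines, 11)
  expect_match(lines[1], "genes_kT0.5")
})

test_that("sampled frequencies estimate the exact probabilities", {
  inst1 <- fixture1()
  fs <- sample_forests(inst1, params = ensemble_params(kT = 1), n = 25,
                       seed = 2)
  fm <- sample_frequency_matrix(fs, inst1)
  expect_equal(fm$probability, 1)

  inst2 <- fixture2()
  exact <- adjacency_probability_matrix(inst2,
    params = ensemble_params(kT = 1))
  p_true <- exact$probability[exact$ancestral]
  for (n in c(100, 10000)) {
    fs <- sample_forests(inst2, params = ensemble_params(kT = 1), n = n,
                         seed = 13)
    fm <- sample_frequency_matrix(fs, inst2)
    err <- abs(fm$probability[fm$ancestral] - p_true)
    # three binomial sigmas at the estimated p
    expect_lt(err, 3 * sqrt(p_true * (1 - p_true) / n))
    expect_equal(fm$probability[fm$extant], c(1, 1))
  }

  one <- sample_frequency_matrix(fs[1], inst2)
  expect_true(all(one$probability %in% c(0, 1)))
  expect_error(sample_frequency_matrix(fs, fixture1()), "different instance")
})
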