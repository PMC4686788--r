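# Shared fixtures: the three canonical micro-instances, the two-species
# figure-style instance, and a generator of small random instances whose
# forest space is exhaustively enumerable.

fx_species_A <- function() parse_species_tree("A;")
fx_species_R <- function() parse_species_tree("(A,B)R;")

# single species, two single-gene trees, one observed adjacency
fixture1 <- function() {
  sp <- fx_species_A()
  g1 <- parse_reconciled_gene_trees("a1[&&NHX:S=A:Ev=Extant];", sp)[[1]]
  g2 <- parse_reconciled_gene_trees("a2[&&NHX:S=A:Ev=Extant];", sp)[[1]]
  deco_instance(g1, g2, tibble::tibble(gene1 = "a1", gene2 = "a2"))
}

# two speciation trees over (A,B)R with both descendant adjacencies observed
fixture2 <- function() {
  sp <- fx_species_R()
  tr <- parse_reconciled_gene_trees(paste0(
    "(a1[&&NHX:S=A:Ev=Extant],b1[&&NHX:S=B:Ev=Extant])r1[&&NHX:S=R:Ev=Spec];\n",
    "(a2[&&NHX:S=A:Ev=Extant],b2[&&NHX:S=B:Ev=Extant])r2[&&NHX:S=R:Ev=Spec];"),
    sp)
  deco_instance(tr[[1]], tr[[2]],
                tibble::tibble(gene1 = c("a1", "b1"), gene2 = c("a2", "b2")))
}

# one duplicated family against a single gene, one observed adjacency
fixture3 <- function() {
  sp <- fx_species_A()
  tr <- parse_reconciled_gene_trees(paste0(
    "(a1[&&NHX:S=A:Ev=Extant],a1b[&&NHX:S=A:Ev=Extant])d1[&&NHX:S=A:Ev=GDup];\n",
    "a2[&&NHX:S=A:Ev=Extant];"), sp)
  deco_instance(tr[[1]], tr[[2]],
                tibble::tibble(gene1 = "a1", gene2 = "a2"))
}

# two-extant-species instance with a duplication ancestral in one tree and
# within-species duplications in the other; its parsimonious forest has
# exactly two adjacency trees
figure_instance <- function() {
  sp <- parse_species_tree("(A,B)C;")
  trees <- parse_reconciled_gene_trees(paste0(
    "((A1[&&NHX:S=A:Ev=Extant],B1[&&NHX:S=B:Ev=Extant])c1[&&NHX:S=C:Ev=Spec],",
    "(A2[&&NHX:S=A:Ev=Extant],B2[&&NHX:S=B:Ev=Extant])c2[&&NHX:S=C:Ev=Spec])",
    "c0[&&NHX:S=C:Ev=GDup];\n",
    "((A3[&&NHX:S=A:Ev=Extant],A4[&&NHX:S=A:Ev=Extant])dA[&&NHX:S=A:Ev=GDup],",
    "(B3[&&NHX:S=B:Ev=Extant],B4[&&NHX:S=B:Ev=Extant])dB[&&NHX:S=B:Ev=GDup])",
    "c3[&&NHX:S=C:Ev=Spec];"), sp)
  adj <- parse_adjacencies("A1\tA3\nB1\tB3\nA2\tA4\nB2\tB4\n", trees)
  build_instances(trees, adj)[[1]]
}

# one random instance with both gene trees at <= max_leaves leaves; returns
# NULL when the draw is too large (caller advances the seed)
random_small_instance <- function(seed, max_leaves = 8L) {
  sim <- simulate_instance(sim_params(
    n_species = 2L + seed %% 3L, p_dup = 0.25, p_loss = 0.15,
    p_gain = 0.08, p_break = 0.1, seed = seed))
  nl <- adjensemble:::gt_n_leaves
  if (nl(sim$instance$g1) > max_leaves || nl(sim$instance$g2) > max_leaves)
    return(NULL)
  sim$instance
}

# n random instances whose forest space enumerates within max_count
collect_instances <- function(n, base_seed, max_leaves = 8L,
                              max_count = 2e4) {
  out <- vector("list", n)
  spaces <- vector("list", n)
  k <- 0L; seed <- base_seed
  while (k < n) {
    inst <- random_small_instance(seed, max_leaves)
    seed <- seed + 1L
    if (is.null(inst)) next
    space <- tryCatch(enumerate_forests(inst, max_count = max_count),
                      adjensemble_enum_overflow = function(e) NULL)
    if (is.null(space)) next
    k <- k + 1L
    out[[k]] <- inst
    spaces[[k]] <- space
  }
  list(instances = out, spaces = spaces)
}

# chi-square goodness of fit of sampled forest signatures against the exact
# Boltzmann distribution from an enumerated space; bins with expected count
# below 5 are pooled
gof_pvalue <- function(samples, space, kT) {
  sig <- vapply(samples, forest_signature, "")
  osig <- vapply(space$forests, forest_signature, "")
  stopifnot(all(sig %in% osig))
  s0 <- min(space$scores)
  w <- exp(-(space$scores - s0) / kT)
  p <- w / sum(w)
  obs <- as.numeric(table(factor(sig, levels = osig)))
  n <- length(samples)
  keep <- p * n >= 5
  if (sum(!keep) > 0L) {
    obs <- c(obs[keep], sum(obs[!keep]))
    p <- c(p[keep], sum(p[!keep]))
  }
  if (length(obs) < 2L) return(1)
  suppressWarnings(stats::chisq.test(obs, p = p)$p.value)
}
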