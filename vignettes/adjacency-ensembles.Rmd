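---
title: "Ensembles of gene-adjacency histories: model, algorithms, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensembles of gene-adjacency histories: model, algorithms, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adjensemble)
```

## The model

A species tree S is a rooted binary phylogeny of genomes. A reconciled gene
tree G maps every node g to a species s(g) and an event e(g): internal nodes
are speciations (`Spec`, the children live in the two species children of
s(g)) or gene duplications (`GDup`, both children stay in s(g)); leaves are
extant genes or gene losses (`GLoss`), with losses materialized as leaves so
that every speciation node has one child lineage per species child.

A gene adjacency — two genes consecutive on a chromosome — evolves inside
this scaffold. Its history for a pair of families (G1, G2) is an *adjacency
forest*: a forest over pairs (g1, g2) of co-specific gene nodes. An
adjacency passes speciations (`Spec` nodes), follows one copy through a
one-sided duplication (`GDup` nodes), duplicates when both genes duplicate
simultaneously (`ADup`, producing two adjacencies among the four copy
pairs), disappears with gene loss (`GLoss`/`ALoss` leaves, not penalized —
the loss is already charged to the gene tree), is broken by rearrangement
(`ABreak` leaves, penalty AB), or is created by rearrangement (a gain,
penalty AG, flagged on the root of the gained tree). The parsimony score of
a forest is

$$ s(F) \;=\; AG \cdot \#\text{gains}(F) + AB \cdot \#\text{breaks}(F), $$

and the ensemble view weights every forest of the solution space
$\mathcal F(G_1,G_2)$ by its Boltzmann factor $e^{-s(F)/kT}$, normalized by
the partition function $Z = \sum_F e^{-s(F)/kT}$.

Assumptions worth stating explicitly: gene orientation is not modelled
(adjacencies are unordered label pairs); evolution is duplication–loss only
(no lateral transfer); observed extant adjacencies are treated as data —
every forest of the space realizes exactly the observed set at its extant
leaves.

## The dynamic program and its solution space

For every species-matched pair (g1, g2), two quantities are computed in
double post-order: `c1` (best score / total weight under presence of an
adjacency at the pair) and `c0` (under absence). The recurrence cases follow
the event pair:

* **Extant × Extant** — `c1` is feasible iff the pair is an observed
  adjacency, `c0` iff it is not.
* **any GLoss** — history truncated; both states cost 0.
* **Spec × Spec** — the adjacency passes to both species children: each
  matched child pair either keeps it (`c1`) or breaks it (`c0` + AB).
  Under absence, each child pair stays absent or gains (`c1` + AG).
* **GDup × other** (and symmetric) — the adjacency follows copy a or copy
  b, follows both (one gain), or is broken at the duplication (one break).
* **GDup × GDup** — either a simultaneous `ADup` under one of the two
  copy matchings (each matched pair keeps or breaks; the two cross pairs
  continue in the absent state), or one gene duplicates first (cascade,
  both directions), or the adjacency breaks at the pair. The absent state
  descends the G1 side only.

Each alternative is recorded as a transition (constant cost + recursive
calls); the same records drive the min-plus evaluation, deterministic and
stochastic backtracking, and the inside–outside inversion.

Three design choices fix ambiguities that the prose model leaves open:

1. **Root gains are free.** The instance score is
   `min(c1(r1,r2), c0(r1,r2))` with no extra term, so presence at the root
   pair is not charged a gain; gains are charged only on absent→present
   transitions inside the recurrences. The enumeration oracle uses the same
   convention, so all ensemble quantities are mutually consistent.
2. **One derivation per forest.** The scheme is unambiguous: every forest
   is generated by exactly one execution. Two transcription details are
   needed for this — the broken-at-the-pair alternative of the GDup × GDup
   case is emitted once (continuing with the G1-side decomposition), and
   the absent GDup × GDup state descends one fixed side. The package
   certifies unambiguity on every test batch by running the scheme in the
   counting semiring (kT = ∞, every factor 1) and checking that Z equals
   the number of pairwise-distinct enumerated forests as exact integers.
3. **Break timing is part of the scenario.** A break can be charged on the
   transmission into a pair (after a speciation or an adjacency
   duplication) or at the pair itself (coincident with a gene
   duplication). These are distinct solutions of the scheme; forest nodes
   carry a presence flag and the canonical serialization (children in
   construction order, trees in byte order) distinguishes them, so the
   serialization is injective over the solution space.

## Partition function, rescaling, sampling

Replacing (min, +) by (Σ, ×) and every cost C by `exp(−C/kT)` turns the
same scheme into the partition function. Table values shrink exponentially
with instance size and score, so the sum–product evaluation applies a
*homogeneous rescaling*: a factor α multiplies every call whose pair has
both events ≠ GDup. The number κ(g1, g2) of such factors below a pair is
execution-independent (the package asserts this per pair while building the
tables; the simultaneous-duplication case needs absent-state calls on the
two cross pairs for the count to balance against the cascades, and calls
truncated by a gene loss are counted as if expanded down to the leaves of
the surviving partner subtree). Homogeneity makes the rescaled table value
of each pair exactly `α^κ · c`, so

$$ Z = Z_\alpha / \alpha^{\kappa_{root}}, $$

sampled distributions are unchanged (every alternative of a left-hand side
scales by the same power of α), and inside–outside products cancel the α
powers exactly — the package's tests verify all three invariances to
1e−9 or better.

`choose_rescaling()` returns α = 1 when the plain run stays in range;
otherwise it reads the first failing cell, proposes
`α = exp(s_min/(kT·κ))` from that cell's min-plus score (centring the
rescaled cell near 1), and refines by bisection in log α. A single
homogeneous factor has a bounded feasible window per instance: cells whose
κ-to-score ratio differs strongly cannot all be centred at once, and on
extreme instances (e.g. parsimony score ≳ 10 at kT = 0.01) the window can
be empty; the search then reports this rather than returning a biased
value. Within the regime the method targets — rearrangements are rare, so
scores are small — the window is comfortably wide. Log-space evaluation
would avoid the window entirely but is kept out of the shipped code path
(it exists in spirit in the tests via score-shifted oracle sums); the
rescaling is part of the method being implemented, not an implementation
detail.

Stochastic backtracking draws an alternative at every left-hand side with
probability proportional to its contribution, yielding i.i.d. forests with
probability `exp(−s(F)/kT)/Z`. One seeded generator is used per call
(cumulative-sum inversion over alternatives in recorded order), so a seed
fully determines the output and the caller's RNG state is untouched.

The inside–outside pass inverts the recorded transitions in reverse double
post-order: `d_x(r1,r2) = 1` at the root, and every transition propagates
`d(lhs) · exp(−C/kT) · Π(other inside values)` to each of its calls. Since
each derivation enters a pair at most once (a consequence of the disjoint
descendant rectangles of the scheme, certified by the counting test), the
probability that the ensemble contains adjacency (g1, g2) is simply
`c1·d1/Z` — no multiplicity correction. Values are clamped to [0, 1] only
within 1e−9; a larger excursion raises an error instead of being hidden.

## Parameters

* `kT` (dimensionless, default 0.1): sharpness of the Boltzmann
  distribution. Around 0.5 suboptimal scenarios retain visible mass; 0.1
  concentrates on optimal and slightly suboptimal forests; 0.01 is
  numerically indistinguishable from the co-optimal ensemble. The default
  is the middle of that working range.
* `AG`, `AB` (default 1 each): gain/break penalties; with the defaults the
  score is the plain event count.
* `alpha` (default 1): rescaling factor; `choose_rescaling()` or the CLI's
  `--alpha auto` picks it automatically.
* Probability threshold (analysis-time): candidate ancestral adjacencies
  (both genes pre-speciation, i.e. `Spec` nodes) are retained at
  probability ≥ t; the t = 1 row uses ≥ 1 − 1e−9 so that certainty
  survives floating-point noise. Conflict counts report genes incident to
  ≥ 3 retained adjacencies.

## The synthetic generator

`simulate_instance()` is the package's test surface: a random binary
species tree (default 4 genomes), two gene trees evolved with per-branch
duplication (0.15) and loss (0.1) probabilities, and an adjacency evolved
top-down — persisting through speciations, following one random copy
through one-sided duplications, duplicating under a random matching at
simultaneous duplications, breaking with probability 0.05 per transmission
and gained with probability 0.03 on adjacency-free pairs. The defaults
describe the regime the method is meant for: duplication and loss are
common relative to rearrangement, which is rare. Everything is reproducible
from the seed.

The generator returns the true history, with one deliberate distinction:
a truly-present pair is *witnessed* if at least one extant adjacency
survives below it. An adjacency all of whose extant witnesses were lost is
unidentifiable in principle — presence and absence at that pair have
identical cost, and the ensemble correctly reports ~0.5 — so recovery
checks ("every true ancestral adjacency gets probability ≥ 0.99 at small
kT when rearrangement rates vanish") are asserted on the witnessed set.

What the generator does not emulate: realistic mammalian-scale rate
calibration, lateral transfer, gene conversion, orientation, assembly or
annotation error in extant adjacencies, and errors in the reconciled gene
trees themselves. Passing tests therefore demonstrate algorithmic
correctness of the ensemble machinery on the model's own terms, not
robustness of biological conclusions to model misspecification — on real
data, gene-tree error is a known source of residual syntenic conflict that
no adjacency-level method can remove.

## Numerical and engineering choices

* Infeasible min-plus states are `+Inf`, mapping to weight 0 under
  sum–product; the empty-alternative case is represented explicitly.
* Ties in deterministic backtracking break to the first minimal
  alternative in transcription order, presence preferred at the root.
* All canonical orderings (forest trees, TSV rows) use byte order
  (`method = "radix"`), so outputs are identical across locales.
* The counting certificate uses kT = ∞ so that every weight is exactly 1.0
  and sums are exact integers up to 2^53.
* Exhaustive enumeration is memoized per (pair, state) and capped
  (default 10^6 forests; tests use 2·10^4) with an explicit overflow
  error — the space grows exponentially and the oracle is a test
  instrument, not a user feature.
* Test problem sizes: 200 enumerable instances with gene trees of ≤ 8
  leaves for the oracle-equivalence batteries; 10,000 samples per
  goodness-of-fit check; 50 instances × 3 temperatures for summary
  monotonicity; one ~50-leaf-per-tree instance for rescaling at scale.
  These sizes make every check exact or statistically sharp while keeping
  the whole suite in the minutes range.

## Known limitations

* One homogeneous α per instance; no per-cell or log-space fallback in the
  shipped path (see the feasible-window discussion above).
* The enumeration oracle, and hence the strongest tests, only reach
  instances with a few thousand to a few tens of thousands of forests.
* Self-instances (adjacencies within one family) are handled by a
  two-copy encoding of the same tree; orientation, circular-chromosome
  closure adjacencies and transfer events are out of scope.
* Maximum-expected-accuracy consensus forests are not implemented; the
  probability matrix is the intended entry point for any such
  post-processing.
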