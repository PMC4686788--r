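Package: adjensemble
Title: Boltzmann Ensembles of Gene Adjacency Evolution Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of ancestral gene adjacencies from pairs of
    reconciled gene trees under an ensemble view of the DeCo parsimony model.
    Computes parsimonious adjacency-evolution scenarios, the partition function
    over all adjacency forests, Boltzmann-distributed samples of forests, and
    exact Boltzmann probabilities of candidate ancestral adjacencies via an
    inside-outside algorithm with homogeneous rescaling against numerical
    overflow. Includes threshold-based filtering of ancestral adjacencies,
    syntenic-conflict reporting, an exhaustive enumeration oracle for small
    instances, and a synthetic instance simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
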