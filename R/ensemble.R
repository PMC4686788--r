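## Threshold filtering of ancestral adjacencies, syntenic-conflict
## accounting, and ensemble summary tables.

#' Is a pair of gene nodes a candidate ancestral adjacency?
#'
#' Ancestral genome reconstruction considers pre-speciation genes that were
#' not duplicated within their own species, i.e. gene nodes whose event is a
#' speciation. A pair qualifies when both members do.
#'
#' @param event1,event2 the events of the two gene nodes (`"Spec"`,
#'   `"GDup"`, `"GLoss"`, `"Extant"`), vectorized.
#' @return Logical vector.
#' @export
is_ancestral_candidate <- function(event1, event2) {
  event1 == "Spec" & event2 == "Spec"
}

#' Filter candidate ancestral adjacencies by Boltzmann probability
#'
#' Retains ancestral-candidate pairs with probability at or above the
#' threshold. A threshold of exactly 1 keeps probabilities above
#' `1 - 1e-9` so that co-optimal certainty survives floating-point noise.
#'
#' @param matrix tibble from [adjacency_probability_matrix()] (or several
#'   row-bound ones).
#' @param threshold a probability in `[0, 1]`.
#' @return The retained rows of `matrix`.
#' @export
filter_by_probability <- function(matrix, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a probability in [0,1]", call. = FALSE)
  thr <- if (threshold >= 1) 1 - 1e-9 else threshold
  matrix[matrix$ancestral & matrix$probability >= thr, ]
}

#' Count genes and syntenic conflicts among retained adjacencies
#'
#' A gene on a linear (or circular) chromosome has at most two neighbours;
#' a gene incident to three or more retained adjacencies is in syntenic
#' conflict.
#'
#' @param retained tibble of retained pairs (columns `gene1`, `gene2`).
#' @return A list with `genes` (distinct genes incident to at least one
#'   retained adjacency) and `conflicted` (genes incident to three or more).
#' @export
count_conflicts <- function(retained) {
  if (nrow(retained) == 0L) return(list(genes = 0L, conflicted = 0L))
  deg <- table(c(retained$gene1, retained$gene2))
  list(genes = length(deg), conflicted = sum(deg >= 3L))
}

#' Ensemble summary over pseudo-temperatures and probability thresholds
#'
#' For each kT and each threshold, counts the retained candidate ancestral
#' adjacencies, the distinct ancestral genes incident to them, and the genes
#' in syntenic conflict (incident to three or more retained adjacencies).
#' All three counts are non-increasing in the threshold.
#'
#' @param matrices named list, one element per kT value, each a probability
#'   matrix tibble (or several instances' matrices row-bound together).
#'   Names are the kT values.
#' @param thresholds ascending numeric vector of probability thresholds.
#' @return A tibble with columns `kT`, `threshold`, `ancestral_genes`,
#'   `ancestral_adjacencies`, `syntenic_conflicts`.
#' @export
summarize_ensemble <- function(matrices, thresholds) {
  if (is.unsorted(thresholds))
    stop("thresholds must be sorted ascending", call. = FALSE)
  rows <- list()
  for (k in seq_along(matrices)) {
    kt <- names(matrices)[k]
    m <- matrices[[k]]
    for (th in thresholds) {
      kept <- if (is.null(m) || nrow(m) == 0L)
        tibble::tibble(gene1 = character(0), gene2 = character(0)) else
          filter_by_probability(m, th)
      cc <- count_conflicts(kept)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kT = kt, threshold = th,
        ancestral_genes = cc$genes,
        ancestral_adjacencies = nrow(kept),
        syntenic_conflicts = cc$conflicted)
    }
  }
  do.call(rbind, rows)
}

#' Observed adjacency frequencies in a forest sample
#'
#' The sampling-based estimator of adjacency probabilities: for every
#' species-matched pair of the instance, the fraction of sampled forests
#' containing the adjacency. Converges to the exact inside-outside
#' probabilities at rate ~ n^(-1/2).
#'
#' @param samples nonempty list of `adjacency_forest` objects from one
#'   instance.
#' @param instance the `deco_instance` the samples were drawn from.
#' @return A tibble shaped like [adjacency_probability_matrix()] with the
#'   empirical frequency in the `probability` column.
#' @export
sample_frequency_matrix <- function(samples, instance) {
  if (length(samples) < 1L) stop("need at least one sample", call. = FALSE)
  ids <- vapply(samples, function(f) f$instance_id, "")
  if (any(ids != instance$id))
    stop("samples stem from a different instance", call. = FALSE)
  pairs <- deco_pairs(instance)
  g1 <- instance$g1; g2 <- instance$g2
  key <- paste0(g1$label[pairs$px], "\t", g2$label[pairs$py])
  counts <- stats::setNames(numeric(length(key)), key)
  for (f in samples) {
    pk <- forest_present_pairs(f)
    counts[pk] <- counts[pk] + 1
  }
  obs <- rep(FALSE, pairs$P)
  adj <- instance$adjacencies
  obs[pairs$pid_map[cbind(adj$node1, adj$node2)]] <- TRUE
  out <- tibble::tibble(
    gene1 = g1$label[pairs$px],
    gene2 = g2$label[pairs$py],
    species = g1$species_tree$label[g1$species[pairs$px]],
    probability = unname(counts) / length(samples),
    ancestral = pairs$e1 == "Spec" & pairs$e2 == "Spec",
    extant = obs)
  attr(out, "instance_id") <- instance$id
  attr(out, "n_samples") <- length(samples)
  out
}
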